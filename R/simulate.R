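#' @name simulate
#' @title Monte Carlo signal synthesis
#' @description
#' Random-walk engines (compiled) generate ground-truth signals for every
#' acquisition of a protocol from one shared trajectory set: each DDE block
#' timing contributes one scalar dephasing profile, per-particle profile
#' moments are accumulated during the walk, and all rotations/b-values are
#' scored from those moments. Signals are the real channel, mean cos(phi).
NULL

# scalar dephasing-profile machinery -----------------------------------------

# primitive of the unit block profile (exact cell averages for any dt)
block_profile_primitive <- function(t, t0, delta, Delta) {
  s <- pmin(pmax(t - t0, 0), Delta + delta)
  if (delta == 0) return(pmin(s, Delta))
  up <- ifelse(s < delta, s^2 / (2 * delta), delta / 2 + (s - delta))
  over <- pmax(s - Delta, 0)
  dn <- ifelse(over < delta, over^2 / (2 * delta), delta / 2 + (over - delta))
  up - dn
}

# build the profile matrix U (n_steps x n_prof) and per-row waveform table;
# ptype 1 rows are scored as analytic spherical means (antiparallel pairs
# carry a negative second-block amplitude)
mc_setup <- function(protocol, dt, ptype = NULL) {
  delta <- unique(protocol$delta)
  Delta <- unique(protocol$Delta)
  if (length(delta) != 1 || length(Delta) != 1) {
    stop("all acquisitions must share delta and Delta for trajectory reuse",
         call. = FALSE)
  }
  tms <- sort(unique(protocol$tm[protocol$b2 > 0]))
  t_end <- if (length(tms)) max(2 * Delta + 2 * delta + tms) else Delta + delta
  n_steps <- ceiling(t_end / dt - 1e-9)
  edges <- (0:n_steps) * dt
  cell_avg <- function(t0) {
    diff(block_profile_primitive(edges, t0, delta, Delta)) / dt
  }
  U <- cbind(cell_avg(0))
  prof_of_tm <- integer(0)
  for (tm in tms) {
    U <- cbind(U, cell_avg(Delta + delta + tm))
    prof_of_tm[as.character(tm)] <- ncol(U) - 1L # 0-based for C++
  }
  eff <- if (delta == 0) Delta else Delta - delta / 3
  wf <- list(
    p1 = ifelse(protocol$b1 > 0, 0L, -1L),
    a1 = sqrt(protocol$b1 / eff),
    n1 = as.matrix(protocol[, c("d1x", "d1y", "d1z")]),
    p2 = ifelse(protocol$b2 > 0,
                prof_of_tm[as.character(protocol$tm)], -1L),
    a2 = sqrt(protocol$b2 / eff),
    n2 = as.matrix(protocol[, c("d2x", "d2y", "d2z")])
  )
  wf$p2[is.na(wf$p2)] <- -1L
  if (is.null(ptype)) ptype <- rep(0L, nrow(protocol))
  wf$a2 <- ifelse(ptype == 1L & protocol$theta == 180, -wf$a2, wf$a2)
  wf$ptype <- as.integer(ptype)
  list(U = U, wf = wf, n_steps = n_steps, t_end = t_end)
}

mc_signals <- function(protocol, res) {
  protocol %>%
    dplyr::mutate(
      signal = res$sum_cos / res$n,
      signal_se = sqrt(pmax(res$sum_cos2 / res$n - (res$sum_cos / res$n)^2, 0) /
                         res$n),
      signal_imag = res$sum_sin / res$n
    )
}

#' Monte Carlo signals for exchanging Gaussian pools
#'
#' Random walk with per-step pool switching (probability rate x dt) and
#' Gaussian displacements drawn from the current pool's diffusion tensor.
#'
#' @param sub a [gaussian_substrate()].
#' @param protocol a [build_protocol()] tibble (shared `delta`, `Delta`).
#' @param n_particles walkers (default 1e5).
#' @param dt time step (ms); must satisfy max(rate) * dt < 0.01.
#' @param seed RNG seed (C++ stream; independent of R's RNG).
#' @return protocol tibble with `signal` and `signal_se` columns.
#' @export
simulate_gaussian_exchange <- function(sub, protocol, n_particles = 1e5,
                                       dt = 0.05, seed = 1) {
  stopifnot(inherits(sub, "gaussian_substrate"))
  max_rate <- max(rowSums(sub$rates) - diag(sub$rates))
  if (max_rate * dt >= 0.01) {
    stop("unstable dt: max exchange rate * dt must be < 0.01", call. = FALSE)
  }
  su <- mc_setup(protocol, dt)
  res <- mc_gaussian_cpp(
    su$U, dt, lapply(sub$pools, `[[`, "L"), sub$fractions, sub$rates,
    su$wf$p1, su$wf$a1, su$wf$n1, su$wf$p2, su$wf$a2, su$wf$n2,
    as.integer(n_particles), as.integer(seed), integer(0), su$wf$ptype
  )
  mc_signals(protocol, res)
}

#' Monte Carlo signals in a restricted permeable geometry
#'
#' Random walk with elastic specular reflection at compartment walls and
#' membrane transmission probability \eqn{p = \kappa \sqrt{\pi \, dt / D_0}}
#' at permeable walls; periodic lattice; equal initial particle density in
#' every compartment (or intracellular only).
#'
#' @param sub a [geometry_substrate()].
#' @param protocol acquisition tibble as in [simulate_gaussian_exchange()].
#' @param n_particles walkers (default 1e5; the full-scale study conditions
#'   use 1e6).
#' @param dt time step (ms), default 2e-3 (2 us).
#' @param seed RNG seed.
#' @param intra_only initialise (and keep, when impermeable) all walkers
#'   intracellular.
#' @param record_times times (ms) at which compartment labels and squared
#'   displacements are recorded (for exchange-rate and confinement checks).
#' @param powder `"scheme"` scores every listed rotation with its fixed
#'   directions; `"spherical"` Rao-Blackwellises the rotation average for
#'   collinear-pair shells (SDE, parallel and antiparallel DDE): the exact
#'   spherical mean sin(|W|)/|W| of the per-particle phase is scored instead
#'   of discrete rotations, collapsing those shells to one row each. This is
#'   an exact variance reduction for the (isotropic-measure) powder average;
#'   orthogonal shells keep the discrete scheme.
#' @return protocol tibble with `signal`, `signal_se`; attributes
#'   `label_corr` (tibble t, match fraction), `msd` (tibble t, x/y/z mean
#'   squared displacement), `f_intra` (initial intracellular fraction).
#' @export
simulate_restricted <- function(sub, protocol, n_particles = 1e5, dt = 2e-3,
                                seed = 1, intra_only = FALSE,
                                record_times = NULL,
                                powder = c("scheme", "spherical")) {
  stopifnot(inherits(sub, "geometry_substrate"))
  powder <- match.arg(powder)
  ptype <- NULL
  if (powder == "spherical") {
    collin <- protocol$b2 == 0 | protocol$theta %in% c(0, 180)
    coll <- protocol[collin, ]
    coll <- coll[!duplicated(coll$shell), ]
    coll$rot <- 1L
    protocol <- dplyr::bind_rows(coll, protocol[!collin, ])
    ptype <- c(rep(1L, nrow(coll)), rep(0L, sum(!collin)))
  }
  step_rms <- sqrt(2 * sub$D0 * dt)
  feature <- switch(sub$kind,
    spheres = sub$R, cylinders = sub$R,
    beads = sqrt(max(sub$r0 - sub$r1, 0))
  )
  if (step_rms > feature / 5) {
    stop("step length exceeds feature size / 5; reduce dt", call. = FALSE)
  }
  su <- mc_setup(protocol, dt, ptype)
  rec <- if (is.null(record_times)) integer(0) else {
    sort(unique(pmin(pmax(round(record_times / dt), 1), su$n_steps))) - 1L
  }
  res <- mc_restricted_cpp(
    su$U, dt, sub$kind_code,
    c(sub$R, sub$L, sub$a, sub$r0, sub$r1, sub$period),
    sub$D0, sub$permeability, intra_only,
    su$wf$p1, su$wf$a1, su$wf$n1, su$wf$p2, su$wf$a2, su$wf$n2,
    as.integer(n_particles), as.integer(seed), rec, su$wf$ptype
  )
  out <- mc_signals(protocol, res)
  if (length(rec)) {
    tt <- (rec + 1L) * dt
    attr(out, "label_corr") <- tibble::tibble(
      t = tt, match = res$label_match / res$n
    )
    attr(out, "msd") <- tibble::tibble(
      t = tt, x = res$msd[, 1], y = res$msd[, 2], z = res$msd[, 3]
    )
  }
  attr(out, "f_intra") <- res$n_intra0 / res$n
  out
}

#' Exchange rate from a compartment-label autocorrelation
#'
#' Fits the mono-exponential decay of the label self-agreement
#' \eqn{C(t) = C_\infty + (1 - C_\infty) e^{-kt}} and returns the total
#' two-pool rate \eqn{k = k_{in} + k_{out}} (the rate entering h(k)).
#'
#' @param label_corr tibble with columns `t` (ms) and `match` (fraction of
#'   walkers whose label equals their initial label).
#' @param C_inf equilibrium agreement \eqn{\sum_j f_j^2}; taken from the
#'   table's `C_inf` attribute (set by [label_correlation()]) if NULL.
#' @param tol relative residual above which the decay is flagged as
#'   non-exponential (a warning; a second timescale usually means multiple
#'   distinct exchange processes).
#' @return exchange rate in 1/s (attribute `k_per_ms` carries 1/ms).
#' @export
measure_exchange_rate <- function(label_corr, C_inf = NULL, tol = 0.05) {
  tt <- label_corr$t
  cc <- label_corr$match
  if (is.null(C_inf)) C_inf <- attr(label_corr, "C_inf")
  if (is.null(C_inf)) {
    stop("supply C_inf (= sum of squared equilibrium fractions)", call. = FALSE)
  }
  y <- cc - C_inf
  keep <- y > 1e-4
  if (sum(keep) < 2) stop("label correlation already at equilibrium", call. = FALSE)
  fit <- lm(log(y[keep]) ~ tt[keep])
  k <- -coef(fit)[[2]]
  res <- sqrt(mean(fit$residuals^2))
  if (res > tol) {
    warning("label autocorrelation is not mono-exponential (rms log residual ",
            signif(res, 2), "); slowest-rate estimate returned", call. = FALSE)
  }
  structure(k * ms_per_s, k_per_ms = k)
}

#' Label autocorrelation of a substrate (no encoding)
#'
#' Runs the walker engine without waveforms and records the fraction of
#' walkers still carrying their initial compartment label.
#'
#' @param sub [geometry_substrate()] or [gaussian_substrate()].
#' @param t_max duration (ms).
#' @param n_record number of sample times.
#' @param n_particles,dt,seed as in the simulators.
#' @return tibble with columns `t`, `match`.
#' @export
label_correlation <- function(sub, t_max = 50, n_record = 25,
                              n_particles = 2e4, dt = NULL, seed = 1) {
  rec_t <- seq(t_max / n_record, t_max, length.out = n_record)
  if (inherits(sub, "geometry_substrate")) {
    if (is.null(dt)) dt <- 2e-3
    n_steps <- ceiling(t_max / dt)
    rec <- pmin(pmax(round(rec_t / dt), 1), n_steps) - 1L
    res <- mc_restricted_cpp(
      matrix(0, n_steps, 1), dt, sub$kind_code,
      c(sub$R, sub$L, sub$a, sub$r0, sub$r1, sub$period),
      sub$D0, sub$permeability, FALSE,
      integer(0), numeric(0), matrix(0, 0, 3),
      integer(0), numeric(0), matrix(0, 0, 3),
      as.integer(n_particles), as.integer(seed), as.integer(rec), integer(0)
    )
    f <- res$n_intra0 / res$n
    C_inf <- f^2 + (1 - f)^2
  } else {
    if (is.null(dt)) dt <- 0.05
    n_steps <- ceiling(t_max / dt)
    rec <- pmin(pmax(round(rec_t / dt), 1), n_steps) - 1L
    res <- mc_gaussian_cpp(
      matrix(0, n_steps, 1), dt, lapply(sub$pools, `[[`, "L"),
      sub$fractions, sub$rates,
      integer(0), numeric(0), matrix(0, 0, 3),
      integer(0), numeric(0), matrix(0, 0, 3),
      as.integer(n_particles), as.integer(seed), as.integer(rec), integer(0)
    )
    C_inf <- sum(sub$fractions^2)
  }
  out <- tibble::tibble(t = (rec + 1L) * dt, match = res$label_match / res$n)
  attr(out, "C_inf") <- C_inf
  out
}

#' Calibrate membrane permeability to a target exchange rate
#'
#' Bisection on kappa such that the measured label-autocorrelation exchange
#' rate matches `k_target_per_s` within `tol_frac`. The measured rate (not
#' the transmission-probability rule) defines k.
#'
#' @param sub a [geometry_substrate()].
#' @param k_target_per_s target rate (1/s).
#' @param seed RNG seed.
#' @param tol_frac relative tolerance (default 0.05).
#' @param n_particles,dt,t_max simulation scale for each probe run.
#' @param kappa_max upper bracket for kappa (um/ms).
#' @return calibrated kappa (um/ms), with attribute `k_measured_per_s`.
#' @export
calibrate_permeability <- function(sub, k_target_per_s, seed = 1,
                                   tol_frac = 0.05, n_particles = 2e4,
                                   dt = 2e-3, t_max = 40, kappa_max = 0.5) {
  stopifnot(k_target_per_s >= 0)
  if (k_target_per_s == 0) {
    return(structure(0, k_measured_per_s = 0))
  }
  probe <- function(kappa, s) {
    sub$permeability <- kappa
    lc <- label_correlation(sub, t_max = t_max, n_particles = n_particles,
                            dt = dt, seed = s)
    suppressWarnings(as.numeric(measure_exchange_rate(lc)))
  }
  lo <- 0
  hi <- kappa_max
  k_hi <- probe(hi, seed)
  if (k_hi < k_target_per_s) stop("unattainable target exchange rate", call. = FALSE)
  k_mid <- NA
  for (it in 1:12) {
    mid <- (lo + hi) / 2
    k_mid <- probe(mid, seed + it)
    if (abs(k_mid - k_target_per_s) < tol_frac * k_target_per_s) {
      return(structure(mid, k_measured_per_s = k_mid))
    }
    if (k_mid < k_target_per_s) lo <- mid else hi <- mid
  }
  structure((lo + hi) / 2, k_measured_per_s = k_mid)
}
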