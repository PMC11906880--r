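#' Powder-average per-rotation signals
#'
#' Arithmetic mean of normalized signals over rotations (and repeated
#' second-pair directions) within each acquisition shell: same set, total
#' b-value, pair angle and mixing time.
#'
#' @param signals tibble with the protocol columns plus `signal`.
#' @return powder table: one row per shell with `signal` (mean) and
#'   `n_rotations`; retains `b`, `b_shape`, `b_mu`, timings.
#' @export
powder_average <- function(signals) {
  if (!nrow(signals)) stop("empty signal table", call. = FALSE)
  if (!"shell" %in% names(signals)) {
    signals <- dplyr::mutate(
      signals,
      shell = paste(.data$set_id, .data$b1 + .data$b2, .data$tm, sep = "|")
    )
  }
  out <- signals %>%
    dplyr::group_by(
      .data$shell, .data$set_id, .data$b1, .data$b2, .data$theta,
      .data$delta, .data$Delta, .data$tm
    ) %>%
    dplyr::summarise(
      signal = mean(.data$signal),
      n_rotations = dplyr::n(),
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      b = .data$b1 + .data$b2,
      b_shape = b_shape_closed(.data$b1, .data$b2, .data$theta),
      b_mu = b_mu_closed(.data$b1, .data$b2)
    ) %>%
    dplyr::arrange(.data$set_id, .data$b, .data$tm, .data$theta)
  class(out) <- c("ddex_powder", class(out))
  out
}

#' Corrupt signals with Rician (magnitude-MRI) noise
#'
#' \eqn{S_{noisy} = |S + n_r + i n_i|} with independent Gaussian noise of
#' standard deviation 1/snr in each channel.
#'
#' @param signal numeric vector of normalized signals.
#' @param snr signal-to-noise ratio at S = 1; must be > 0.
#' @param seed optional seed for reproducibility.
#' @return noisy signal vector.
#' @export
add_rician_noise <- function(signal, snr, seed = NULL) {
  if (snr <= 0) stop("snr must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  sigma <- 1 / snr
  sqrt((signal + rnorm(length(signal), 0, sigma))^2 +
         rnorm(length(signal), 0, sigma)^2)
}

#' Long-mixing-time diagnostic: parallel vs antiparallel DDE
#'
#' Difference of the logs of powder-averaged signals from parallel
#' (theta = 0) and antiparallel (theta = 180) DDE at equal b. A vanishing
#' difference is the conventional indicator that the displacement-correlation
#' (long mixing time) regime of CTI has been reached.
#'
#' @param powder a [powder_average()] table containing both shells.
#' @return the scalar log-signal difference (or a tibble when several
#'   b-values are present).
#' @export
long_mixing_check <- function(powder) {
  par <- powder[powder$theta == 0 & powder$b2 > 0, ]
  apar <- powder[powder$theta == 180, ]
  if (!nrow(par) || !nrow(apar)) {
    stop("powder table must contain theta = 0 and theta = 180 shells", call. = FALSE)
  }
  j <- dplyr::inner_join(
    dplyr::select(par, "b", "tm", sp = "signal"),
    dplyr::select(apar, "b", "tm", sa = "signal"),
    by = c("b", "tm")
  )
  if (!nrow(j)) stop("no matching b between parallel and antiparallel shells", call. = FALSE)
  d <- log(j$sp) - log(j$sa)
  if (length(d) == 1) d else dplyr::mutate(j, diff = d)
}

# exchange-weight evaluators --------------------------------------------------

#' Per-shell exchange-weight evaluator for model fitting
#'
#' Returns a function `k -> list(h, h_shape)` aligned with the rows of
#' `shells`. Narrow-pulse shells use the closed forms ([h_pair_closed()]);
#' finite-pulse shells use lag-series of the isotropic and anisotropic
#' autocorrelation projections of the sampled waveform, pre-computed once and
#' integrated against exp(-kt) at call time.
#'
#' @param shells tibble with columns `b1`, `b2`, `theta`, `delta`, `Delta`,
#'   `tm` (one row per shell).
#' @param method "auto" (closed when `delta == 0`), "closed" (treat as
#'   narrow-pulse regardless), or "numeric".
#' @param dt waveform sample interval for the numeric path (ms).
#' @param lag_bin lag-series bin width for the numeric path (ms).
#' @return function of a scalar k (1/ms).
#' @export
make_weight_eval <- function(shells, method = c("auto", "closed", "numeric"),
                             dt = 0.01, lag_bin = 0.1) {
  method <- match.arg(method)
  if (method == "auto") {
    method <- if (all(shells$delta == 0)) "closed" else "numeric"
  }
  if (method == "closed") {
    grp <- paste(shells$Delta, shells$tm)
    ug <- !duplicated(grp)
    uDelta <- shells$Delta[ug]
    utm <- shells$tm[ug]
    gidx <- match(grp, grp[ug])
    q1sq <- shells$b1 / shells$Delta
    q2sq <- shells$b2 / shells$Delta
    btot2 <- (shells$b1 + shells$b2)^2
    c2 <- cos(shells$theta * pi / 180)^2
    function(k) {
      gs_u <- mapply(function(D) g_self(k, D), uDelta)
      gc_u <- mapply(function(D, tm) g_cross(k, D, tm), uDelta, utm)
      gs <- gs_u[gidx]
      gc_ <- gc_u[gidx]
      self_term <- 2 * gs * (q1sq^2 + q2sq^2)
      cross <- q1sq * q2sq * gc_
      h <- (self_term + 2 * cross) / btot2
      list(h = h, h_shape = (self_term + cross * (3 * c2 - 1)) / (btot2 * h))
    }
  } else {
    series <- purrr::pmap(
      list(shells$b1, shells$b2, shells$theta, shells$delta, shells$Delta,
           shells$tm),
      function(b1, b2, theta, delta, Delta, tm) {
        weight_series(b1, b2, theta, delta, Delta, tm, dt, lag_bin)
      }
    )
    function(k) {
      vals <- vapply(series, function(s) {
        iso <- s$iso0 + 2 * sum(s$iso * exp(-k * s$tau))
        ani <- s$ani0 + 2 * sum(s$ani * exp(-k * s$tau))
        h <- iso * s$dt_sq / s$b_sq
        c(h, 1.5 * ani * s$dt_sq / (s$b_sq * h))
      }, numeric(2))
      list(h = vals[1, ], h_shape = vals[2, ])
    }
  }
}

# binned lag series of the isotropic (|q|^2) and anisotropic (traceless
# Voigt components) autocorrelations of one representative waveform
weight_series <- function(b1, b2, theta, delta, Delta, tm, dt, lag_bin) {
  w <- make_dde_waveform(
    dde_block(b1 = b1, b2 = max(b2, 0), theta = theta, delta = delta,
              Delta = Delta, tm = tm, dir1 = c(0, 0, 1)),
    dt = dt
  )
  q <- w$q
  v_iso <- rowSums(q^2)
  # orthonormal traceless basis of symmetric tensors (Voigt, sqrt-2 scaling)
  s1 <- (q[, 1]^2 - q[, 2]^2) / sqrt(2)
  s2 <- (q[, 1]^2 + q[, 2]^2 - 2 * q[, 3]^2) / sqrt(6)
  s3 <- sqrt(2) * q[, 1] * q[, 2]
  s4 <- sqrt(2) * q[, 1] * q[, 3]
  s5 <- sqrt(2) * q[, 2] * q[, 3]
  ci <- corr_series(v_iso, v_iso)
  ca <- corr_series(s1, s1) + corr_series(s2, s2) + corr_series(s3, s3) +
    corr_series(s4, s4) + corr_series(s5, s5)
  n <- length(ci)
  lag <- (seq_len(n) - 1) * w$dt
  bin <- pmax(ceiling(lag / lag_bin), 1)[-1]
  wsum <- function(x) as.numeric(tapply(x[-1], bin, sum))
  wmean_lag <- function(x) {
    s <- as.numeric(tapply(abs(x[-1]), bin, sum))
    m <- as.numeric(tapply(lag[-1] * abs(x[-1]), bin, sum))
    ifelse(s > 0, m / s, as.numeric(tapply(lag[-1], bin, mean)))
  }
  list(
    tau = wmean_lag(ci), iso = wsum(ci), iso0 = ci[1],
    ani = wsum(ca), ani0 = ca[1],
    dt_sq = w$dt^2, b_sq = (sum(v_iso) * w$dt)^2
  )
}

# model fitting ---------------------------------------------------------------

model_params <- function(model, fit_s0) {
  p <- switch(model,
    cti = c("D", "K_I", "K_A", "K_mu"),
    mge1d = c("D", "K_T", "k"),
    mge = c("D", "K_I0", "K_A0", "K_Iinf", "K_Ainf", "k"),
    tmge = c("D", "K_I0", "K_A0", "K_Iinf", "K_Ainf", "K_eps", "k")
  )
  if (fit_s0) c(p, "S0") else p
}

default_bounds <- function(params) {
  lower <- c(D = 1e-3, K_I = -3, K_A = -3, K_mu = -3, K_T = -3, K_I0 = -3,
             K_A0 = -3, K_Iinf = -3, K_Ainf = -3, K_eps = -3, k = 0, S0 = 0.5)
  upper <- c(D = 4, K_I = 5, K_A = 5, K_mu = 5, K_T = 5, K_I0 = 5,
             K_A0 = 5, K_Iinf = 5, K_Ainf = 5, K_eps = 5, k = 0.5, S0 = 1.5)
  list(lower = lower[params], upper = upper[params])
}

#' Fit a signal representation to a powder table
#'
#' Bounded multi-start Levenberg-Marquardt least squares (the analogue of the
#' study's lsqnonlin procedure: starts drawn uniformly between the bounds,
#' lowest-residual convergent fit returned). Exchange weights (h,
#' \eqn{h_\Delta^2}) are re-evaluated inside the objective from each shell's
#' waveform at the current exchange rate. Models:
#'
#' * `"cti"` - [cti_signal()]; fitted at a single (long) mixing time.
#' * `"mge1d"` - [mge1d_signal()]; restricted to the theta = 0 subset
#'   (SDE plus parallel DDE).
#' * `"mge"` - [mge_signal()].
#' * `"tmge"` - [tmge_signal()]; requires at least two distinct DDE mixing
#'   times, otherwise k and the transient kurtosis are inseparable.
#'
#' @param table a [powder_average()] table (columns `b`, `b_shape`, `b_mu`,
#'   `delta`, `Delta`, `tm`, `theta`, `b1`, `b2`, `signal`).
#' @param model one of "cti", "mge1d", "mge", "tmge".
#' @param n_starts random starts (default 10).
#' @param seed RNG seed for the starts.
#' @param bounds optional list(lower, upper) named vectors overriding the
#'   defaults (D in (0, 4] um^2/ms, kurtosis in [-3, 5], k in [0, 0.5] 1/ms).
#' @param weights passed to [make_weight_eval()] (`method`).
#' @param log_domain fit in the log-signal domain instead of linear signals.
#' @param fit_s0 estimate a nuisance scale S0 (for noisy data).
#' @return object of class `ddex_fit`; see [tidy.ddex_fit()],
#'   [glance.ddex_fit()], [autoplot.ddex_fit()].
#' @export
fit_model <- function(table, model = c("cti", "mge1d", "mge", "tmge"),
                      n_starts = 10, seed = 1, bounds = NULL,
                      weights = "auto", log_domain = FALSE, fit_s0 = FALSE) {
  model <- match.arg(model)
  tab <- dplyr::arrange(tibble::as_tibble(table),
                        .data$set_id, .data$b, .data$tm, .data$theta)
  if (model == "mge1d") {
    tab <- tab[tab$theta == 0 | tab$b2 == 0, ]
  }
  if (!nrow(tab)) stop("no usable rows for model ", model, call. = FALSE)
  if (model == "tmge") {
    n_tm <- length(unique(tab$tm[tab$b2 > 0]))
    if (n_tm < 2) {
      stop("tMGE requires at least two distinct DDE mixing times", call. = FALSE)
    }
  }
  params <- model_params(model, fit_s0)
  bb <- default_bounds(params)
  if (!is.null(bounds)) {
    bb$lower[names(bounds$lower)] <- bounds$lower
    bb$upper[names(bounds$upper)] <- bounds$upper
  }
  w_eval <- if (model == "cti") NULL else {
    make_weight_eval(tab, method = weights)
  }
  predict_ln <- function(p) {
    s0 <- if (fit_s0) p[["S0"]] else 1
    ln <- switch(model,
      cti = cti_signal(p[["D"]], p[["K_I"]], p[["K_A"]], p[["K_mu"]],
                       tab$b, tab$b_shape, tab$b_mu),
      mge1d = {
        wts <- w_eval(p[["k"]])
        mge1d_signal(p[["D"]], p[["K_T"]], tab$b, wts$h)
      },
      mge = {
        wts <- w_eval(p[["k"]])
        mge_signal(p[["D"]], p[["K_I0"]], p[["K_A0"]], p[["K_Iinf"]],
                   p[["K_Ainf"]], tab$b, tab$b_shape, wts$h, wts$h_shape)
      },
      tmge = {
        wts <- w_eval(p[["k"]])
        tmge_signal(p[["D"]], p[["K_I0"]], p[["K_A0"]], p[["K_Iinf"]],
                    p[["K_Ainf"]], p[["K_eps"]], tab$b, tab$b_shape,
                    tab$b_mu, wts$h, wts$h_shape)
      }
    )
    list(ln = ln, s0 = s0)
  }
  residual_fn <- function(p) {
    names(p) <- params
    pr <- predict_ln(p)
    if (log_domain) {
      pr$ln + log(pr$s0) - log(pmax(table_signal, 1e-12))
    } else {
      pr$s0 * exp(pr$ln) - table_signal
    }
  }
  table_signal <- tab$signal

  set.seed(seed)
  starts <- lapply(seq_len(n_starts), function(i) {
    runif(length(params), bb$lower, bb$upper)
  })
  best <- NULL
  n_conv <- 0L
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = st, lower = unname(bb$lower), upper = unname(bb$upper),
        fn = residual_fn,
        control = minpack.lm::nls.lm.control(maxiter = 300, ftol = 1e-14,
                                             ptol = 1e-14)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    n_conv <- n_conv + 1L
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    stop("no start converged: insufficient design for model ", model, call. = FALSE)
  }
  est <- setNames(best$fit$par, params)
  # identifiability report: column-normalized finite-difference Jacobian
  J <- vapply(seq_along(params), function(j) {
    hstep <- pmax(abs(est[j]), 0.1) * 1e-6
    pp <- est
    pp[j] <- pp[j] + hstep
    (residual_fn(pp) - residual_fn(est)) / hstep
  }, numeric(nrow(tab)))
  cn <- sqrt(colSums(J^2))
  sv <- svd(J / rep(pmax(cn, 1e-300), each = nrow(J)))$d
  rank_def <- min(sv) < 1e-8 * max(sv)
  if (rank_def) {
    warning("rank-deficient design at the solution: some ", model,
            " parameters are not identifiable from this table", call. = FALSE)
  }
  pr <- predict_ln(est)
  structure(
    list(model = model, estimates = est, residual_norm = sqrt(best$rss),
         rss = best$rss, n_starts = n_starts, n_converged = n_conv,
         converged = best$fit$info %in% 1:4, rank_deficient = rank_def,
         bounds = bb, seed = seed, log_domain = log_domain,
         data = tab, fitted = pr$s0 * exp(pr$ln)),
    class = "ddex_fit"
  )
}

#' @export
print.ddex_fit <- function(x, ...) {
  cat(sprintf("<ddex_fit: %s> %d shells, rss = %.3g%s\n", x$model,
              nrow(x$data), x$rss,
              if (x$rank_deficient) " [rank-deficient]" else ""))
  est <- x$estimates
  if ("k" %in% names(est)) {
    cat(sprintf("  k = %.4g /ms (%.3g /s)\n", est[["k"]],
                est[["k"]] * ms_per_s))
  }
  print(round(est, 5))
  invisible(x)
}

#' Tidy a fitted signal representation
#' @param x a `ddex_fit`.
#' @param ... unused.
#' @return tibble with columns `term`, `estimate` (exchange rate additionally
#'   reported as `k_per_s`).
#' @method tidy ddex_fit
#' @export
tidy.ddex_fit <- function(x, ...) {
  out <- tibble::tibble(term = names(x$estimates),
                        estimate = unname(x$estimates))
  if ("k" %in% out$term) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      term = "k_per_s", estimate = x$estimates[["k"]] * ms_per_s
    ))
  }
  out
}

#' One-row summary of a fitted signal representation
#' @param x a `ddex_fit`.
#' @param ... unused.
#' @method glance ddex_fit
#' @export
glance.ddex_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model, n_obs = nrow(x$data), rss = x$rss,
    residual_norm = x$residual_norm, n_starts = x$n_starts,
    n_converged = x$n_converged, converged = x$converged,
    rank_deficient = x$rank_deficient, seed = x$seed
  )
}

#' Design-matrix sensitivity of the tMGE representation
#'
#' For each exchange rate, the coefficients multiplying each kurtosis
#' parameter of the tMGE log-signal across the protocol's shells
#' (per unit signal, at diffusivity `D`), together with collinearity
#' diagnostics: the correlation between the exchanging and persistent
#' isotropic/anisotropic columns, the condition number of the scaled
#' kurtosis design block, and the residual mixing-time dependence of h.
#' At k = 0 the exchanging and persistent columns are exactly collinear;
#' at very fast exchange the mixing-time dependence collapses.
#'
#' @param shells shell tibble ([protocol_shells()]).
#' @param k_per_s exchange rates to probe (1/s).
#' @param D diffusivity used for the coefficients (um^2/ms).
#' @param weights method for [make_weight_eval()].
#' @return list with `coefficients` (long tibble: k_per_s, shell, term,
#'   value) and `diagnostics` (per k: `cor_iso`, `cor_aniso`, `condition`,
#'   `tm_span_h`).
#' @export
design_sensitivity <- function(shells, k_per_s = c(0, 5, 20, 50, 200), D = 1,
                               weights = "auto") {
  if (length(unique(shells$tm[shells$b2 > 0])) < 2) {
    stop("protocol must contain multiple mixing times", call. = FALSE)
  }
  w_eval <- make_weight_eval(shells, method = weights)
  pref <- shells$b^2 * D^2 / 6
  coefs <- list()
  diags <- list()
  for (kps in k_per_s) {
    wts <- w_eval(kps / ms_per_s)
    X <- cbind(
      K_I0 = pref * wts$h,
      K_A0 = pref * wts$h * wts$h_shape,
      K_Iinf = pref,
      K_Ainf = pref * shells$b_shape,
      K_eps = pref * shells$b_mu
    )
    coefs[[length(coefs) + 1L]] <- tibble::tibble(
      k_per_s = kps, shell = rep(shells$shell, ncol(X)),
      term = rep(colnames(X), each = nrow(X)), value = as.vector(X)
    )
    Xs <- scale(X, center = FALSE,
                scale = apply(X, 2, function(c) max(abs(c), 1e-12)))
    sv <- svd(Xs)$d
    dde <- shells$b2 > 0 & shells$theta == 0
    h_span <- if (any(dde)) {
      stats::aggregate(wts$h[dde], list(shells$b[dde]), function(v) diff(range(v)))
    } else NULL
    diags[[length(diags) + 1L]] <- tibble::tibble(
      k_per_s = kps,
      cor_iso = stats::cor(X[, "K_I0"], X[, "K_Iinf"]),
      cor_aniso = stats::cor(X[, "K_A0"], X[, "K_Ainf"]),
      condition = max(sv) / max(min(sv), 1e-300),
      tm_span_h = if (is.null(h_span)) NA_real_ else max(h_span$x)
    )
  }
  list(coefficients = dplyr::bind_rows(coefs),
       diagnostics = dplyr::bind_rows(diags))
}

#' Parameter-recovery study for a signal representation
#'
#' Generate -> corrupt (Rician) -> fit, repeated; reports per-parameter
#' estimates across noise realisations.
#'
#' @param truth named list/vector of true parameters (model-appropriate;
#'   `k` in 1/ms).
#' @param protocol acquisition tibble (rotation level).
#' @param model fitted representation.
#' @param snr Rician signal-to-noise ratio (Inf for noiseless).
#' @param n_reps noise realisations (>= 2 unless noiseless).
#' @param seed base seed; rep r uses seed + r for noise and fits.
#' @param ... passed to [fit_model()].
#' @return tibble of class `ddex_recovery`: columns `rep`, `term`,
#'   `estimate`, `true`; attribute `summary` has per-term bias, sd, median.
#' @export
recovery_study <- function(truth, protocol, model = "tmge", snr = 200,
                           n_reps = 50, seed = 1, ...) {
  shells <- protocol_shells(protocol)
  w_eval <- make_weight_eval(shells, method = "auto")
  wts <- w_eval(truth[["k"]])
  ln <- switch(model,
    mge1d = mge1d_signal(truth[["D"]], truth[["K_T"]], shells$b, wts$h),
    mge = mge_signal(truth[["D"]], truth[["K_I0"]], truth[["K_A0"]],
                     truth[["K_Iinf"]], truth[["K_Ainf"]], shells$b,
                     shells$b_shape, wts$h, wts$h_shape),
    tmge = tmge_signal(truth[["D"]], truth[["K_I0"]], truth[["K_A0"]],
                       truth[["K_Iinf"]], truth[["K_Ainf"]], truth[["K_eps"]],
                       shells$b, shells$b_shape, shells$b_mu, wts$h,
                       wts$h_shape),
    stop("recovery_study supports mge1d, mge, tmge", call. = FALSE)
  )
  rot <- dplyr::left_join(
    protocol, dplyr::mutate(shells, .ln = ln)[, c("shell", ".ln")],
    by = "shell"
  )
  out <- purrr::map_dfr(seq_len(n_reps), function(r) {
    sig <- exp(rot$.ln)
    if (is.finite(snr)) sig <- add_rician_noise(sig, snr, seed = seed + r)
    pt <- powder_average(dplyr::mutate(rot, signal = sig))
    fit <- fit_model(pt, model = model, seed = seed + r, ...)
    dplyr::mutate(tidy(fit), rep = r)
  })
  tr <- tibble::tibble(term = names(truth), true = unlist(truth))
  out <- dplyr::left_join(out, tr, by = "term")
  smry <- out %>%
    dplyr::filter(!is.na(.data$true)) %>%
    dplyr::group_by(.data$term) %>%
    dplyr::summarise(
      true = .data$true[1],
      median = median(.data$estimate),
      bias = mean(.data$estimate) - .data$true[1],
      sd = sd(.data$estimate),
      .groups = "drop"
    )
  attr(out, "summary") <- smry
  class(out) <- c("ddex_recovery", class(out))
  out
}
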