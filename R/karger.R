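#' Kaerger matrix-exponential signal for exchanging Gaussian pools
#'
#' Exact narrow-pulse DDE/SDE signal for Gaussian pools with first-order
#' exchange: between impulses the magnetisation fractions evolve as
#' \deqn{m' = [K - q^2 \mathrm{diag}(D_{app})] m,} with K the exchange
#' generator and \eqn{D_{app,j}} the projection of pool j's tensor on the
#' active encoding direction. The signal is the sum of the pool
#' magnetisations at the end of the waveform. This is the reference oracle
#' against which the Monte Carlo engine and the cumulant representations are
#' validated.
#'
#' @param sub a [gaussian_substrate()] (any number of pools).
#' @param spec a [dde_block()] with `delta = 0` (narrow pulses).
#' @return normalized signal E in (0, 1].
#' @examples
#' sub <- gaussian_substrate(
#'   list(gaussian_pool(2, fraction = 0.5), gaussian_pool(0.5, fraction = 0.5)),
#'   k = 0.05
#' )
#' karger_signal(sub, dde_block(1.25, 1.25, delta = 0, Delta = 12, tm = 12))
#' @export
karger_signal <- function(sub, spec) {
  stopifnot(inherits(sub, "gaussian_substrate"), inherits(spec, "dde_block"))
  if (spec$delta != 0) {
    stop("karger_signal requires narrow pulses (delta = 0)", call. = FALSE)
  }
  f <- sub$fractions
  K <- karger_generator(sub$rates)
  q1sq <- spec$b1 / spec$Delta
  q2sq <- spec$b2 / spec$Delta
  d_app <- function(dir) {
    vapply(sub$pools, function(p) as.numeric(dir %*% p$D %*% dir), numeric(1))
  }
  m <- f
  m <- expm_db(K - q1sq * diag(d_app(spec$dir1), length(f)), f, spec$Delta) %*% m
  if (spec$tm > 0) m <- expm_db(K, f, spec$tm) %*% m
  if (q2sq > 0) {
    m <- expm_db(K - q2sq * diag(d_app(spec$dir2), length(f)), f, spec$Delta) %*% m
  }
  sum(m)
}

# exchange generator: dm_j/dt = sum_i k_{i->j} m_i - (sum_j k_{j->i}) m_j
karger_generator <- function(rates) {
  n <- nrow(rates)
  K <- t(rates)
  diag(K) <- 0
  diag(K) <- -(rowSums(rates) - diag(rates))
  K
}

# matrix exponential exp(G t) for generators similar (via the equilibrium
# fractions f, detailed balance) to a symmetric matrix: eigen-decompose
# F^{-1/2} G F^{1/2} which is symmetric, then transform back
expm_db <- function(G, f, t) {
  s <- sqrt(f)
  S <- G * outer(1 / s, s)
  S <- (S + t(S)) / 2 # symmetrise away rounding
  es <- eigen(S, symmetric = TRUE)
  V <- es$vectors
  (V %*% (exp(es$values * t) * t(V))) * outer(s, 1 / s)
}

#' Kaerger signals for every acquisition of a protocol
#'
#' @param sub a [gaussian_substrate()].
#' @param protocol a [build_protocol()] tibble realised with
#'   `narrow_pulse = TRUE`.
#' @return the protocol tibble with a `signal` column appended.
#' @export
karger_signals <- function(sub, protocol) {
  if (any(protocol$delta != 0)) {
    stop("use a narrow-pulse protocol (build_protocol(..., narrow_pulse = TRUE))",
         call. = FALSE)
  }
  iso <- all(vapply(sub$pools, function(p) p$D_delta == 0, logical(1)))
  if (iso) {
    # isotropic pools: the signal depends only on (b1, b2, Delta, tm)
    key <- protocol %>%
      dplyr::distinct(.data$b1, .data$b2, .data$Delta, .data$tm) %>%
      dplyr::mutate(signal = purrr::pmap_dbl(
        list(.data$b1, .data$b2, .data$Delta, .data$tm),
        function(b1, b2, Delta, tm) {
          karger_signal(sub, dde_block(b1, b2, theta = 90, delta = 0,
                                       Delta = Delta, tm = tm))
        }
      ))
    dplyr::left_join(protocol, key, by = c("b1", "b2", "Delta", "tm"))
  } else {
    protocol %>%
      dplyr::mutate(signal = purrr::pmap_dbl(
        list(.data$b1, .data$b2, .data$Delta, .data$tm,
             .data$d1x, .data$d1y, .data$d1z,
             .data$d2x, .data$d2y, .data$d2z),
        function(b1, b2, Delta, tm, x1, y1, z1, x2, y2, z2) {
          karger_signal(sub, dde_block(
            b1, b2, delta = 0, Delta = Delta, tm = tm,
            dir1 = c(x1, y1, z1),
            dir2 = if (b2 > 0) c(x2, y2, z2) else NULL
          ))
        }
      ))
  }
}
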