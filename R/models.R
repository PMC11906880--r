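#' CTI log-signal representation
#'
#' Correlation tensor imaging expresses the powder-averaged DDE log-signal
#' through three kurtosis components:
#' \deqn{\ln E = -b\bar D + \tfrac16 b^2 \bar D^2 (K_I + b_\Delta^2 K_A +
#' b_\mu^2 K_\mu).}
#'
#' @param D mean diffusivity (um^2/ms).
#' @param K_I,K_A,K_mu isotropic, anisotropic and microscopic kurtosis.
#' @param b total b-value(s) (ms/um^2).
#' @param b_shape encoding-shape metric \eqn{b_\Delta^2}.
#' @param b_mu microscopic-kurtosis sensitivity \eqn{b_\mu^2}.
#' @return log-signal(s) ln E.
#' @examples
#' # SDE minus parallel DDE at equal b isolates K_mu / 12 (times b^2 D^2 / 2)
#' cti_signal(1, .2, .3, .4, b = 2.5, b_shape = 1, b_mu = 1) -
#'   cti_signal(1, .2, .3, .4, b = 2.5, b_shape = 1, b_mu = 0.5)
#' @export
cti_signal <- function(D, K_I, K_A, K_mu, b, b_shape, b_mu) {
  stopifnot(D > 0, all(b >= 0))
  -b * D + (1 / 6) * b^2 * D^2 * (K_I + b_shape * K_A + b_mu * K_mu)
}

#' CTI log-signal in the raw (b1, b2, theta) parameterisation
#'
#' Equivalent to [cti_signal()] with the shape metrics expanded:
#' \deqn{\ln E = -(b_1+b_2)\bar D + \tfrac16 (b_1^2+b_2^2)\bar D^2 K_T +
#' \tfrac12 b_1 b_2 \cos^2\theta \bar D^2 K_A +
#' \tfrac16 b_1 b_2 \bar D^2 (2 K_I - K_A),} with
#' \eqn{K_T = K_I + K_A + K_\mu}.
#'
#' @inheritParams cti_signal
#' @param b1,b2 block b-values (ms/um^2).
#' @param theta inter-pair angle (degrees).
#' @export
cti_signal_raw <- function(D, K_I, K_A, K_mu, b1, b2, theta) {
  K_T <- K_I + K_A + K_mu
  c2 <- cos(theta * pi / 180)^2
  -(b1 + b2) * D + (1 / 6) * (b1^2 + b2^2) * D^2 * K_T +
    0.5 * b1 * b2 * c2 * D^2 * K_A +
    (1 / 6) * b1 * b2 * D^2 * (2 * K_I - K_A)
}

#' One-dimensional multi-Gaussian exchange (1D-MGE) log-signal
#'
#' \deqn{\ln E = -b\bar D + \tfrac16 b^2 \bar D^2 K_T\, h(k),} where h(k) is
#' the waveform's exchange weight. Assumes negligible intra-compartmental
#' kurtosis and isotropic (or powder-equivalent) diffusion.
#'
#' @inheritParams cti_signal
#' @param K_T total kurtosis.
#' @param h exchange weight(s) of the acquisition, in (0, 1].
#' @export
mge1d_signal <- function(D, K_T, b, h) {
  stopifnot(D > 0, all(b >= 0), all(h > 0), all(h <= 1 + 1e-9))
  -b * D + (1 / 6) * b^2 * D^2 * K_T * h
}

#' Anisotropy-aware multi-Gaussian exchange (MGE) log-signal
#'
#' \deqn{\ln E = -bD + \tfrac16 b^2 h(k) D^2 [K_I^0 + h_\Delta^2(k) K_A^0] +
#' \tfrac16 b^2 D^2 [K_I^\infty + b_\Delta^2 K_A^\infty].}
#' The 0-superscripted terms decay with exchange (weighted by the isotropic
#' and anisotropic projections of the exchange-sensitised tensor); the
#' infinity terms persist (non-exchanging ensembles, residual anisotropy).
#' At k = 0 the representation is degenerate: h = 1 and
#' \eqn{h_\Delta^2 = b_\Delta^2} make the 0 and infinity terms
#' indistinguishable.
#'
#' @inheritParams cti_signal
#' @param K_I0,K_A0 exchanging isotropic/anisotropic kurtosis.
#' @param K_Iinf,K_Ainf persistent long-time kurtosis.
#' @param h,h_shape exchange-weight projections h(k) and
#'   \eqn{h_\Delta^2(k)} for each acquisition.
#' @export
mge_signal <- function(D, K_I0, K_A0, K_Iinf, K_Ainf, b, b_shape, h, h_shape) {
  stopifnot(D > 0, all(b >= 0))
  -b * D + (1 / 6) * b^2 * h * D^2 * (K_I0 + h_shape * K_A0) +
    (1 / 6) * b^2 * D^2 * (K_Iinf + b_shape * K_Ainf)
}

#' tMGE log-signal: MGE with transient kurtosis
#'
#' Adds an exchange-independent transient kurtosis \eqn{K_\varepsilon},
#' weighted by \eqn{b_\varepsilon^2 \equiv b_\mu^2}, to the persistent
#' bracket of [mge_signal()]:
#' \deqn{\ln E = -bD + \tfrac16 b^2 D^2 h [K_I^0 + h_\Delta^2 K_A^0] +
#' \tfrac16 b^2 D^2 [K_I^\infty + b_\Delta^2 K_A^\infty +
#' b_\varepsilon^2 K_\varepsilon].}
#' Transient kurtosis reaches its long-mixing-time value already at short
#' mixing times, so only exchange produces a tm-dependence; this is what lets
#' DDE at multiple mixing times disentangle the two.
#'
#' @inheritParams mge_signal
#' @param K_eps transient kurtosis \eqn{K_\varepsilon}.
#' @param b_mu \eqn{b_\varepsilon^2} of the acquisition (1 SDE, 1/2 DDE).
#' @export
tmge_signal <- function(D, K_I0, K_A0, K_Iinf, K_Ainf, K_eps,
                        b, b_shape, b_mu, h, h_shape) {
  mge_signal(D, K_I0, K_A0, K_Iinf, K_Ainf, b, b_shape, h, h_shape) +
    (1 / 6) * b^2 * D^2 * b_mu * K_eps
}

#' Microscopic kurtosis predicted from exchange in a multi-Gaussian system
#'
#' What CTI measures when the SDE-vs-parallel-DDE contrast is generated by
#' exchange alone:
#' \deqn{K_\mu = 2 K_T [h_{SDE}(k,\Delta) - h_{DDE}(k,\Delta,t_m)].}
#' Companions: `method = "linearised"` gives the small-kDelta, small-k tm
#' expansion \eqn{K_\mu = K_T (\tfrac23 \Delta + t_m) k};
#' `method = "long_tm"` the long-mixing-time limit
#' \eqn{K_\mu = K_T\, h_{SDE}(k,\Delta)}; and `method = "long_tm_lin"` its
#' small-kDelta form \eqn{K_T (1 - k\Delta/3)}.
#'
#' @param K_T total kurtosis of the exchanging system.
#' @param k exchange rate(s) (1/ms).
#' @param Delta pulse spacing (ms).
#' @param tm mixing time (ms); ignored by the long-tm variants.
#' @param method one of "exact", "linearised", "long_tm", "long_tm_lin".
#' @return K_mu value(s).
#' @export
kmu_from_exchange <- function(K_T, k, Delta, tm = NULL,
                              method = c("exact", "linearised", "long_tm",
                                         "long_tm_lin")) {
  method <- match.arg(method)
  stopifnot(all(k >= 0))
  switch(method,
    exact = {
      stopifnot(!is.null(tm))
      2 * K_T * (h_sde(k, Delta) - h_dde(k, Delta, tm))
    },
    linearised = {
      stopifnot(!is.null(tm))
      K_T * (2 / 3 * Delta + tm) * k
    },
    long_tm = K_T * h_sde(k, Delta),
    long_tm_lin = K_T * (1 - k * Delta / 3)
  )
}

#' Kurtosis ladder: how tMGE separates transient kurtosis from exchange
#'
#' For the isotropic case (no anisotropic terms), the observable kurtoses are
#' \deqn{K_{SDE} = K_I^0 h_{SDE} + K_I^\infty + K_\varepsilon,}
#' \deqn{K_{DDE}(t_m) = K_I^0 h_{DDE}(t_m) + K_I^\infty +
#' \tfrac12 K_\varepsilon,}
#' and the SDE kurtosis predicted from DDE alone (treating
#' \eqn{K_I^\infty + K_\varepsilon/2} as one dummy offset) is
#' \deqn{K_{SDE}^{pred} = K_I^0 h_{SDE} + (K_I^\infty + \tfrac12
#' K_\varepsilon).}
#' The deviation \eqn{K_{SDE} - K_{SDE}^{pred} = K_\varepsilon/2} exposes the
#' transient kurtosis, and the CTI-style contrast decomposes as
#' \eqn{K_\mu = K_I^0 h_{SDE} + K_\varepsilon}.
#'
#' @param K_I0,K_Iinf,K_eps isotropic model parameters.
#' @param k exchange rate (1/ms).
#' @param Delta pulse spacing (ms).
#' @param tm_list mixing times (ms) for the DDE rungs.
#' @return tibble of class `ddex_ladder` with one row per mixing time and
#'   attributes `K_SDE`, `K_SDE_pred`, `K_eps_extracted`, `K_mu_decomposed`.
#' @export
kurtosis_ladder <- function(K_I0, K_Iinf, K_eps, k, Delta, tm_list) {
  hs <- h_sde(k, Delta)
  K_SDE <- K_I0 * hs + K_Iinf + K_eps
  K_DDE <- K_I0 * h_dde(k, Delta, tm_list) + K_Iinf + 0.5 * K_eps
  K_SDE_pred <- K_I0 * hs + (K_Iinf + 0.5 * K_eps)
  out <- tibble::tibble(tm = tm_list, K_DDE = K_DDE)
  attr(out, "K_SDE") <- K_SDE
  attr(out, "K_SDE_pred") <- K_SDE_pred
  attr(out, "K_eps_extracted") <- 2 * (K_SDE - K_SDE_pred)
  attr(out, "K_mu_decomposed") <- K_I0 * hs + K_eps
  class(out) <- c("ddex_ladder", class(out))
  out
}

#' @export
print.ddex_ladder <- function(x, ...) {
  cat(sprintf(
    "<kurtosis ladder> K_SDE = %.4f, K_SDE_pred = %.4f, extracted K_eps = %.4f, K_mu = %.4f\n",
    attr(x, "K_SDE"), attr(x, "K_SDE_pred"),
    attr(x, "K_eps_extracted"), attr(x, "K_mu_decomposed")
  ))
  NextMethod()
}
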