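#' Plot exchange-weighting functions of SDE and DDE
#'
#' h(k) for narrow-pulse SDE and DDE over a rate grid, for one or more
#' mixing times.
#'
#' @param Delta pulse spacing (ms).
#' @param tm mixing times (ms).
#' @param k_per_s rate grid (1/s).
#' @return a ggplot.
#' @export
plot_exchange_weights <- function(Delta = 12, tm = c(1, 12, 50, 300),
                                  k_per_s = seq(0, 300, by = 2)) {
  k <- k_per_s / ms_per_s
  df <- dplyr::bind_rows(
    tibble::tibble(k_per_s = k_per_s, h = h_sde(k, Delta),
                   curve = "SDE"),
    purrr::map_dfr(tm, function(t) {
      tibble::tibble(k_per_s = k_per_s, h = h_dde(k, Delta, t),
                     curve = sprintf("DDE tm = %g ms", t))
    })
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$k_per_s, .data$h,
                                   colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "exchange rate k (1/s)", y = "h(k)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot exchange-driven microscopic kurtosis versus exchange rate
#'
#' The finite-mixing-time curves rise to a mixing-time-dependent peak and
#' then fall; the long-mixing-time envelope decreases monotonically.
#'
#' @param K_T total kurtosis.
#' @param Delta pulse spacing (ms).
#' @param tm mixing times (ms).
#' @param k_per_s rate grid (1/s).
#' @return a ggplot.
#' @export
plot_kmu_theory <- function(K_T = 1, Delta = 12, tm = c(5, 12, 25, 50, 100),
                            k_per_s = seq(0, 300, by = 2)) {
  k <- k_per_s / ms_per_s
  df <- purrr::map_dfr(tm, function(t) {
    tibble::tibble(k_per_s = k_per_s,
                   K_mu = kmu_from_exchange(K_T, k, Delta, t),
                   curve = sprintf("tm = %g ms", t))
  })
  env <- tibble::tibble(
    k_per_s = k_per_s,
    K_mu = kmu_from_exchange(K_T, k, Delta, method = "long_tm"),
    curve = "tm -> Inf"
  )
  ggplot2::ggplot(dplyr::bind_rows(df, env),
                  ggplot2::aes(.data$k_per_s, .data$K_mu,
                               colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "exchange rate k (1/s)",
                  y = expression(K[mu]), colour = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_model plot fitted versus observed powder signals.
#' @param object a `ddex_fit`.
#' @param ... unused.
#' @method autoplot ddex_fit
#' @export
autoplot.ddex_fit <- function(object, ...) {
  df <- dplyr::mutate(object$data, fitted = object$fitted)
  ggplot2::ggplot(df, ggplot2::aes(.data$b)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$signal,
                                     colour = factor(.data$tm),
                                     shape = .data$set_id)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted,
                                    colour = factor(.data$tm),
                                    group = interaction(.data$set_id, .data$tm)),
                       linewidth = 0.3) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "b (ms/um^2)", y = "powder signal",
                  colour = "tm (ms)", shape = NULL,
                  title = sprintf("%s fit", object$model)) +
    ggplot2::theme_minimal()
}

#' @describeIn recovery_study plot estimate distributions against truth.
#' @param object a `ddex_recovery`.
#' @param ... unused.
#' @method autoplot ddex_recovery
#' @export
autoplot.ddex_recovery <- function(object, ...) {
  df <- dplyr::filter(object, !is.na(.data$true))
  ggplot2::ggplot(df, ggplot2::aes(.data$term, .data$estimate)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::geom_point(ggplot2::aes(y = .data$true), colour = "red",
                        shape = 4, size = 3) +
    ggplot2::labs(x = NULL, y = "estimate",
                  title = "parameter recovery (red cross = truth)") +
    ggplot2::theme_minimal()
}

#' Plot tMGE design-coefficient collinearity diagnostics
#'
#' @param ds result of [design_sensitivity()].
#' @return a ggplot of the isotropic/anisotropic column correlations and h's
#'   mixing-time span versus exchange rate.
#' @export
plot_design_sensitivity <- function(ds) {
  df <- ds$diagnostics %>%
    tidyr::pivot_longer(c("cor_iso", "cor_aniso", "tm_span_h"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$k_per_s, .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "exchange rate k (1/s)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
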