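test_that("CTI on non-exchanging Gaussian pools returns zero microscopic kurtosis", {
  p <- proto1_small()
  sig <- dplyr::mutate(p, signal = 0.5 * exp(-b * 2) + 0.5 * exp(-b * 0.5))
  fit <- fit_model(powder_average(sig), "cti", seed = 1)
  expect_lt(abs(fit$estimates[["K_mu"]]), 1e-6)
  expect_equal(fit$estimates[["K_A"]], 0, tolerance = 1e-6)
})

test_that("each representation recovers its own noiseless parameters", {
  p <- proto3_small(narrow_pulse = TRUE, tm_max = 100)
  truth <- list(D = 1, K_I0 = 1, K_A0 = 1, K_Iinf = 0.5, K_Ainf = 0.5,
                K_eps = 0.5, k = 0.02)
  rot <- tmge_rotation_signals(p, truth)
  fit <- fit_model(powder_average(rot), "tmge", seed = 2)
  expect_rel_equal(fit$estimates[names(truth)], unlist(truth), 1e-4)

  # MGE on data from its own forward model
  sh <- protocol_shells(p)
  wts <- make_weight_eval(sh)(0.03)
  ln <- mge_signal(1.2, 0.8, 0.4, 0.3, 0.2, sh$b, sh$b_shape, wts$h,
                   wts$h_shape)
  rot2 <- dplyr::left_join(
    p, dplyr::mutate(sh, signal = exp(ln))[, c("shell", "signal")], by = "shell"
  )
  fit2 <- fit_model(powder_average(rot2), "mge", seed = 3)
  expect_rel_equal(
    fit2$estimates[c("D", "K_I0", "K_A0", "K_Iinf", "K_Ainf", "k")],
    c(1.2, 0.8, 0.4, 0.3, 0.2, 0.03), 1e-4
  )

  # 1D-MGE on its own forward model (theta = 0 shells)
  wts1 <- make_weight_eval(sh)(0.05)
  ln1 <- mge1d_signal(1.1, 0.9, sh$b, wts1$h)
  rot3 <- dplyr::left_join(
    p, dplyr::mutate(sh, signal = exp(ln1))[, c("shell", "signal")],
    by = "shell"
  )
  fit3 <- fit_model(powder_average(rot3), "mge1d", seed = 4)
  expect_rel_equal(fit3$estimates[c("D", "K_T", "k")], c(1.1, 0.9, 0.05), 1e-4)
})

test_that("fits are deterministic under a fixed seed and invariant to row order", {
  p <- proto3_small(narrow_pulse = TRUE, tm_max = 50)
  truth <- list(D = 1, K_I0 = 1, K_A0 = 0.5, K_Iinf = 0.3, K_Ainf = 0.2,
                K_eps = 0.4, k = 0.03)
  pt <- powder_average(tmge_rotation_signals(p, truth))
  pt$signal <- add_rician_noise(pt$signal, 500, seed = 9)
  f1 <- fit_model(pt, "tmge", seed = 7)
  f2 <- fit_model(pt, "tmge", seed = 7)
  expect_identical(f1$estimates, f2$estimates)
  set.seed(1)
  f3 <- fit_model(pt[sample(nrow(pt)), ], "tmge", seed = 7)
  expect_equal(f1$estimates, f3$estimates, tolerance = 1e-12)
})

test_that("1D-MGE uses only the theta = 0 subset", {
  p <- proto3_small(narrow_pulse = TRUE, tm_max = 50)
  sub <- iso_iso(0.05)
  pt <- powder_average(karger_signals(sub, p))
  f_all <- fit_model(pt, "mge1d", seed = 1)
  f_par <- fit_model(pt[pt$theta == 0 | pt$b2 == 0, ], "mge1d", seed = 1)
  expect_equal(f_all$estimates, f_par$estimates)
})

test_that("tMGE refuses a single mixing time", {
  p <- proto1_small(narrow_pulse = TRUE)
  sig <- dplyr::mutate(p, signal = exp(-b))
  expect_error(fit_model(powder_average(sig), "tmge", seed = 1),
               "two distinct")
})

test_that("design sensitivity reports the k = 0 degeneracy and its resolution", {
  sh <- protocol_shells(proto3_small(narrow_pulse = TRUE, tm_max = 100))
  ds <- design_sensitivity(sh, k_per_s = c(0, 20, 200))
  dg <- ds$diagnostics
  # zero exchange: exchanging and persistent columns exactly collinear
  expect_gt(dg$cor_iso[dg$k_per_s == 0], 1 - 1e-12)
  expect_gt(dg$cor_aniso[dg$k_per_s == 0], 1 - 1e-12)
  expect_gt(dg$condition[dg$k_per_s == 0], 1e8)
  # intermediate exchange: full column rank, usable conditioning
  expect_lt(dg$cor_iso[dg$k_per_s == 20], 0.9999)
  expect_lt(dg$condition[dg$k_per_s == 20], 1e4)
  # very fast exchange: mixing-time dependence of h collapses
  expect_lt(dg$tm_span_h[dg$k_per_s == 200],
            dg$tm_span_h[dg$k_per_s == 20] / 5)
  expect_error(design_sensitivity(sh[sh$tm == 12 | sh$b2 == 0, ]), "multiple")
})

test_that("clinical timings lose the mixing-time dependence at lower rates than preclinical", {
  sh3 <- protocol_shells(proto3_small(narrow_pulse = TRUE, tm_max = 100))
  sh4 <- protocol_shells(build_protocol(4, n_dirs = 2, narrow_pulse = TRUE))
  d3 <- design_sensitivity(sh3, k_per_s = 100)$diagnostics
  d4 <- design_sensitivity(sh4, k_per_s = 100)$diagnostics
  expect_lt(d4$tm_span_h / max(d3$tm_span_h, 1e-12), 0.7)
})

test_that("noiseless recovery is unbiased inside the bounds", {
  p <- proto3_small(narrow_pulse = TRUE, tm_max = 100)
  truth <- list(D = 1, K_I0 = 1, K_A0 = 1, K_Iinf = 0.5, K_Ainf = 0.5,
                K_eps = 0.5, k = 0.02)
  rec <- recovery_study(truth, p, model = "tmge", snr = Inf, n_reps = 1,
                        seed = 1)
  s <- attr(rec, "summary")
  expect_lt(max(abs(s$bias / unlist(truth)[s$term])), 1e-3)
})

test_that("tidy and glance expose the fit in broom form", {
  p <- proto1_small()
  sig <- dplyr::mutate(p, signal = 0.5 * exp(-b * 2) + 0.5 * exp(-b * 0.5))
  fit <- fit_model(powder_average(sig), "cti", seed = 1)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate"))
  expect_setequal(td$term, c("D", "K_I", "K_A", "K_mu"))
  gl <- glance(fit)
  expect_equal(gl$model, "cti")
  expect_true(gl$converged)
  expect_s3_class(autoplot(fit), "ggplot")
})
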