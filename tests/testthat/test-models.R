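test_that("CTI contrasts isolate the anisotropic and microscopic kurtosis", {
  D <- 1.1; KI <- 0.4; KA <- 0.6; Km <- 0.3; b <- 2.5
  expect_equal(cti_signal(D, KI, KA, Km, 0, 1, 1), 0)
  par_orth <- cti_signal(D, KI, KA, Km, b, 1, 0.5) -
    cti_signal(D, KI, KA, Km, b, 0.25, 0.5)
  expect_equal(par_orth, b^2 * D^2 * KA / 8)
  sde_par <- cti_signal(D, KI, KA, Km, b, 1, 1) -
    cti_signal(D, KI, KA, Km, b, 1, 0.5)
  expect_equal(sde_par, b^2 * D^2 * Km / 12)
})

test_that("raw (b1, b2, theta) and shape-metric CTI parameterisations coincide", {
  set.seed(5)
  for (i in 1:10) {
    D <- runif(1, 0.3, 2); KI <- runif(1, -0.5, 1); KA <- runif(1, 0, 1)
    Km <- runif(1, -0.5, 1)
    b1 <- runif(1, 0.1, 2); b2 <- runif(1, 0, 2); th <- runif(1, 0, 180)
    expect_equal(
      cti_signal_raw(D, KI, KA, Km, b1, b2, th),
      cti_signal(D, KI, KA, Km, b1 + b2, b_shape_closed(b1, b2, th),
                 b_mu_closed(b1, b2)),
      tolerance = 1e-12
    )
  }
})

test_that("1D-MGE reduces to the plain cumulant form at k = 0 and is purely mono-exponential at K_T = 0", {
  b <- c(0.5, 1, 2)
  expect_equal(mge1d_signal(1.2, 0.8, b, 1),
               -b * 1.2 + b^2 * 1.2^2 * 0.8 / 6)
  expect_equal(mge1d_signal(1.2, 0, b, 0.4), -b * 1.2)
  # SDE-DDE contrast carries (h_SDE - h_DDE)
  k <- 0.04
  hs <- h_sde(k, 12); hd <- h_dde(k, 12, 12)
  expect_equal(mge1d_signal(1, 1, 2, hs) - mge1d_signal(1, 1, 2, hd),
               (1 / 6) * 4 * 1 * (hs - hd))
})

test_that("MGE collapses correctly in its degenerate and persistent-only limits", {
  b <- c(0.5, 1.5); bs <- c(1, 0.25)
  # k = 0: h = 1, h_shape = b_shape -> sums of 0 and inf terms, no K_mu
  expect_equal(
    mge_signal(1, 0.7, 0.3, 0.2, 0.1, b, bs, h = 1, h_shape = bs),
    cti_signal(1, 0.7 + 0.2, 0.3 + 0.1, 0, b, bs, b_mu = 0.5)
  )
  # no exchanging terms -> no dependence on (h, h_shape), i.e. no tm dependence
  s1 <- mge_signal(1, 0, 0, 0.2, 0.1, b, bs, h = 0.9, h_shape = 0.5)
  s2 <- mge_signal(1, 0, 0, 0.2, 0.1, b, bs, h = 0.4, h_shape = 0.9)
  expect_equal(s1, s2)
  # b -> 0 slope is exactly -D
  eps <- 1e-6
  sl <- mge_signal(1.3, 1, 1, 0.5, 0.5, eps, 1, 0.95, 0.95) / eps
  expect_equal(sl, -1.3, tolerance = 1e-4)
})

test_that("tMGE reduces to MGE at zero transient kurtosis and decomposes K_mu at k -> 0", {
  b <- c(1, 2); bs <- c(1, 0.25); bm <- c(1, 0.5)
  expect_equal(
    tmge_signal(1, 0.7, 0.3, 0.2, 0.1, 0, b, bs, bm, 0.8, 0.6),
    mge_signal(1, 0.7, 0.3, 0.2, 0.1, b, bs, 0.8, 0.6)
  )
  # K_mu (SDE vs long-tm parallel DDE contrast) -> K_I0 + K_eps as k -> 0
  lad <- kurtosis_ladder(K_I0 = 0.8, K_Iinf = 0.2, K_eps = 0.5, k = 1e-7,
                         Delta = 12, tm_list = c(12, 100))
  expect_equal(attr(lad, "K_mu_decomposed"), 0.8 + 0.5, tolerance = 1e-5)
})

test_that("the kurtosis ladder extracts the transient kurtosis exactly", {
  lad <- kurtosis_ladder(K_I0 = 1, K_Iinf = 0.3, K_eps = 0.5, k = 0.02,
                         Delta = 12, tm_list = c(1, 12, 100))
  expect_equal(attr(lad, "K_eps_extracted"), 0.5, tolerance = 1e-12)
  lad0 <- kurtosis_ladder(1, 0.3, 0, 0.02, 12, c(1, 12))
  expect_equal(attr(lad0, "K_SDE") - attr(lad0, "K_SDE_pred"), 0)
  # Eq-41-style long-tm contrast: K_SDE - K_DDE(inf) = (K_I0 h_SDE + K_eps)/2
  lad_inf <- kurtosis_ladder(1, 0.3, 0.5, 0.02, 12, 1e8)
  expect_equal(attr(lad_inf, "K_SDE") - lad_inf$K_DDE,
               0.5 * (1 * h_sde(0.02, 12) + 0.5), tolerance = 1e-9)
  # ladder values agree with the tMGE forward model evaluated on SDE/DDE weights
  k <- 0.02; b <- 0.3; D <- 1
  ln_sde <- tmge_signal(D, 1, 0, 0.3, 0, 0.5, b, 1, 1, h_sde(k, 12), 1)
  K_sde_fwd <- (ln_sde + b * D) * 6 / (b^2 * D^2)
  expect_equal(K_sde_fwd, attr(lad, "K_SDE"), tolerance = 1e-12)
})

test_that("exchange-driven microscopic kurtosis behaves per its closed forms", {
  expect_equal(kmu_from_exchange(1, 0, 12, 12), 0)
  # linearisation vs exact at k = 0.01/ms: 0.2 vs exact, within 15%
  lin <- kmu_from_exchange(1, 0.01, 12, 12, method = "linearised")
  expect_equal(lin, 0.2)
  ex <- kmu_from_exchange(1, 0.01, 12, 12)
  expect_lt(abs(lin - ex) / lin, 0.15)
  # exact equals its definition through the h functions
  expect_equal(ex, 2 * (h_sde(0.01, 12) - h_dde(0.01, 12, 12)))
  # long-mixing-time limit: K_T h_SDE; at kDelta = 1 this is 2/e
  expect_equal(kmu_from_exchange(1, 1 / 12, 12, method = "long_tm"),
               2 * exp(-1), tolerance = 1e-12)
  # linearisation error shrinks linearly with k (true convergence behaviour)
  rel_err <- function(x) {
    k <- x / 12
    abs(kmu_from_exchange(1, k, 12, 12, method = "linearised") -
          kmu_from_exchange(1, k, 12, 12)) / kmu_from_exchange(1, k, 12, 12)
  }
  expect_lt(rel_err(0.04), 0.05)
  expect_lt(rel_err(0.02), 0.025)
  expect_gt(rel_err(0.08) / rel_err(0.04), 1.8) # ~ linear in k
})

test_that("all forward models are exactly linear in each kurtosis parameter", {
  b <- 1.7; bs <- 0.25; bm <- 0.5; h <- 0.8; hsh <- 0.4; D <- 1.1
  lin_check <- function(f) {
    # f(x): log-signal as a function of one kurtosis parameter
    d1 <- f(1) - f(0)
    d2 <- f(2) - f(1)
    expect_equal(d1, d2, tolerance = 1e-12)
  }
  lin_check(function(x) cti_signal(D, x, 0.3, 0.2, b, bs, bm))
  lin_check(function(x) cti_signal(D, 0.3, x, 0.2, b, bs, bm))
  lin_check(function(x) mge1d_signal(D, x, b, h))
  lin_check(function(x) mge_signal(D, x, 0.2, 0.1, 0.1, b, bs, h, hsh))
  lin_check(function(x) tmge_signal(D, 0.2, 0.2, 0.1, 0.1, x, b, bs, bm, h, hsh))
})
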