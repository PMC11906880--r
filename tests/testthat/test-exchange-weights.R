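test_that("q4 autocorrelation is normalised, positive at zero lag, and triangular for narrow SDE", {
  w <- make_dde_waveform(dde_block(b1 = 2, b2 = 0, delta = 0, Delta = 10))
  q4 <- q4_autocorr(w)
  expect_gt(q4$q4[1], 0)
  expect_equal(h_numeric(w, 0), 1, tolerance = 1e-12) # 2 int q4~ dt = 1
  # boxcar q^2 correlates to an exact triangle q^4 (Delta - t) on [0, Delta]
  qsq <- 2 / 10 # q^2 = b / Delta
  tri <- ifelse(q4$lag <= 10, qsq^2 * (10 - q4$lag), 0)
  expect_equal(q4$q4, tri, tolerance = 1e-12)
})

test_that("closed-form SDE weight matches its limits and values", {
  expect_equal(h_sde(0, 12), 1)
  expect_equal(h_sde(1e-12, 12), 1, tolerance = 1e-9)
  expect_equal(h_sde(1 / 12, 12), 2 * exp(-1), tolerance = 1e-12)
  kbig <- 400 / 12
  expect_equal(h_sde(kbig, 12), 2 / (kbig * 12), tolerance = 1e-2)
  expect_error(h_sde(0.1, -1), "Delta")
  expect_error(h_sde(-0.1, 12), "k")
})

test_that("closed-form DDE weight has the right limits and long-tm behaviour", {
  expect_equal(h_dde(0, 12, 12), 1)
  expect_equal(h_dde(1e-12, 12, 12), 1, tolerance = 1e-9)
  expect_equal(h_dde(1 / 12, 12, 1e7), h_sde(1 / 12, 12) / 2, tolerance = 1e-12)
  # frozen value cross-checked against the numerical path below
  expect_equal(h_dde(0.05, 12, 12), 0.5685352, tolerance = 1e-6)
})

test_that("numerical h agrees with closed forms over k in [0, 500] 1/s (narrow pulses)", {
  ks <- seq(0, 0.5, length.out = 21)
  ws <- make_dde_waveform(dde_block(b1 = 2.5, b2 = 0, delta = 0, Delta = 12))
  expect_lt(max(abs(h_numeric(ws, ks) - h_sde(ks, 12))), 1e-4)
  for (tm in c(1, 12, 100)) {
    wd <- make_dde_waveform(dde_block(b1 = 1.25, b2 = 1.25, theta = 0,
                                      delta = 0, Delta = 12, tm = tm))
    expect_lt(max(abs(h_numeric(wd, ks) - h_dde(ks, 12, tm))), 1e-4)
  }
})

test_that("short finite pulses converge to the narrow-pulse closed forms", {
  ks <- c(0, 0.05, 0.2, 0.5)
  w <- make_dde_waveform(dde_block(b1 = 1, b2 = 1, theta = 0, delta = 0.01,
                                   Delta = 12, tm = 12), dt = 0.0025)
  expect_lt(max(abs(h_numeric(w, ks) - h_dde(ks, 12, 12))), 1e-4)
})

test_that("h decays monotonically to zero at large rates", {
  w <- make_dde_waveform(dde_block(b1 = 1, b2 = 1, theta = 0, delta = 0,
                                   Delta = 12, tm = 12))
  ks <- seq(0, 2, length.out = 40)
  h <- h_numeric(w, ks)
  expect_true(all(diff(h) < 0))
  expect_lt(h[40], 0.05)
})

test_that("the exchange-sensitised tensor reduces to the squared b-tensor at k = 0", {
  for (narrow in c(TRUE, FALSE)) {
    w <- make_dde_waveform(dde_block(b1 = 1.5, b2 = 1, theta = 60,
                                     delta = if (narrow) 0 else 3.5,
                                     Delta = 12, tm = 12))
    H0 <- H_tensor(w, 0)
    Bv <- ddex:::voigt6(b_tensor(w)$B)
    expect_equal(unclass(H0), outer(Bv, Bv), tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("SDE tensor weight is one-dimensional and equals b^2 h_sde", {
  w <- make_dde_waveform(dde_block(b1 = 2, b2 = 0, delta = 0, Delta = 12,
                                   dir1 = c(1, 0, 0)))
  for (k in c(0, 0.1)) {
    H <- H_tensor(w, k)
    expect_equal(H[1, 1], 4 * h_sde(k, 12), tolerance = 1e-4)
    expect_lt(max(abs(H[-1, -1])), 1e-10)
    pr <- project_h(H)
    expect_equal(pr$h_shape, 1, tolerance = 1e-9) # SDE: pure anisotropic square
  }
})

test_that("projection normalisation pins hold for every protocol-1 shell", {
  p <- build_protocol(1, n_dirs = 2)
  shells <- p[!duplicated(p$set_id), ]
  for (w in protocol_waveforms(shells, dt = 0.02)) {
    pr <- project_h(H_tensor(w, 0))
    bt <- b_tensor(w)
    expect_equal(pr$h, 1, tolerance = 1e-9)
    expect_equal(pr$h_shape, bt$b_shape, tolerance = 1e-9)
  }
})

test_that("tensor and scalar exchange-weight paths agree for parallel DDE", {
  w <- make_dde_waveform(dde_block(b1 = 1.25, b2 = 1.25, theta = 0, delta = 0,
                                   Delta = 12, tm = 12))
  for (k in c(0, 0.02, 0.2)) {
    expect_equal(project_h(H_tensor(w, k))$h, h_numeric(w, k),
                 tolerance = 1e-9)
  }
})

test_that("orthogonal DDE: isotropic projection converges towards the anisotropic one", {
  # h_shape rises from b_shape = 1/4 towards 1 as exchange suppresses the
  # cross-block (differently oriented) contribution
  sh <- vapply(c(0, 0.05, 0.2, 0.5, 2), function(k) {
    h_pair_closed(k, 12, 12, 1.25, 1.25, 90)$h_shape
  }, numeric(1))
  expect_equal(sh[1], 0.25, tolerance = 1e-12)
  expect_true(all(diff(sh) > 0))
  expect_gt(sh[5], 0.9)
})

test_that("closed pair weights equal the tensor projections for general pairs", {
  for (th in c(0, 45, 90)) {
    w <- make_dde_waveform(dde_block(b1 = 1.5, b2 = 0.75, theta = th,
                                     delta = 0, Delta = 10, tm = 20))
    for (k in c(0.01, 0.1)) {
      pr <- project_h(H_tensor(w, k))
      pc <- h_pair_closed(k, 10, 20, 1.5, 0.75, th)
      expect_equal(pr$h, pc$h, tolerance = 1e-5)
      expect_equal(pr$h_shape, pc$h_shape, tolerance = 1e-5)
    }
  }
})

test_that("Voigt storage round-trips through the full fourth-order array", {
  set.seed(2)
  M <- matrix(rnorm(36), 6)
  H <- M + t(M)
  expect_equal(array_to_h4(h4_to_array(H)), H, tolerance = 1e-12)
  # full array has pair-exchange symmetry
  A <- h4_to_array(H)
  expect_equal(A[1, 2, 3, 3], A[2, 1, 3, 3])
  expect_equal(A, aperm(A, c(3, 4, 1, 2)))
})

test_that("exchange-weight tables export one row per waveform and rate", {
  ws <- protocol_waveforms(build_protocol(2, n_dirs = 1))
  tab <- exchange_weight_table(ws, k_per_s = c(0, 100))
  expect_equal(nrow(tab), 4L)
  expect_named(tab, c("waveform_id", "k_per_s", "h", "h_shape"))
  expect_equal(tab$h[tab$k_per_s == 0], c(1, 1), tolerance = 1e-9)
})
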