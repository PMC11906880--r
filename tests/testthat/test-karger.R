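test_that("non-exchanging pools give an exact bi-exponential", {
  sub <- iso_iso(0)
  for (b in c(0.5, 1.5, 2.5)) {
    s <- karger_signal(sub, dde_block(b, 0, delta = 0, Delta = 12))
    expect_equal(s, 0.5 * exp(-b * 2) + 0.5 * exp(-b * 0.5), tolerance = 1e-12)
  }
})

test_that("fast exchange collapses to a mono-exponential at the mean diffusivity", {
  sub <- iso_iso(50) # 50,000 1/s: far beyond any encoding timescale
  s <- karger_signal(sub, dde_block(1.5, 0, delta = 0, Delta = 12))
  expect_equal(s, exp(-1.5 * 1.25), tolerance = 1e-2)
})

test_that("small-b cumulant expansion of the oracle recovers D and K_T h", {
  sub <- iso_iso(0.05)
  b <- seq(0.04, 0.2, by = 0.04)
  ln <- log(vapply(b, function(bb) {
    karger_signal(sub, dde_block(bb, 0, delta = 0, Delta = 12))
  }, numeric(1)))
  fit <- lm(ln ~ b + I(b^2))
  expect_equal(-coef(fit)[[2]], 1.25, tolerance = 1e-3)
  expect_equal(coef(fit)[[3]] * 6 / 1.25^2, sub$K_T * h_sde(0.05, 12),
               tolerance = 0.02)
})

test_that("the exchange generator preserves equilibrium and detailed balance is enforced", {
  sub <- three_pool_transient_substrate(5)
  f <- sub$fractions
  G <- ddex:::karger_generator(sub$rates)
  expect_equal(as.numeric(G %*% f), rep(0, 3), tolerance = 1e-12)
  expect_equal(as.numeric(ddex:::expm_db(G, f, 37) %*% f), f, tolerance = 1e-9)
  bad <- matrix(c(0, 0.01, 0.5, 0), 2, 2, byrow = TRUE)
  expect_error(
    gaussian_substrate(list(gaussian_pool(1, fraction = 0.5),
                            gaussian_pool(2, fraction = 0.5)), rates = bad),
    "detailed balance"
  )
})

test_that("finite pulses are rejected and anisotropic pools use directional diffusivity", {
  sub <- iso_iso(0.02)
  expect_error(karger_signal(sub, dde_block(1, 0, delta = 3.5, Delta = 12)),
               "narrow")
  stick <- gaussian_substrate(
    list(gaussian_pool(0.5, 1, orientation = c(1, 0, 0), fraction = 1))
  )
  s_par <- karger_signal(stick, dde_block(1, 0, delta = 0, Delta = 12,
                                          dir1 = c(1, 0, 0)))
  s_perp <- karger_signal(stick, dde_block(1, 0, delta = 0, Delta = 12,
                                           dir1 = c(0, 1, 0)))
  expect_equal(s_par, exp(-1.5), tolerance = 1e-12) # axial D = 1.5
  expect_equal(s_perp, 1, tolerance = 1e-12)        # radial D = 0
})

test_that("protocol-level Kaerger signals vectorise consistently", {
  sub <- iso_iso(0.05)
  p <- proto3_small(n_dirs = 2, narrow_pulse = TRUE, tm_max = 12)
  sig <- karger_signals(sub, p)
  expect_equal(nrow(sig), nrow(p))
  row <- sig[sig$set_id == "dde_par" & sig$b == 1 & sig$tm == 12, ][1, ]
  direct <- karger_signal(sub, dde_block(0.5, 0.5, theta = 0, delta = 0,
                                         Delta = 12, tm = 12))
  expect_equal(row$signal, direct, tolerance = 1e-12)
  expect_error(karger_signals(sub, proto3_small(n_dirs = 2)), "narrow")
})
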