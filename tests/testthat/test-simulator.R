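# reduced-scale Monte Carlo checks; acceptance-level runs live in
# test-acceptance.R at the full desk scale

test_that("free Gaussian diffusion attenuates as exp(-bD) and the ADC is unbiased", {
  sub <- gaussian_substrate(list(gaussian_pool(1, fraction = 1)), k = 0)
  p <- proto3_small(n_dirs = 1, narrow_pulse = TRUE, tm_max = 12)
  sde <- p[p$b2 == 0 & p$b >= 0.5, ]
  mc <- simulate_gaussian_exchange(sub, sde, n_particles = 1e5, dt = 0.05,
                                   seed = 2)
  adc <- -coef(lm(log(mc$signal) ~ 0 + mc$b))[[1]]
  expect_equal(adc, 1, tolerance = 5e-3) # 0.5%
  # imaginary channel of balanced waveforms vanishes within noise
  expect_lt(max(abs(mc$signal_imag)), 4 * sqrt(0.5 / 1e5))
})

test_that("Gaussian-exchange walkers reproduce the Kaerger oracle", {
  p <- proto3_small(n_dirs = 1, narrow_pulse = TRUE)
  sel <- p[p$b %in% c(1, 2.5) & (p$b2 == 0 | p$tm %in% c(1, 12, 50)), ]
  for (kps in c(0, 50)) {
    sub <- iso_iso(kps / 1000)
    mc <- simulate_gaussian_exchange(sub, sel, n_particles = 3e4, dt = 0.05,
                                     seed = 10 + kps)
    ka <- karger_signals(sub, sel)
    z <- (mc$signal - ka$signal) / mc$signal_se
    expect_lt(max(abs(z)), 3)
  }
})

test_that("one trajectory set scoring all waveforms matches independent runs", {
  sub <- iso_iso(0.05)
  p <- build_protocol(2, n_dirs = 4, seed = 0, narrow_pulse = TRUE)
  joint <- simulate_gaussian_exchange(sub, p, n_particles = 2e4, dt = 0.05,
                                      seed = 21)
  solo <- simulate_gaussian_exchange(sub, p[p$theta == 0, ],
                                     n_particles = 2e4, dt = 0.05, seed = 22)
  z <- (joint$signal[joint$theta == 0] - solo$signal) /
    sqrt(joint$signal_se[joint$theta == 0]^2 + solo$signal_se^2)
  expect_lt(max(abs(z)), 4)
})

test_that("impermeable spheres confine walkers to the exact uniform-ball statistics", {
  sub <- geometry_substrate("spheres", diameter = 6, packing = 0.5, D0 = 2)
  rho <- function(q, R = 3) 3 * (sin(q * R) - q * R * cos(q * R)) / (q * R)^3
  q <- 0.3; Delta <- 40
  p <- tibble::tibble(
    protocol = 1L, set_id = "sde", b1 = q^2 * Delta, b2 = 0, theta = 0,
    delta = 0, Delta = Delta, tm = 0, rot = 1L, rep = 1L,
    d1x = 1, d1y = 0, d1z = 0, d2x = 1, d2y = 0, d2z = 0,
    b = q^2 * Delta, b_shape = 1, b_mu = 1, shell = "s"
  )
  mc <- simulate_restricted(sub, p, n_particles = 1e4, dt = 2e-3, seed = 3,
                            intra_only = TRUE, record_times = c(20, 40))
  # long-diffusion-time signal -> squared structure factor of the sphere
  expect_equal(mc$signal, rho(q)^2, tolerance = 4 * mc$signal_se / rho(q)^2)
  # per-axis displacement variance saturates at 2 R^2 / 5 = d^2 / 10
  msd <- attr(mc, "msd")
  expect_equal(unlist(msd[msd$t == 40, c("x", "y", "z")]),
               rep(2 * 9 / 5, 3), tolerance = 0.05, ignore_attr = TRUE)
})

test_that("restricted ADC decreases with diffusion time (time dependence present)", {
  sub <- geometry_substrate("spheres", diameter = 6, packing = 0.5, D0 = 2)
  adc <- vapply(c(3, 12), function(Delta) {
    b <- 0.5
    p <- tibble::tibble(
      protocol = 1L, set_id = "sde", b1 = b, b2 = 0, theta = 0, delta = 0,
      Delta = Delta, tm = 0, rot = 1L, rep = 1L,
      d1x = 1, d1y = 0, d1z = 0, d2x = 1, d2y = 0, d2z = 0,
      b = b, b_shape = 1, b_mu = 1, shell = "s"
    )
    mc <- simulate_restricted(sub, p, n_particles = 5e3, dt = 2e-3,
                              seed = 5, intra_only = TRUE)
    -log(mc$signal) / b
  }, numeric(1))
  expect_gt(adc[1], adc[2] * 1.5)
})

test_that("step-size and rate-stability guards trigger", {
  sub <- geometry_substrate("spheres")
  p <- build_protocol(2, n_dirs = 1)
  expect_error(simulate_restricted(sub, p, n_particles = 10, dt = 0.5),
               "step length")
  gsub <- iso_iso(0.3)
  expect_error(simulate_gaussian_exchange(gsub, p, n_particles = 10, dt = 0.1),
               "unstable dt")
})

test_that("label autocorrelation of a two-pool Markov chain yields the summed rate", {
  # pools with identical diffusivity: pure label dynamics, k12 = k21 = 25/s
  sub <- gaussian_substrate(list(gaussian_pool(1, fraction = 0.5),
                                 gaussian_pool(1, fraction = 0.5)), k = 0.05)
  lc <- label_correlation(sub, t_max = 40, n_particles = 2e4, dt = 0.05,
                          seed = 9)
  k <- measure_exchange_rate(lc)
  expect_equal(as.numeric(k), 50, tolerance = 0.08)
})

test_that("the three-pool substrate has the study fractions and a two-scale decay", {
  sub <- three_pool_transient_substrate(5)
  expect_equal(sub$fractions, c(0.25, 0.25, 0.5))
  expect_equal(vapply(sub$pools, `[[`, numeric(1), "D_iso"), c(0.1, 0.5, 1))
  # matrix-exponential oracle for the label autocorrelation
  G <- ddex:::karger_generator(sub$rates)
  f <- sub$fractions
  C <- function(t) {
    P <- ddex:::expm_db(G, f, t)
    sum(f * diag(P))
  }
  # tail (fast pair fully equilibrated): clean mono-exponential at the slow
  # summed rate
  tt <- seq(50, 600, by = 25)
  lc <- tibble::tibble(t = tt, match = vapply(tt, C, numeric(1)))
  k_tail <- measure_exchange_rate(lc, C_inf = sum(f^2))
  expect_equal(as.numeric(k_tail), 5, tolerance = 0.2)
  # including early times exposes the fast second scale: flagged
  tt2 <- c(seq(1, 20, by = 2), seq(50, 600, by = 50))
  lc2 <- tibble::tibble(t = tt2, match = vapply(tt2, C, numeric(1)))
  expect_warning(measure_exchange_rate(lc2, C_inf = sum(f^2)),
                 "mono-exponential")
})

test_that("permeability calibration is monotone and reaches its target", {
  sub <- geometry_substrate("spheres", permeability = 0, D0 = 2)
  lc0 <- label_correlation(sub, t_max = 20, n_particles = 3e3, dt = 5e-3,
                           seed = 2)
  expect_gt(min(lc0$match), 0.995) # impermeable: labels frozen
  expect_identical(as.numeric(calibrate_permeability(sub, 0)), 0)
  k1 <- local({
    sub$permeability <- 0.01
    lc <- label_correlation(sub, t_max = 30, n_particles = 5e3, dt = 5e-3,
                            seed = 3)
    as.numeric(measure_exchange_rate(lc))
  })
  k2 <- local({
    sub$permeability <- 0.05
    lc <- label_correlation(sub, t_max = 30, n_particles = 5e3, dt = 5e-3,
                            seed = 3)
    as.numeric(measure_exchange_rate(lc))
  })
  expect_gt(k2, k1) # measured rate nondecreasing in permeability
  kap <- calibrate_permeability(sub, 50, seed = 11, n_particles = 5e3,
                                dt = 5e-3, t_max = 30)
  expect_equal(attr(kap, "k_measured_per_s"), 50, tolerance = 0.05)
  expect_error(calibrate_permeability(sub, 1e6, n_particles = 2e3,
                                      dt = 5e-3, t_max = 10, kappa_max = 0.02),
               "unattainable")
})
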