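test_that("SDE waveform has single-axis b-tensor with the requested b-value", {
  w <- make_dde_waveform(dde_block(b1 = 2.5, b2 = 0, delta = 3.5, Delta = 12,
                                   dir1 = c(1, 0, 0)))
  bt <- b_tensor(w)
  expect_equal(bt$b, 2.5, tolerance = 1e-6)
  expect_equal(bt$b_shape, 1, tolerance = 1e-9)
  expect_equal(bt$B / bt$b, diag(c(1, 0, 0)), tolerance = 1e-9)
})

test_that("parallel DDE at the same total b reproduces the SDE b-tensor", {
  ws <- make_dde_waveform(dde_block(b1 = 2.5, delta = 3.5, Delta = 12,
                                    dir1 = c(0, 1, 0)))
  wp <- make_dde_waveform(dde_block(b1 = 1.25, b2 = 1.25, theta = 0,
                                    delta = 3.5, Delta = 12,
                                    dir1 = c(0, 1, 0)))
  expect_equal(b_tensor(wp)$B, b_tensor(ws)$B, tolerance = 1e-6)
  expect_equal(b_tensor(wp)$b_mu, 0.5)
})

test_that("orthogonal equal-b DDE has b-tensor shape 1/4", {
  w <- make_dde_waveform(dde_block(b1 = 1.25, b2 = 1.25, theta = 90,
                                   delta = 3.5, Delta = 12))
  expect_equal(b_tensor(w)$b_shape, 0.25, tolerance = 1e-9)
})

test_that("closed-form shape metrics match their defining expressions", {
  expect_equal(b_shape_closed(1.25, 1.25, 0), 1)
  expect_equal(b_shape_closed(1.25, 1.25, 90), 0.25)
  expect_equal(b_shape_closed(1, 3, 90), (1 + 9 - 3) / 16) # 0.4375
  expect_equal(b_mu_closed(2.5, 0), 1)
  expect_equal(b_mu_closed(1.25, 1.25), 0.5)
  expect_equal(b_mu_closed(1, 3), 0.625)
  expect_error(b_shape_closed(0, 0, 0), "b1")
  expect_error(b_mu_closed(0, 0), "b1")
})

test_that("eigenvalue-based b-shape agrees with the closed form across specs", {
  set.seed(11)
  for (i in 1:15) {
    b1 <- runif(1, 0.1, 2.5)
    b2 <- runif(1, 0, 2.5)
    th <- runif(1, 0, 180)
    narrow <- i %% 2 == 0
    w <- make_dde_waveform(
      dde_block(b1 = b1, b2 = b2, theta = th,
                delta = if (narrow) 0 else 2, Delta = 10, tm = 8),
      dt = 0.01
    )
    bt <- b_tensor(w)
    expect_equal(bt$b, b1 + b2, tolerance = 2e-6)
    expect_equal(bt$b_shape, b_shape_closed(b1, b2, th), tolerance = 1e-6)
    expect_lt(max(abs(ddex:::waveform_q_end(w))), 1e-9) # rephasing
  }
})

test_that("infeasible or under-sampled specs are rejected", {
  expect_error(make_dde_waveform(dde_block(b1 = 1, delta = 3.5, Delta = 12),
                                 dt = 2), "dt")
  expect_error(dde_block(b1 = 1, delta = 12, Delta = 10), ">=")
})

test_that("narrow-pulse mode stores an exact piecewise-constant q", {
  w <- make_dde_waveform(dde_block(b1 = 1, b2 = 1, theta = 0, delta = 0,
                                   Delta = 12, tm = 12))
  expect_false(is.null(w$steps))
  expect_equal(b_tensor(w)$b, 2) # exact, no quadrature
  expect_equal(w$T, 2 * 12 + 12)
})
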