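# shared small-scale fixtures, built in code at test time

# study-conditions two-pool isotropic Gaussian substrate (D = 2, 0.5; 50/50)
iso_iso <- function(k_per_ms = 0) {
  gaussian_substrate(
    list(gaussian_pool(2, 0, fraction = 0.5),
         gaussian_pool(0.5, 0, fraction = 0.5)),
    k = k_per_ms
  )
}

# reduced-rotation protocols for fast tests
proto1_small <- function(n_dirs = 6, seed = 0, ...) {
  build_protocol(1, n_dirs = n_dirs, seed = seed, ...)
}

proto3_small <- function(n_dirs = 6, seed = 0, tm_max = Inf, ...) {
  p <- build_protocol(3, n_dirs = n_dirs, seed = seed, ...)
  p[p$tm <= tm_max, ]
}

# per-shell forward tmge signals joined back to the rotation level
tmge_rotation_signals <- function(protocol, truth) {
  shells <- protocol_shells(protocol)
  wts <- make_weight_eval(shells)(truth$k)
  ln <- tmge_signal(truth$D, truth$K_I0, truth$K_A0, truth$K_Iinf,
                    truth$K_Ainf, truth$K_eps, shells$b, shells$b_shape,
                    shells$b_mu, wts$h, wts$h_shape)
  dplyr::left_join(protocol,
                   dplyr::mutate(shells, signal = exp(ln))[, c("shell", "signal")],
                   by = "shell")
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-12)), tol)
}
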