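#' Specify one double-diffusion-encoding (DDE) block pair
#'
#' A DDE acquisition consists of two Stejskal-Tanner gradient pairs (blocks)
#' separated by a mixing time. Block i has b-value `b_i`, pulse duration
#' `delta` (ms), pulse spacing `Delta` (ms), and encoding direction `dir_i`;
#' `theta` is the angle between the two directions and `tm` the mixing time
#' measured from the end of the last pulse of block 1 to the start of the
#' first pulse of block 2 (so that with narrow pulses the four impulses sit
#' at 0, Delta, Delta + tm and 2 Delta + tm).
#'
#' @param b1,b2 b-values of the two blocks (ms/um^2); `b2 = 0` gives SDE.
#' @param theta angle between the two gradient pairs (degrees). Ignored if
#'   `dir2` is given explicitly.
#' @param delta pulse duration (ms); 0 requests narrow-pulse (impulse) mode.
#' @param Delta pulse spacing (ms), must be >= `delta`.
#' @param tm mixing time (ms).
#' @param dir1,dir2 unit 3-vectors; `dir2` defaults to `dir1` rotated by
#'   `theta` about an axis perpendicular to `dir1`.
#' @return An object of class `dde_block` (a named list).
#' @examples
#' dde_block(b1 = 1.25, b2 = 1.25, theta = 90)
#' @export
dde_block <- function(b1, b2 = 0, theta = 0, delta = 3.5, Delta = 12, tm = 12,
                      dir1 = c(1, 0, 0), dir2 = NULL) {
  stopifnot(b1 >= 0, b2 >= 0, delta >= 0, Delta >= delta, tm >= 0)
  dir1 <- dir1 / sqrt(sum(dir1^2))
  if (is.null(dir2)) {
    dir2 <- rotate_about_perp(dir1, theta)
  } else {
    dir2 <- dir2 / sqrt(sum(dir2^2))
    theta <- angle_deg(dir1, dir2)
  }
  if (b2 > 0 && abs(angle_deg(dir1, dir2) - theta) > 1e-9) {
    stop("angle between dir1 and dir2 does not match theta", call. = FALSE)
  }
  structure(
    list(b1 = b1, b2 = b2, theta = theta, delta = delta, Delta = Delta,
         tm = tm, dir1 = dir1, dir2 = dir2),
    class = "dde_block"
  )
}

angle_deg <- function(u, v) {
  c1 <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(min(1, max(-1, c1))) * 180 / pi
}

rotate_about_perp <- function(u, theta_deg) {
  th <- theta_deg * pi / 180
  # any unit vector perpendicular to u
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  p <- a - sum(a * u) * u
  p <- p / sqrt(sum(p^2))
  cos(th) * u + sin(th) * p
}

#' Realise a DDE block specification as a sampled gradient waveform
#'
#' Builds the dephasing vector q(t) (units 1/um) for four rectangular pulses
#' with signs +,-,+,- along `dir1` then `dir2`. Pulse amplitudes are set
#' analytically so each block's b-value is exact
#' (b = q_max^2 (Delta - delta/3) for rectangular pulses). With `delta = 0`
#' the impulses are represented analytically as a piecewise-constant q(t)
#' (no sampling bias); otherwise q is sampled at cell midpoints on a grid of
#' width `dt`.
#'
#' @param spec a [dde_block()].
#' @param dt sample interval (ms); must satisfy `dt <= delta/4` for finite
#'   pulses. Default 0.01 ms.
#' @return An object of class `dde_waveform`: a list with elements `dt`,
#'   `t` (cell midpoints), `q` (N x 3 matrix of cell values), `T` (total
#'   duration, ms), `steps` (exact piecewise-constant description in
#'   narrow-pulse mode, else NULL), and the originating `spec`.
#' @examples
#' w <- make_dde_waveform(dde_block(b1 = 2.5, delta = 3.5, Delta = 12))
#' b_tensor(w)$b
#' @export
make_dde_waveform <- function(spec, dt = 0.01) {
  stopifnot(inherits(spec, "dde_block"))
  delta <- spec$delta
  Delta <- spec$Delta
  tm <- spec$tm
  narrow <- delta == 0
  if (!narrow && dt > delta / 4 + 1e-12) {
    stop("dt must be <= delta/4 for finite pulses", call. = FALSE)
  }
  eff <- if (narrow) Delta else (Delta - delta / 3)
  if (eff <= 0) stop("infeasible spec: Delta - delta/3 <= 0", call. = FALSE)
  a1 <- sqrt(spec$b1 / eff)
  a2 <- sqrt(spec$b2 / eff)
  t_end <- 2 * Delta + 2 * delta + tm # collapses to 2*Delta + tm when narrow
  t2 <- Delta + delta + tm            # onset of block 2
  if (narrow) {
    steps <- data.frame(
      t0 = c(0, Delta, Delta + tm),
      t1 = c(Delta, Delta + tm, 2 * Delta + tm),
      amp = c(a1, 0, a2),
      block = c(1L, 0L, 2L)
    )
    n <- max(64L, ceiling(t_end / dt))
    dtt <- t_end / n
    tmid <- (seq_len(n) - 0.5) * dtt
    u1 <- as.numeric(tmid >= 0 & tmid < Delta)
    u2 <- as.numeric(tmid >= Delta + tm & tmid < 2 * Delta + tm)
  } else {
    steps <- NULL
    n <- ceiling(t_end / dt)
    dtt <- t_end / n
    tmid <- (seq_len(n) - 0.5) * dtt
    u1 <- block_profile(tmid, 0, delta, Delta)
    u2 <- block_profile(tmid, t2, delta, Delta)
  }
  q <- a1 * outer(u1, spec$dir1) + a2 * outer(u2, spec$dir2)
  structure(
    list(dt = dtt, t = tmid, q = q, T = t_end, steps = steps,
         u1 = u1, u2 = u2, a1 = a1, a2 = a2, narrow = narrow, spec = spec),
    class = "dde_waveform"
  )
}

# unit trapezoid profile of q(t) for one rectangular-pulse block
block_profile <- function(t, t0, delta, Delta) {
  s <- t - t0
  up <- pmin(pmax(s / delta, 0), 1)
  dn <- pmin(pmax((s - Delta) / delta, 0), 1)
  (up - dn) * (s >= 0 & s <= Delta + delta)
}

#' @export
print.dde_waveform <- function(x, ...) {
  s <- x$spec
  cat(sprintf(
    "<dde_waveform> b1=%.3g b2=%.3g ms/um^2, theta=%.1f deg, delta=%.3g, Delta=%.3g, tm=%.3g ms%s\n",
    s$b1, s$b2, s$theta, s$delta, s$Delta, s$tm,
    if (x$narrow) " (narrow-pulse)" else ""
  ))
  invisible(x)
}

#' b-tensor and encoding-shape metrics of a waveform
#'
#' Computes the b-tensor \eqn{B = \int q(t) q(t)^T dt}, its trace b, the
#' encoding-shape metric \eqn{b_\Delta^2 = (3/2) (B\!:\!B)/b^2 - 1/2}
#' (1 for SDE/parallel DDE, 1/4 for orthogonal DDE at b1 = b2), and the
#' microscopic-kurtosis sensitivity \eqn{b_\mu^2 = (b_1^2+b_2^2)/(b_1+b_2)^2}.
#'
#' @param w a [make_dde_waveform()] result.
#' @return list with elements `B` (3x3, ms/um^2), `b`, `b_shape`, `b_mu`.
#' @export
b_tensor <- function(w) {
  stopifnot(inherits(w, "dde_waveform"))
  q_end <- waveform_q_end(w)
  if (max(abs(q_end)) > 1e-9) {
    stop("waveform does not rephase: q(T) != 0", call. = FALSE)
  }
  if (!is.null(w$steps)) {
    s <- w$spec
    B <- s$b1 * outer(s$dir1, s$dir1) + s$b2 * outer(s$dir2, s$dir2)
  } else {
    B <- crossprod(w$q) * w$dt
  }
  b <- sum(diag(B))
  b_shape <- if (b > 0) 1.5 * sum(B * B) / b^2 - 0.5 else NA_real_
  s <- w$spec
  b_mu <- if (s$b1 + s$b2 > 0) b_mu_closed(s$b1, s$b2) else NA_real_
  list(B = B, b = b, b_shape = b_shape, b_mu = b_mu)
}

# q at end of waveform; zero by construction, checked for safety
waveform_q_end <- function(w) {
  if (!is.null(w$steps)) return(c(0, 0, 0))
  # cell values of last cell lie on the final down-ramp; evaluate analytically
  s <- w$spec
  u1 <- block_profile(w$T, 0, s$delta, s$Delta)
  u2 <- block_profile(w$T, s$Delta + s$delta + s$tm, s$delta, s$Delta)
  w$a1 * u1 * s$dir1 + w$a2 * u2 * s$dir2
}

#' Closed-form b-tensor shape for a DDE block pair
#'
#' \deqn{b_\Delta^2 = [b_1^2 + b_2^2 + b_1 b_2 (3\cos^2\theta - 1)] /
#' (b_1+b_2)^2.}
#'
#' @param b1,b2 block b-values (ms/um^2); `b1 + b2 > 0`.
#' @param theta angle between gradient pairs (degrees).
#' @return dimensionless shape in [1/4, 1] for the schemes used here.
#' @export
b_shape_closed <- function(b1, b2, theta) {
  if (any(b1 + b2 <= 0)) stop("b1 + b2 must be > 0", call. = FALSE)
  c2 <- cos(theta * pi / 180)^2
  (b1^2 + b2^2 + b1 * b2 * (3 * c2 - 1)) / (b1 + b2)^2
}

#' Closed-form microscopic-kurtosis encoding sensitivity
#'
#' \deqn{b_\mu^2 = (b_1^2 + b_2^2)/(b_1+b_2)^2:} 1 for SDE, 1/2 for DDE with
#' equal b-values. Also written \eqn{b_\varepsilon^2} in the transient-kurtosis
#' representation.
#'
#' @inheritParams b_shape_closed
#' @return dimensionless value in [1/2, 1].
#' @export
b_mu_closed <- function(b1, b2) {
  if (any(b1 + b2 <= 0)) stop("b1 + b2 must be > 0", call. = FALSE)
  (b1^2 + b2^2) / (b1 + b2)^2
}
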