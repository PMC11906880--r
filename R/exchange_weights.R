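#' Closed-form exchange-weighting function for narrow-pulse SDE
#'
#' \deqn{h_{SDE}(k,\Delta) = 2/(k\Delta) - 2/(k\Delta)^2 +
#' 2 e^{-k\Delta}/(k\Delta)^2,} with the series limit 1 as k -> 0.
#' h(k) expresses how strongly a waveform weights intercompartmental exchange
#' at rate k into the fourth-cumulant (kurtosis) term of the signal.
#'
#' @param k exchange rate (1/ms); vectorised.
#' @param Delta pulse spacing (ms), > 0.
#' @return dimensionless weight in (0, 1].
#' @export
h_sde <- function(k, Delta) {
  if (any(Delta <= 0)) stop("Delta must be > 0", call. = FALSE)
  if (any(k < 0)) stop("k must be >= 0", call. = FALSE)
  n <- max(length(k), length(Delta))
  k <- rep_len(k, n)
  Delta <- rep_len(Delta, n)
  2 * g_self(k, Delta) / Delta^2
}

#' Closed-form exchange-weighting function for narrow-pulse DDE
#'
#' For equal blocks (b1 = b2, common pulse spacing Delta) and mixing time tm:
#' \deqn{h_{DDE} = h_{SDE}/2 + [e^{-k t_m} + e^{-k(2\Delta+t_m)} -
#' 2e^{-k(\Delta+t_m)}] / (2 (k\Delta)^2).}
#' Limits: 1 as k -> 0 and h_sde/2 as tm -> infinity.
#'
#' @inheritParams h_sde
#' @param tm mixing time (ms), >= 0.
#' @export
h_dde <- function(k, Delta, tm) {
  if (any(Delta <= 0) || any(tm < 0)) stop("negative timing", call. = FALSE)
  if (any(k < 0)) stop("k must be >= 0", call. = FALSE)
  n <- max(length(k), length(Delta), length(tm))
  k <- rep_len(k, n)
  Delta <- rep_len(Delta, n)
  tm <- rep_len(tm, n)
  0.5 * h_sde(k, Delta) + g_cross(k, Delta, tm) / (2 * Delta^2)
}

# G_self(k) = int_0^Delta (Delta - t) e^{-kt} dt = (kD - 1 + e^{-kD})/k^2
# series used for small k*Delta to avoid catastrophic cancellation;
# k and Delta recycled to a common length by the callers
g_self <- function(k, Delta) {
  n <- max(length(k), length(Delta))
  k <- rep_len(k, n)
  Delta <- rep_len(Delta, n)
  x <- k * Delta
  out <- numeric(n)
  small <- x < 0.5
  if (any(small)) {
    xs <- x[small]
    acc <- 0
    term <- rep(1, length(xs))
    for (m in 0:18) { # Delta^2 * sum_m (-x)^m / (m+2)!
      term <- if (m == 0) 1 / 2 else term * (-xs) / (m + 2)
      acc <- acc + term
    }
    out[small] <- Delta[small]^2 * acc
  }
  if (any(!small)) {
    xl <- x[!small]
    out[!small] <- (xl - 1 + exp(-xl)) * (Delta[!small] / xl)^2
  }
  out
}

# G_cross(k) = int tri(t) e^{-kt} dt where tri is the triangle of base
# [tm, 2 Delta + tm] and height Delta (block-1 x block-2 lag overlap)
g_cross <- function(k, Delta, tm) {
  nn <- max(length(k), length(Delta), length(tm))
  k <- rep_len(k, nn)
  Delta <- rep_len(Delta, nn)
  tm <- rep_len(tm, nn)
  out <- numeric(nn)
  small <- k * (2 * Delta + tm) < 0.5
  if (any(small)) {
    ks <- k[small]
    Ds <- Delta[small]
    ts <- tm[small]
    acc <- 0
    pow <- rep(1, length(ks))
    fact <- 2
    for (m in 0:24) { # sum_m (-k)^m S_{m+2} / (m+2)!
      n <- m + 2
      s_n <- ts^n + (2 * Ds + ts)^n - 2 * (Ds + ts)^n
      if (m > 0) {
        pow <- pow * (-ks)
        fact <- fact * n
      }
      acc <- acc + pow * s_n / fact
    }
    out[small] <- acc
  }
  if (any(!small)) {
    kl <- k[!small]
    Dl <- Delta[!small]
    tl <- tm[!small]
    out[!small] <- (exp(-kl * tl) + exp(-kl * (2 * Dl + tl)) -
                      2 * exp(-kl * (Dl + tl))) / kl^2
  }
  out
}

#' Closed-form scalar weights for a general narrow-pulse DDE pair
#'
#' Generalisation of [h_sde()]/[h_dde()] to unequal block b-values and an
#' arbitrary inter-pair angle, derived from the analytic fourth-order
#' autocorrelation of a piecewise-constant q(t):
#' \eqn{h(k) b^2 = 2 G_{self}(q_1^4 + q_2^4) + 2 q_1^2 q_2^2 G_{cross}} and
#' \eqn{h_\Delta^2(k)\, h(k)\, b^2 = 2 G_{self}(q_1^4+q_2^4) +
#' q_1^2 q_2^2 G_{cross} (3\cos^2\theta - 1)} with \eqn{q_i^2 = b_i/\Delta}.
#'
#' @inheritParams h_dde
#' @param b1,b2 block b-values (ms/um^2).
#' @param theta angle between pairs (degrees); only `h_shape` depends on it.
#' @return tibble with columns `k`, `h`, `h_shape`.
#' @export
h_pair_closed <- function(k, Delta, tm, b1, b2, theta = 0) {
  stopifnot(b1 + b2 > 0, Delta > 0, tm >= 0)
  q1sq <- b1 / Delta
  q2sq <- b2 / Delta
  b2tot <- (b1 + b2)^2
  gs <- g_self(k, Delta)
  gc_ <- g_cross(k, Delta, tm)
  self_term <- 2 * gs * (q1sq^2 + q2sq^2)
  cross <- q1sq * q2sq * gc_
  h <- (self_term + 2 * cross) / b2tot
  c2 <- cos(theta * pi / 180)^2
  hs <- (self_term + cross * (3 * c2 - 1)) / (b2tot * h)
  tibble::tibble(k = k, h = h, h_shape = hs)
}

#' Fourth-order autocorrelation of the squared dephasing magnitude
#'
#' \deqn{q_4(t) = \int_0^T q^2(t') q^2(t'+t) dt'.} For narrow-pulse waveforms
#' q^2 is piecewise constant and the correlation is evaluated exactly at a
#' knot-refined lag grid (q4 is then piecewise linear); for finite pulses it
#' is a discrete correlation on the waveform's sample grid.
#'
#' @param w a `dde_waveform`.
#' @param n_lag approximate number of lag samples for the narrow-pulse exact
#'   path.
#' @return tibble with columns `lag` (ms) and `q4` ((1/um)^4 ms); attribute
#'   `b_sq` holds the squared numeric b-value used to normalise.
#' @export
q4_autocorr <- function(w, n_lag = 2048) {
  stopifnot(inherits(w, "dde_waveform"))
  if (!is.null(w$steps)) {
    st <- w$steps
    s_vals <- st$amp^2 # |q|^2 per segment
    lags <- narrow_lag_grid(st, n_lag)
    q4 <- step_corr(st$t0, st$t1, s_vals, s_vals, lags)
    b_sq <- (sum(s_vals * (st$t1 - st$t0)))^2
    out <- tibble::tibble(lag = lags, q4 = q4)
  } else {
    s <- rowSums(w$q^2)
    n <- length(s)
    if (n == 0 || all(s == 0)) stop("empty waveform", call. = FALSE)
    cc <- corr_series(s, s)
    out <- tibble::tibble(lag = (seq_len(n) - 1) * w$dt, q4 = cc * w$dt)
    b_sq <- (sum(s) * w$dt)^2
  }
  attr(out, "b_sq") <- b_sq
  out
}

# positive-lag discrete cross-correlation sum_i x_i y_{i+m}, FFT-based
corr_series <- function(x, y) {
  n <- length(x)
  convolve(y, x, conj = TRUE, type = "open")[n:(2 * n - 1)]
}

# lag grid with every knot of the piecewise-linear step correlation included
narrow_lag_grid <- function(st, n_lag) {
  br <- unique(c(st$t0, st$t1))
  knots <- unique(abs(as.vector(outer(br, br, "-"))))
  tmax <- max(st$t1)
  sort(unique(c(knots[knots <= tmax], seq(0, tmax, length.out = n_lag))))
}

# exact correlation of two step functions on shared segments
step_corr <- function(t0, t1, f, g, lags) {
  out <- numeric(length(lags))
  for (a in seq_along(f)) {
    if (f[a] == 0) next
    for (b in seq_along(g)) {
      if (g[b] == 0) next
      ov <- pmax(0, pmin(t1[a], t1[b] - lags) - pmax(t0[a], t0[b] - lags))
      out <- out + f[a] * g[b] * ov
    }
  }
  out
}

#' Numerical exchange-weighting function of a waveform
#'
#' Evaluates \eqn{h(k) = 2 \int_0^T \tilde q_4(t) e^{-kt} dt} by trapezoidal
#' quadrature of [q4_autocorr()], with \eqn{\tilde q_4 = q_4 / b^2}.
#' Satisfies h(0) = 1 for every rephased waveform.
#'
#' @param w a `dde_waveform`.
#' @param k exchange rate(s), 1/ms; must be >= 0.
#' @return numeric vector, one value per element of `k`.
#' @examples
#' w <- make_dde_waveform(dde_block(b1 = 1.25, b2 = 1.25, delta = 0, Delta = 12))
#' h_numeric(w, 0) # 1
#' @export
h_numeric <- function(w, k) {
  if (any(k < 0)) stop("k must be >= 0", call. = FALSE)
  q4 <- q4_autocorr(w)
  b_sq <- attr(q4, "b_sq")
  if (!is.null(w$steps)) {
    vapply(k, function(kk) {
      2 * trapz(q4$lag, q4$q4 * exp(-kk * q4$lag)) / b_sq
    }, numeric(1))
  } else {
    # Riemann double-sum form: exact 1 at k = 0 by construction
    dt <- w$dt
    vapply(k, function(kk) {
      wts <- exp(-kk * q4$lag)
      (2 * sum(q4$q4 * wts) - q4$q4[1]) * dt / b_sq
    }, numeric(1))
  }
}

trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

#' Exchange-sensitised square of the b-tensor
#'
#' Computes \eqn{\mathbb{H}(k) = 2\int_0^T \mathbb{Q}_4(t) e^{-kt} dt} with
#' \eqn{\mathbb{Q}_4(t) = \int q^{\otimes 2}(t') \otimes q^{\otimes 2}(t'+t)
#' dt'}, equivalently \eqn{H = \int\!\!\int v(t_1) v(t_2)^T e^{-k|t_1-t_2|}}
#' in the Voigt representation \eqn{v = (q_x^2, q_y^2, q_z^2, \sqrt2 q_xq_y,
#' \sqrt2 q_xq_z, \sqrt2 q_yq_z)}. At k = 0 it reduces to the outer square of
#' the b-tensor, \eqn{\mathbb{H}(0) = B^{\otimes 2}}.
#'
#' @param w a `dde_waveform`.
#' @param k single exchange rate (1/ms), >= 0.
#' @return An object of class `ddex_h4`: a 6 x 6 matrix in Voigt form (units
#'   (ms/um^2)^2) with attributes `k` and `b`. Convert with [h4_to_array()].
#' @export
H_tensor <- function(w, k) {
  stopifnot(length(k) == 1, k >= 0)
  if (!is.null(w$steps)) {
    st <- w$steps
    segv <- t(vapply(seq_len(nrow(st)), function(i) {
      d <- if (st$block[i] == 1L) w$spec$dir1 else w$spec$dir2
      voigt6(st$amp[i]^2 * outer(d, d))
    }, numeric(6)))
    lags <- narrow_lag_grid(st, 2048)
    H <- matrix(0, 6, 6)
    for (a in 1:6) {
      for (b in a:6) {
        cab <- step_corr(st$t0, st$t1, segv[, a], segv[, b], lags)
        cba <- step_corr(st$t0, st$t1, segv[, b], segv[, a], lags)
        val <- trapz(lags, (cab + cba) * exp(-k * lags))
        H[a, b] <- H[b, a] <- val
      }
    }
  } else {
    v <- cbind(
      w$q[, 1]^2, w$q[, 2]^2, w$q[, 3]^2,
      sqrt(2) * w$q[, 1] * w$q[, 2],
      sqrt(2) * w$q[, 1] * w$q[, 3],
      sqrt(2) * w$q[, 2] * w$q[, 3]
    )
    n <- nrow(v)
    ek <- exp(-k * (seq_len(n) - 1) * w$dt)
    H <- matrix(0, 6, 6)
    for (a in 1:6) {
      for (b in a:6) {
        cab <- corr_series(v[, a], v[, b])
        cba <- if (a == b) cab else corr_series(v[, b], v[, a])
        val <- (sum((cab + cba) * ek) - cab[1]) * w$dt^2
        H[a, b] <- H[b, a] <- val
      }
    }
  }
  bt <- b_tensor(w)
  structure(H, class = "ddex_h4", k = k, b = bt$b)
}

voigt6 <- function(m) {
  c(m[1, 1], m[2, 2], m[3, 3],
    sqrt(2) * m[1, 2], sqrt(2) * m[1, 3], sqrt(2) * m[2, 3])
}

#' Convert a Voigt-form fourth-order tensor to a full 3x3x3x3 array
#' @param H a `ddex_h4` (or plain 6x6 Voigt matrix with sqrt-2 convention).
#' @return 3x3x3x3 array with full minor and major symmetry.
#' @export
h4_to_array <- function(H) {
  idx <- rbind(c(1, 1), c(2, 2), c(3, 3), c(1, 2), c(1, 3), c(2, 3))
  wts <- c(1, 1, 1, sqrt(2), sqrt(2), sqrt(2))
  A <- array(0, c(3, 3, 3, 3))
  for (a in 1:6) {
    for (b in 1:6) {
      val <- H[a, b] / (wts[a] * wts[b])
      i <- idx[a, 1]; j <- idx[a, 2]; k <- idx[b, 1]; l <- idx[b, 2]
      for (ij in list(c(i, j), c(j, i))) {
        for (kl in list(c(k, l), c(l, k))) {
          A[ij[1], ij[2], kl[1], kl[2]] <- val
        }
      }
    }
  }
  A
}

#' Convert a full minor-symmetric 3x3x3x3 array to Voigt form
#' @param A 3x3x3x3 array.
#' @return 6x6 matrix in the package's sqrt-2 Voigt convention.
#' @export
array_to_h4 <- function(A) {
  idx <- rbind(c(1, 1), c(2, 2), c(3, 3), c(1, 2), c(1, 3), c(2, 3))
  wts <- c(1, 1, 1, sqrt(2), sqrt(2), sqrt(2))
  H <- matrix(0, 6, 6)
  for (a in 1:6) {
    for (b in 1:6) {
      H[a, b] <- A[idx[a, 1], idx[a, 2], idx[b, 1], idx[b, 2]] *
        wts[a] * wts[b]
    }
  }
  H
}

#' Isotropic and anisotropic projections of the exchange-sensitised tensor
#'
#' \deqn{h(k) = (\mathbb{H} : 9 \mathbb{I}_I)/b^2, \qquad
#' h_\Delta^2(k) = (\mathbb{H} : \tfrac92 \mathbb{I}_A)/(b^2 h(k)),}
#' with \eqn{\mathbb{I}_I = \tfrac19 \delta\otimes\delta} and
#' \eqn{\mathbb{I}_A = \tfrac13 \mathbb{I}_{sym} - \mathbb{I}_I} (bulk/shear
#' split). The normalisation is pinned by the identities h(0) = 1 and
#' \eqn{h_\Delta^2(0) = b_\Delta^2}, which hold for every rephased waveform.
#'
#' @param H a [H_tensor()] result.
#' @param b total b-value (trace of the b-tensor); defaults to the value
#'   stored in `H`.
#' @return list with elements `h` and `h_shape`.
#' @export
project_h <- function(H, b = attr(H, "b")) {
  stopifnot(b > 0)
  e <- c(1, 1, 1, 0, 0, 0)
  iso <- as.numeric(e %*% H %*% e) # H : (delta x delta)
  tr6 <- sum(diag(H))              # H : I_sym
  h <- iso / b^2
  if (h <= 0) stop("nonpositive isotropic projection: numerical failure", call. = FALSE)
  hs <- (1.5 * tr6 - 0.5 * iso) / (b^2 * h)
  list(h = h, h_shape = hs)
}

#' Tabulate exchange weights of a set of waveforms
#'
#' @param waveforms list of `dde_waveform` (e.g. [protocol_waveforms()]).
#' @param k_per_s exchange rates in 1/s.
#' @param ids optional waveform labels.
#' @return tibble with columns `waveform_id`, `k_per_s`, `h`, `h_shape`,
#'   suitable for CSV export.
#' @export
exchange_weight_table <- function(waveforms, k_per_s = seq(0, 200, by = 20),
                                  ids = seq_along(waveforms)) {
  k_ms <- k_per_s / ms_per_s
  purrr::map2_dfr(waveforms, ids, function(w, id) {
    hs <- vapply(k_ms, function(kk) {
      unlist(project_h(H_tensor(w, kk)))
    }, numeric(2))
    tibble::tibble(
      waveform_id = id, k_per_s = k_per_s,
      h = hs[1, ], h_shape = hs[2, ]
    )
  })
}
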