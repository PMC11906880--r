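#' Define a Gaussian diffusion pool
#'
#' An axially symmetric diffusion tensor parameterised by its mean
#' diffusivity and shape anisotropy: eigenvalues
#' \eqn{D_{iso}(1 - D_\Delta)} (radial, twice) and
#' \eqn{D_{iso}(1 + 2 D_\Delta)} (axial). `D_delta = 0` is isotropic,
#' `D_delta = 1` a stick, `D_delta = -1/2` a plate.
#'
#' @param D_iso mean diffusivity (um^2/ms).
#' @param D_delta shape anisotropy in [-0.5, 1].
#' @param orientation axis of symmetry (unit 3-vector).
#' @param fraction equilibrium fraction in (0, 1].
#' @return list of class `gaussian_pool` with the tensor `D`, its Cholesky
#'   -like factor `L` (D = L L'), eigenvalues and eigenvalue variance.
#' @export
gaussian_pool <- function(D_iso, D_delta = 0, orientation = c(0, 0, 1),
                          fraction = 1) {
  stopifnot(D_iso >= 0, D_delta >= -0.5, D_delta <= 1,
            fraction > 0, fraction <= 1)
  u <- orientation / sqrt(sum(orientation^2))
  rad <- D_iso * (1 - D_delta)
  ax <- D_iso * (1 + 2 * D_delta)
  D <- rad * diag(3) + (ax - rad) * outer(u, u)
  ev <- c(rad, rad, ax)
  es <- eigen(D, symmetric = TRUE)
  L <- es$vectors %*% diag(sqrt(pmax(es$values, 0)))
  structure(
    list(D_iso = D_iso, D_delta = D_delta, orientation = u,
         fraction = fraction, D = D, L = L,
         eigenvalues = ev, V_lambda = mean((ev - mean(ev))^2)),
    class = "gaussian_pool"
  )
}

#' Assemble exchanging Gaussian pools into a substrate
#'
#' For two pools a single total exchange rate `k` (the sum of the directional
#' rates, as used by the exchange-weighting function) is split to satisfy
#' detailed balance: \eqn{k_{1\to2} = k f_2}, \eqn{k_{2\to1} = k f_1}. For
#' more pools supply the full directional `rates` matrix (1/ms, entry [i, j]
#' is the rate from pool i to pool j); detailed balance
#' \eqn{f_i k_{ij} = f_j k_{ji}} is checked.
#'
#' @param pools list of [gaussian_pool()]; fractions must sum to 1.
#' @param k total two-pool exchange rate (1/ms); ignored if `rates` given.
#' @param rates optional directional rate matrix (1/ms).
#' @return list of class `gaussian_substrate` with pools, `rates`, mean
#'   diffusivity `D_mean` and the total-kurtosis summary `K_T`
#'   (isotropic pools: \eqn{3\,\mathrm{Var}(D)/\langle D\rangle^2}).
#' @export
gaussian_substrate <- function(pools, k = 0, rates = NULL) {
  f <- vapply(pools, `[[`, numeric(1), "fraction")
  if (abs(sum(f) - 1) > 1e-9) stop("pool fractions must sum to 1", call. = FALSE)
  n <- length(pools)
  if (is.null(rates)) {
    if (n == 1) {
      rates <- matrix(0, 1, 1)
    } else if (n == 2) {
      rates <- matrix(0, 2, 2)
      rates[1, 2] <- k * f[2]
      rates[2, 1] <- k * f[1]
    } else {
      stop("supply a `rates` matrix for more than two pools", call. = FALSE)
    }
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && abs(f[i] * rates[i, j] - f[j] * rates[j, i]) > 1e-9) {
        stop("rates violate detailed balance", call. = FALSE)
      }
    }
  }
  D_iso <- vapply(pools, `[[`, numeric(1), "D_iso")
  D_mean <- sum(f * D_iso)
  V_iso <- sum(f * D_iso^2) - D_mean^2
  V_aniso <- sum(f * vapply(pools, `[[`, numeric(1), "V_lambda")) * 6 / 5 / 2
  structure(
    list(pools = pools, fractions = f, rates = rates,
         D_mean = D_mean,
         K_I = 3 * V_iso / D_mean^2,
         K_A = (6 / 5) * sum(f * vapply(pools, `[[`, numeric(1), "V_lambda")) /
           D_mean^2,
         K_T = 3 * V_iso / D_mean^2 +
           (6 / 5) * sum(f * vapply(pools, `[[`, numeric(1), "V_lambda")) /
           D_mean^2),
    class = "gaussian_substrate"
  )
}

#' Three-pool substrate with fast and slow exchange timescales
#'
#' Two isotropic pools (\eqn{D} = 0.1 and 0.5 um^2/ms, fractions 0.25 each)
#' in rapid exchange (total rate `k_fast`, default 100 1/s) form a combined
#' unit with effective transient kurtosis; that unit is in slow exchange
#' (total rate `k_slow`) with a third pool (\eqn{D} = 1 um^2/ms, fraction
#' 0.5). Used to demonstrate that tMGE separates transient kurtosis (the
#' fast pair's heterogeneity) from intercompartmental exchange.
#'
#' @param k_slow_per_s slow exchange rate between the fast pair and the
#'   third pool (1/s), in [0, 10] for the study conditions.
#' @param k_fast_per_s fast within-pair rate (1/s).
#' @return a [gaussian_substrate()].
#' @export
three_pool_transient_substrate <- function(k_slow_per_s, k_fast_per_s = 100) {
  stopifnot(k_slow_per_s >= 0)
  kf <- k_fast_per_s / ms_per_s
  ks <- k_slow_per_s / ms_per_s
  pools <- list(
    gaussian_pool(0.1, 0, fraction = 0.25),
    gaussian_pool(0.5, 0, fraction = 0.25),
    gaussian_pool(1.0, 0, fraction = 0.5)
  )
  rates <- matrix(0, 3, 3)
  # fast pair: equal fractions, split the total rate equally
  rates[1, 2] <- rates[2, 1] <- kf / 2
  # slow group <-> pool 3: group fraction 0.5 equals pool-3 fraction
  rates[1, 3] <- rates[2, 3] <- ks / 2
  rates[3, 1] <- rates[3, 2] <- ks / 4
  gaussian_substrate(pools, rates = rates)
}

#' Define a restricted periodic geometry substrate
#'
#' Supported geometries:
#' * `spheres`: simple cubic lattice of spheres of `diameter`; the lattice
#'   constant is set by `packing` (0.5 gives near-touching spheres,
#'   lattice constant ~ 6.09 um at d = 6 um).
#' * `cylinders`: hexagonally packed parallel cylinders (axis z).
#' * `beads`: axially periodic bead chains, radius
#'   \eqn{r(z) = r_0 + r_1 \sin(2\pi z/\mathrm{period})} between
#'   `d_min/2` and `d_max/2`, on a square lattice in x, y.
#'
#' @param kind "spheres", "cylinders" or "beads".
#' @param diameter sphere/cylinder diameter (um); for beads use `d_min`,
#'   `d_max`.
#' @param packing intracellular volume fraction.
#' @param permeability membrane permeability kappa (um/ms); 0 = impermeable.
#' @param D0 bulk diffusivity (um^2/ms).
#' @param d_min,d_max,period bead profile parameters (um).
#' @return list of class `geometry_substrate` with the resolved lattice
#'   parameters.
#' @export
geometry_substrate <- function(kind = c("spheres", "cylinders", "beads"),
                               diameter = 6, packing = 0.5, permeability = 0,
                               D0 = 2, d_min = 1, d_max = 6, period = 10) {
  kind <- match.arg(kind)
  stopifnot(packing > 0, packing < 1, permeability >= 0, D0 > 0)
  R <- diameter / 2
  par <- switch(kind,
    spheres = {
      L <- ((4 / 3) * pi * R^3 / packing)^(1 / 3)
      if (L < 2 * R) stop("packing too dense for a cubic sphere lattice", call. = FALSE)
      list(kind_code = 1L, R = R, L = L, a = 0, r0 = 0, r1 = 0, period = 0)
    },
    cylinders = {
      a <- sqrt(pi * R^2 / (packing * sqrt(3) / 2))
      if (a < 2 * R) stop("packing too dense for a hexagonal cylinder lattice", call. = FALSE)
      list(kind_code = 2L, R = R, L = 0, a = a, r0 = 0, r1 = 0, period = 0)
    },
    beads = {
      # radius profile sinusoidal in r^2 (r^2(z) = a0 + a1 sin(2 pi z / P)):
      # spends more length near the maximum diameter than a sinusoidal r(z),
      # which is what makes the nominal 40% packing geometrically attainable
      a0 <- (d_max^2 + d_min^2) / 8
      a1 <- (d_max^2 - d_min^2) / 8
      vol <- pi * a0 * period
      L <- sqrt(vol / (packing * period))
      if (L < d_max) stop("packing too dense for the bead lattice", call. = FALSE)
      list(kind_code = 3L, R = 0, L = L, a = 0, r0 = a0, r1 = a1, period = period)
    }
  )
  structure(
    c(list(kind = kind, diameter = diameter, packing = packing,
           permeability = permeability, D0 = D0), par),
    class = "geometry_substrate"
  )
}
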