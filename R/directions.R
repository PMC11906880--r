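#' Generate gradient directions by electrostatic repulsion
#'
#' Places `n` unit vectors on the sphere at a local minimum of the antipodally
#' symmetrised electrostatic (Coulomb) energy
#' \deqn{E = \sum_{i<j} 1/|x_i - x_j| + 1/|x_i + x_j|,}
#' the standard construction for diffusion-MRI rotation schemes. Directions
#' are defined up to sign, so antipodal pairs are treated as one axis.
#'
#' @param n number of directions (>= 1).
#' @param seed integer seed; the optimisation is deterministic given the seed.
#' @param n_starts random restarts; the lowest-energy solution is kept.
#' @return A tibble with columns `dir`, `x`, `y`, `z` and attribute `energy`.
#' @examples
#' d6 <- generate_directions(6, seed = 0)
#' min_pair_angle(as.matrix(d6[, c("x", "y", "z")]))
#' @export
generate_directions <- function(n, seed = 0, n_starts = 4L) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("`n` must be a single integer >= 1", call. = FALSE)
  }
  n <- as.integer(n)
  if (n == 1L) {
    out <- tibble::tibble(dir = 1L, x = 0, y = 0, z = 1)
    attr(out, "energy") <- 0
    attr(out, "seed") <- seed
    return(out)
  }
  best <- NULL
  for (s in seq_len(n_starts)) {
    set.seed(seed * 1009L + s)
    # spherical-coordinate parameterisation keeps vectors exactly unit norm
    theta0 <- acos(runif(n, -1, 1))
    phi0 <- runif(n, 0, 2 * pi)
    fit <- optim(
      par = c(theta0, phi0),
      fn = function(p) coulomb_energy(angles_to_xyz(p, n)),
      gr = NULL,
      method = "BFGS",
      control = list(maxit = 500, reltol = 1e-12)
    )
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  xyz <- angles_to_xyz(best$par, n)
  # canonical sign: first nonzero component positive
  flip <- sign(xyz[, 3] + 1e-12 * xyz[, 1] + 1e-15 * xyz[, 2])
  xyz <- xyz * flip
  out <- tibble::tibble(dir = seq_len(n), x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  attr(out, "energy") <- best$value
  attr(out, "seed") <- seed
  out
}

angles_to_xyz <- function(p, n) {
  theta <- p[seq_len(n)]
  phi <- p[n + seq_len(n)]
  cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
}

#' Antipodally symmetrised Coulomb energy of a direction set
#' @param xyz n x 3 matrix of unit vectors.
#' @return scalar energy.
#' @export
coulomb_energy <- function(xyz) {
  n <- nrow(xyz)
  if (n < 2) return(0)
  g <- tcrossprod(xyz) # cos angles
  g[g > 1] <- 1
  g[g < -1] <- -1
  iu <- upper.tri(g)
  c1 <- g[iu]
  # |x-y|^2 = 2-2c, |x+y|^2 = 2+2c
  sum(1 / sqrt(pmax(2 - 2 * c1, 1e-12)) + 1 / sqrt(pmax(2 + 2 * c1, 1e-12)))
}

#' Minimum pairwise angle of a direction set (axes, degrees)
#' @param xyz n x 3 matrix of unit vectors.
#' @return smallest inter-axis angle in degrees.
#' @export
min_pair_angle <- function(xyz) {
  n <- nrow(xyz)
  if (n < 2) return(180)
  g <- abs(tcrossprod(xyz))
  g[g > 1] <- 1
  diag(g) <- 0
  min(acos(max(g[upper.tri(g)])) * 180 / pi, 180) # angle of closest pair
}
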