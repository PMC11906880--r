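#' Build one of the four study acquisition protocols
#'
#' Returns the acquisition list of the protocols used throughout the package,
#' one row per acquired waveform (set, rotation, second-pair direction choice,
#' mixing time and b-value). Timing conventions follow [dde_block()].
#'
#' * **Protocol 1** (preclinical CTI): four sets at `delta = 3.5`,
#'   `Delta = tm = 12` ms. Set 1: SDE, b = 2.5 ms/um^2, 45 rotations chosen by
#'   electrostatic repulsion. Set 2: parallel DDE b1 = b2 = 1.25. Set 3:
#'   orthogonal DDE b1 = b2 = 1.25, each rotation repeated for three
#'   equidistant (120 deg apart) second-pair directions, 135 acquisitions.
#'   Set 4: parallel DDE b1 = b2 = 0.5. 270 acquisitions in total.
#' * **Protocol 2** (long-mixing-time check): parallel and antiparallel DDE,
#'   `(b1, b2, theta)` = (1, 1, 0 deg) and (1, 1, 180 deg), protocol-1 timings
#'   and rotations.
#' * **Protocol 3** (variable mixing time): protocol-1 geometry with eleven
#'   mixing times (1, 4, 8, 12, 16, 20, 30, 50, 100, 200, 300 ms) for both
#'   parallel and orthogonal DDE and six total b-values
#'   (0.25, 0.5, 1, 1.5, 2, 2.5 ms/um^2) for both SDE and DDE.
#' * **Protocol 4** (clinical timings): `delta/Delta/tm` = 15.8/31.8/32.3 ms
#'   with added mixing times (1, 4, 8, 12, 16, 20, 32.3, 50, 100 ms), same
#'   b-values and rotation scheme as protocol 3.
#'
#' @param id protocol number, 1 to 4.
#' @param n_dirs rotations per set (default 45, as in the study design).
#' @param seed seed for the rotation scheme.
#' @param narrow_pulse if TRUE, realise the protocol with impulse gradients
#'   (`delta = 0`), e.g. to match narrow-pulse theory or the Kaerger oracle.
#' @param orth_reps second-pair directions per rotation for orthogonal DDE in
#'   protocols 3 and 4 (protocol 1 always uses 3, per the study design).
#' @return A tibble of class `ddex_protocol` with columns `protocol`,
#'   `set_id`, `b1`, `b2`, `theta`, `delta`, `Delta`, `tm`, `rot`,
#'   `d1x..d1z`, `d2x..d2z`, `b`, `b_shape`, `b_mu` and `shell` (an id shared
#'   by acquisitions that are powder-averaged together).
#' @examples
#' p1 <- build_protocol(1)
#' dplyr::count(p1, set_id)
#' @export
build_protocol <- function(id, n_dirs = 45L, seed = 0, narrow_pulse = FALSE,
                           orth_reps = 1L) {
  if (!id %in% 1:4) stop("unknown protocol id: ", id, call. = FALSE)
  dirs <- generate_directions(n_dirs, seed = seed)
  xyz <- as.matrix(dirs[, c("x", "y", "z")])
  delta <- if (narrow_pulse) 0 else if (id == 4) 15.8 else 3.5
  Delta <- if (id == 4) 31.8 else 12
  tm0 <- if (id == 4) 32.3 else 12

  rows <- switch(as.character(id),
    "1" = dplyr::bind_rows(
      proto_set(xyz, "set1_sde", 2.5, 0, 0, tm0),
      proto_set(xyz, "set2_par", 1.25, 1.25, 0, tm0),
      proto_set(xyz, "set3_orth", 1.25, 1.25, 90, tm0, orth_reps = 3L),
      proto_set(xyz, "set4_par", 0.5, 0.5, 0, tm0)
    ),
    "2" = dplyr::bind_rows(
      proto_set(xyz, "parallel", 1, 1, 0, tm0),
      proto_set(xyz, "antiparallel", 1, 1, 180, tm0)
    ),
    "3" = proto_var_tm(xyz,
      tms = c(1, 4, 8, 12, 16, 20, 30, 50, 100, 200, 300),
      bs = c(0.25, 0.5, 1, 1.5, 2, 2.5), tm_sde = tm0, orth_reps = orth_reps
    ),
    "4" = proto_var_tm(xyz,
      tms = c(1, 4, 8, 12, 16, 20, 32.3, 50, 100),
      bs = c(0.25, 0.5, 1, 1.5, 2, 2.5), tm_sde = tm0, orth_reps = orth_reps
    )
  )
  out <- rows %>%
    dplyr::mutate(
      protocol = id, delta = delta, Delta = Delta,
      b = .data$b1 + .data$b2,
      b_shape = b_shape_closed(.data$b1, .data$b2, .data$theta),
      b_mu = b_mu_closed(.data$b1, .data$b2),
      shell = paste(.data$set_id, .data$b, .data$tm, sep = "|")
    ) %>%
    dplyr::relocate("protocol")
  class(out) <- c("ddex_protocol", class(out))
  out
}

# one acquisition set: every rotation, optional multiple second-pair directions
proto_set <- function(xyz, set_id, b1, b2, theta, tm, orth_reps = 1L) {
  n <- nrow(xyz)
  rows <- vector("list", n * orth_reps)
  idx <- 1L
  for (r in seq_len(n)) {
    d1 <- xyz[r, ]
    for (j in seq_len(orth_reps)) {
      d2 <- second_dir(d1, theta, j, orth_reps)
      rows[[idx]] <- tibble::tibble(
        set_id = set_id, b1 = b1, b2 = b2, theta = theta, tm = tm,
        rot = r, rep = j,
        d1x = d1[1], d1y = d1[2], d1z = d1[3],
        d2x = d2[1], d2y = d2[2], d2z = d2[3]
      )
      idx <- idx + 1L
    }
  }
  dplyr::bind_rows(rows)
}

# second-pair direction: parallel/antiparallel reuse dir1; orthogonal uses
# vectors in the plane perpendicular to dir1, `orth_reps` of them 360/n apart
second_dir <- function(d1, theta, j, orth_reps) {
  if (theta == 0) return(d1)
  if (theta == 180) return(-d1)
  a <- if (abs(d1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  p <- a - sum(a * d1) * d1
  p <- p / sqrt(sum(p^2))
  q <- c(
    d1[2] * p[3] - d1[3] * p[2],
    d1[3] * p[1] - d1[1] * p[3],
    d1[1] * p[2] - d1[2] * p[1]
  )
  phi <- 2 * pi * (j - 1) / max(orth_reps, 1)
  perp <- cos(phi) * p + sin(phi) * q
  th <- theta * pi / 180
  cos(th) * d1 + sin(th) * perp
}

proto_var_tm <- function(xyz, tms, bs, tm_sde, orth_reps) {
  sde <- dplyr::bind_rows(lapply(bs, function(b) {
    proto_set(xyz, "sde", b, 0, 0, tm_sde)
  }))
  dde <- dplyr::bind_rows(lapply(tms, function(tm) {
    dplyr::bind_rows(lapply(bs, function(b) {
      dplyr::bind_rows(
        proto_set(xyz, "dde_par", b / 2, b / 2, 0, tm),
        proto_set(xyz, "dde_orth", b / 2, b / 2, 90, tm, orth_reps = orth_reps)
      )
    }))
  }))
  dplyr::bind_rows(sde, dde)
}

#' Realise every acquisition of a protocol row subset as waveforms
#'
#' @param protocol a [build_protocol()] tibble (or any subset of its rows).
#' @param dt sample interval (ms) for finite pulses.
#' @return list of `dde_waveform`, one per row.
#' @export
protocol_waveforms <- function(protocol, dt = 0.01) {
  purrr::pmap(
    list(protocol$b1, protocol$b2, protocol$delta, protocol$Delta, protocol$tm,
         protocol$d1x, protocol$d1y, protocol$d1z,
         protocol$d2x, protocol$d2y, protocol$d2z),
    function(b1, b2, delta, Delta, tm, x1, y1, z1, x2, y2, z2) {
      make_dde_waveform(
        dde_block(b1 = b1, b2 = b2, delta = delta, Delta = Delta, tm = tm,
                  dir1 = c(x1, y1, z1),
                  dir2 = if (b2 > 0) c(x2, y2, z2) else NULL),
        dt = dt
      )
    }
  )
}

#' Unique powder shells of a protocol
#'
#' One row per combination that is powder-averaged together: set, total b,
#' mixing time and pair geometry.
#'
#' @param protocol a [build_protocol()] tibble.
#' @return tibble with one row per shell, retaining timing and shape columns.
#' @export
protocol_shells <- function(protocol) {
  protocol %>%
    dplyr::distinct(
      .data$shell, .data$set_id, .data$b1, .data$b2, .data$b, .data$theta,
      .data$delta, .data$Delta, .data$tm, .data$b_shape, .data$b_mu
    )
}
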