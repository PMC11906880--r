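#' Read a protocol specification from YAML/JSON
#'
#' Accepts a file with keys `b1`, `b2`, `theta_deg`, `delta_ms`, `Delta_ms`,
#' `tm_ms`, `n_dirs`, `seed` (scalars or parallel lists defining several
#' sets), or a single key `protocol: <1-4>` plus options forwarded to
#' [build_protocol()].
#'
#' @param path YAML (or JSON) file.
#' @return an acquisition tibble as produced by [build_protocol()].
#' @export
read_protocol <- function(path) {
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(cfg$protocol)) {
    return(build_protocol(
      cfg$protocol,
      n_dirs = cfg$n_dirs %||% 45L,
      seed = cfg$seed %||% 0,
      narrow_pulse = isTRUE(cfg$narrow_pulse)
    ))
  }
  need <- c("b1", "b2", "theta_deg", "delta_ms", "Delta_ms", "tm_ms")
  if (!all(need %in% names(cfg))) {
    stop("protocol file needs keys ", paste(need, collapse = ", "), call. = FALSE)
  }
  sets <- tibble::tibble(
    b1 = cfg$b1, b2 = cfg$b2, theta = cfg$theta_deg,
    delta = cfg$delta_ms, Delta = cfg$Delta_ms, tm = cfg$tm_ms
  )
  dirs <- generate_directions(cfg$n_dirs %||% 45L, seed = cfg$seed %||% 0)
  xyz <- as.matrix(dirs[, c("x", "y", "z")])
  out <- purrr::pmap_dfr(sets, function(b1, b2, theta, delta, Delta, tm) {
    proto_set(xyz, sprintf("set_b%g_%g_t%g", b1, b2, theta),
              b1, b2, theta, tm) %>%
      dplyr::mutate(delta = delta, Delta = Delta)
  })
  out %>%
    dplyr::mutate(
      protocol = NA_integer_,
      b = .data$b1 + .data$b2,
      b_shape = b_shape_closed(.data$b1, .data$b2, .data$theta),
      b_mu = b_mu_closed(.data$b1, .data$b2),
      shell = paste(.data$set_id, .data$b, .data$tm, sep = "|")
    )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a sampled waveform as plain-text gradient files
#'
#' Two-file dialect: `<stem>.txt` holds the N x 3 gradient samples (T/m),
#' `<stem>_header.txt` the sample interval and duration. The gradient is the
#' time derivative of the stored dephasing vector divided by the proton
#' gyromagnetic ratio.
#'
#' @param w a `dde_waveform` (finite pulses).
#' @param stem output path stem.
#' @return invisibly, the gradient matrix.
#' @export
write_waveform_txt <- function(w, stem) {
  if (!is.null(w$steps)) {
    stop("narrow-pulse waveforms have no finite gradient representation", call. = FALSE)
  }
  gamma <- 267.522187 # rad / (ms mT/m) * 1e-3; q [1/um] = gamma g t
  # q in 1/um, t in ms: g [T/m] = dq/dt [1/(um ms)] / (2.6752e2 rad/ms/T/um)
  g <- rbind(w$q[1, ], diff(w$q)) / w$dt / gamma * 1e3
  utils::write.table(format(g, digits = 8), paste0(stem, ".txt"),
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(c(sprintf("dt_ms %g", w$dt), sprintf("T_ms %g", w$T),
               sprintf("n %d", nrow(w$q))), paste0(stem, "_header.txt"))
  invisible(g)
}

#' Write/read a signals table in the package's CSV schema
#'
#' Columns: set_id, rotation index, b1, b2, theta_deg, delta_ms, Delta_ms,
#' tm_ms, signal.
#'
#' @param signals acquisition tibble with a `signal` column.
#' @param path CSV path.
#' @export
write_signals_csv <- function(signals, path) {
  df <- signals %>%
    dplyr::transmute(
      set_id = .data$set_id, rotation_index = .data$rot,
      b1 = .data$b1, b2 = .data$b2, theta_deg = .data$theta,
      delta_ms = .data$delta, Delta_ms = .data$Delta, tm_ms = .data$tm,
      signal = .data$signal
    )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signals_csv
#' @return `read_signals_csv`: tibble with the package-internal column names
#'   (plus shape metrics), ready for [powder_average()].
#' @export
read_signals_csv <- function(path) {
  df <- utils::read.csv(path)
  tibble::as_tibble(df) %>%
    dplyr::transmute(
      set_id = .data$set_id, rot = .data$rotation_index,
      b1 = .data$b1, b2 = .data$b2, theta = .data$theta_deg,
      delta = .data$delta_ms, Delta = .data$Delta_ms, tm = .data$tm_ms,
      b = .data$b1 + .data$b2,
      b_shape = b_shape_closed(.data$b1, .data$b2, .data$theta),
      b_mu = b_mu_closed(.data$b1, .data$b2),
      signal = .data$signal
    )
}

#' Serialise a fit result to JSON
#' @param fit a `ddex_fit`.
#' @param path output path.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(
    list(
      model = fit$model,
      estimates = as.list(fit$estimates),
      k_per_s = if ("k" %in% names(fit$estimates))
        fit$estimates[["k"]] * ms_per_s else NULL,
      rss = fit$rss, n_starts = fit$n_starts,
      converged = fit$converged, seed = fit$seed,
      bounds = lapply(fit$bounds, as.list)
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
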