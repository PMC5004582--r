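#' Generate synthetic osmoshock datasets
#'
#' Stands in for experimental single-cell osmoshock measurements:
#' simulates a chosen scheme and parameter set for each step shock,
#' samples the normalized volume and Hog1 activation on a grid, and adds
#' independent Gaussian measurement noise per sample and channel. Volume
#' is 1 at `t = 0` before noise; the volume-clipping rule (samples above
#' 1 set to 1) is applied by default, mirroring the preprocessing used
#' when fitting.
#'
#' Noise here is measurement noise added after simulation, distinct from
#' the process noise of [simulate_noisy()]: the fitting cost compares
#' deterministic model output to noisy observations.
#'
#' @param scheme A [scheme_config()] generating the data.
#' @param params An [osmo_params()] set.
#' @param shocks Shock amplitudes in M NaCl (default the three standard
#'   step levels) or a list of [shock_input()]s.
#' @param times Sampling grid, minutes.
#' @param sigma_v,sigma_h Measurement noise standard deviations for
#'   volume and Hog1 (>= 0).
#' @param seed Optional RNG seed.
#' @param clip Apply the volume-clipping rule ([clip_volume()]).
#' @param t_on Shock onset (minutes) used when `shocks` is numeric.
#' @return A tibble with columns `shock_id` (NaCl molarity), `time`,
#'   `volume`, `hog1`, sorted by `(shock_id, time)`.
#' @examples
#' d <- generate_shock_data(scheme_config("UNF-UNF"), sigma_v = 0,
#'                          sigma_h = 0, seed = 1)
#' dplyr::count(d, shock_id)
#' @export
generate_shock_data <- function(scheme, params = osmo_params(),
                                shocks = c(0.2, 0.4, 0.6),
                                times = seq(0, 60, by = 2),
                                sigma_v = 0.01, sigma_h = 0.02,
                                seed = NULL, clip = TRUE, t_on = 5) {
  stopifnot(inherits(scheme, "scheme_config"), sigma_v >= 0, sigma_h >= 0,
            all(diff(times) > 0), min(times) >= 0)
  params <- validate_params(params)
  if (is.numeric(shocks)) {
    shocks <- purrr::map(shocks, shock_input, t_on = t_on)
  }
  if (!is.null(seed)) set.seed(seed)
  out <- purrr::map(shocks, function(sh) {
    traj <- tryCatch(
      .sample_trajectory(scheme, sh, params, times),
      error = function(e) {
        stop("simulation failed for shock ", sh$label, ": ",
             conditionMessage(e), call. = FALSE)
      }
    )
    tibble::tibble(
      shock_id = sh$amplitude_M,
      time = times,
      volume = traj$V + stats::rnorm(length(times), 0, sigma_v),
      hog1 = traj$uHOG + stats::rnorm(length(times), 0, sigma_h)
    )
  })
  out <- dplyr::arrange(dplyr::bind_rows(out), .data$shock_id, .data$time)
  if (clip) out <- clip_volume(out)
  out
}

# Deterministic model curves sampled exactly on `times`.
.sample_trajectory <- function(scheme, shock, params, times) {
  t_end <- max(times)
  if (scheme$hog_kind == "FINF") {
    traj <- simulate_osmo(scheme, shock, params, t_end = t_end,
                          dt = min(diff(times), 0.25), method = "fixed")
    tibble::tibble(
      V = stats::approx(traj$time, traj$V, xout = times)$y,
      uHOG = stats::approx(traj$time, traj$uHOG, xout = times)$y
    )
  } else {
    y0 <- equilibrium_state(params)
    pv <- .osmo_parms_vector(scheme, shock, params)
    grid <- if (min(times) > 0) c(0, times) else times
    sol <- .lsoda_osmo(pv, y0, grid, rtol = 1e-8, atol = 1e-10)
    keep <- match(times, grid)
    tibble::tibble(V = sol[keep, 2], uHOG = sol[keep, 3])
  }
}

#' Write or read osmoshock datasets as CSV
#'
#' The shared dataset dialect has the header
#' `shock_id,time,volume,hog1`, with `shock_id` the NaCl molarity of the
#' shock. Reading canonicalizes row order by `(shock_id, time)`, so a
#' file with shuffled rows yields the same dataset.
#'
#' @param data A dataset tibble (`shock_id`, `time`, `volume`, `hog1`).
#' @param path File path.
#' @return `write_shock_data` returns `path` invisibly;
#'   `read_shock_data` returns the canonical tibble.
#' @export
write_shock_data <- function(data, path) {
  stopifnot(all(c("shock_id", "time", "volume", "hog1") %in% names(data)))
  utils::write.csv(
    as.data.frame(data)[, c("shock_id", "time", "volume", "hog1")],
    path, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_shock_data
#' @export
read_shock_data <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character")
  need <- c("shock_id", "time", "volume", "hog1")
  if (!all(need %in% names(raw))) {
    stop("malformed dataset CSV: expected header ",
         paste(need, collapse = ","), call. = FALSE)
  }
  out <- raw[need]
  for (col in need) {
    vals <- suppressWarnings(as.numeric(out[[col]]))
    bad <- which(is.na(vals) & nzchar(trimws(out[[col]])) |
                   !nzchar(trimws(out[[col]])))
    if (length(bad)) {
      stop("malformed dataset CSV: non-numeric ", col, " at line ",
           bad[1] + 1L, call. = FALSE)  # +1 for the header line
    }
    out[[col]] <- vals
  }
  dplyr::arrange(tibble::as_tibble(out), .data$shock_id, .data$time)
}
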