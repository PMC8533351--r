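#' Simulate a ventricle geometry series
#'
#' Major and minor ventricular diameters oscillate between their diastolic
#' values and the systolic values `D_d * (1 - FS)` following the beat
#' kernel; the cavity area is the ellipse area `(pi/4) * major * minor` per
#' frame. Frames at the kernel extrema are labelled `end_diastole` /
#' `end_systole`, and at those labelled frames the exact extremal diameters
#' are emitted (the labelled frames represent the captured extrema), so
#' fractional shortening recovered from the labels equals the input exactly.
#'
#' @param config A [sim_config()] (beat times and transient kernel).
#' @param fs_major,fs_minor Fractional shortening along each axis, in (0, 1).
#' @param dd_major,dd_minor End-diastolic diameters (um).
#' @param geom_freq Frame rate of the geometry series (Hz), default 50 (the
#'   transmitted-light video rate).
#' @return An object of class `geometry_trace`: data frame with `frame`,
#'   `time_s`, `major_um`, `minor_um`, `area_um2`, `phase` (`""`,
#'   `"end_diastole"` or `"end_systole"`).
#' @examples
#' g <- simulate_geometry(sim_config(duration = 5), 0.28, 0.33, 130, 80)
#' table(g$phase)
#' @export
simulate_geometry <- function(config, fs_major = 0.28, fs_minor = 0.33,
                              dd_major = 130, dd_minor = 80,
                              geom_freq = 50) {
  stopifnot(inherits(config, "sim_config"))
  for (fs in c(fs_major, fs_minor))
    if (!is.numeric(fs) || fs <= 0 || fs >= 1)
      stop("fractional shortening must lie in (0, 1)", call. = FALSE)
  if (dd_major <= 0 || dd_minor <= 0)
    stop("diameters must be positive", call. = FALSE)

  gt <- simulate_ca_trace(config)
  beats <- gt$beat_times_ventricle
  t_end <- gt$n_frames / config$acq_freq
  tt <- seq(0, t_end, by = 1 / geom_freq)
  pk <- beat_kernel_peak(config$tau_rise, config$tau_decay)

  kern <- vapply(tt, function(t) {
    u <- t - beats[beats <= t]
    if (!length(u)) 0 else
      min(1, max(beat_kernel(u, config$tau_rise, config$tau_decay)))
  }, numeric(1))

  phase <- rep("", length(tt))
  # end-systole: frame nearest each beat's kernel peak; end-diastole: frame
  # nearest beat onset (kernel at its minimum before contraction)
  for (tk in beats) {
    i_sys <- which.min(abs(tt - (tk + pk$u_peak)))
    i_dia <- which.min(abs(tt - tk))
    if (tk + pk$u_peak <= t_end) {
      phase[i_sys] <- "end_systole"
      kern[i_sys] <- 1
    }
    if (phase[i_dia] == "") {
      phase[i_dia] <- "end_diastole"
      kern[i_dia] <- 0
    }
  }

  major <- dd_major * (1 - fs_major * kern)
  minor <- dd_minor * (1 - fs_minor * kern)
  out <- data.frame(frame = seq_along(tt),
                    time_s = tt,
                    major_um = major,
                    minor_um = minor,
                    area_um2 = pi / 4 * major * minor,
                    phase = phase)
  class(out) <- c("geometry_trace", "data.frame")
  out
}

#' Read / write geometry CSV
#'
#' Shared dialect: columns `frame`, `time_s`, `major_um`, `minor_um`,
#' `area_um2`, `phase`.
#'
#' @param path CSV path.
#' @return A `geometry_trace` data frame.
#' @export
read_geometry_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "time_s", "major_um", "minor_um", "area_um2", "phase")
  if (!all(need %in% names(df)))
    stop("geometry CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  df$phase[is.na(df$phase)] <- ""
  class(df) <- c("geometry_trace", "data.frame")
  df
}

#' @rdname read_geometry_csv
#' @param geom A `geometry_trace`.
#' @export
write_geometry_csv <- function(geom, path) {
  utils::write.csv(as.data.frame(geom), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
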