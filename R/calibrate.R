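#' Per-frame signal-to-noise ratio from background regions
#'
#' SNR for each frame is `(Signal - Background) / SD(Background)`, where
#' Background is the mean over the background ROI values at that frame and
#' SD their sample standard deviation (n - 1). The statistics are computed
#' across regions per frame, not pooled over time. Frames where the
#' background SD is zero are masked with a warning.
#'
#' @param signal A [lum_trace()] from the chamber ROI.
#' @param backgrounds A list of >= 2 [lum_trace()]s from equal-sized
#'   background ROIs (six in the standard protocol).
#' @return An object of class `snr_trace`: list with `snr`,
#'   `background_mean`, `background_sd` (per frame), `masked` (logical),
#'   and scalar `summary_mean`, `summary_max`.
#' @examples
#' sig <- lum_trace(c(110, 110), 1)
#' bgs <- lapply(1:6, function(i) lum_trace(c(10, 10) + c(-5, 5) * (i %% 2), 1))
#' compute_snr(sig, bgs)$snr
#' @export
compute_snr <- function(signal, backgrounds) {
  stopifnot(inherits(signal, "lum_trace"), is.list(backgrounds))
  if (length(backgrounds) < 2L)
    stop("at least 2 background traces are required", call. = FALSE)
  n <- length(signal$values)
  for (b in backgrounds) {
    if (!inherits(b, "lum_trace") || length(b$values) != n ||
        abs(b$sampling_rate - signal$sampling_rate) > 1e-9)
      stop("all traces must share length and sampling rate", call. = FALSE)
  }
  bg <- vapply(backgrounds, function(b) b$values, numeric(n))
  bg_mean <- rowMeans(bg)
  bg_sd <- apply(bg, 1L, stats::sd)
  masked <- bg_sd == 0
  if (any(masked))
    warning(sprintf("%d frame(s) with zero background SD masked", sum(masked)),
            call. = FALSE)
  snr <- (signal$values - bg_mean) / bg_sd
  snr[masked] <- NA_real_
  structure(
    list(snr = snr, background_mean = bg_mean, background_sd = bg_sd,
         masked = masked,
         summary_mean = mean(snr, na.rm = TRUE),
         summary_max = if (all(masked)) NA_real_ else max(snr, na.rm = TRUE)),
    class = "snr_trace"
  )
}

#' @export
print.snr_trace <- function(x, ...) {
  cat(sprintf("<snr_trace> %d frames | mean SNR %.2f | max SNR %.2f\n",
              length(x$snr), x$summary_mean, x$summary_max))
  invisible(x)
}

#' Aequorin luminescence budget calibration
#'
#' Transforms a raw luminescence recording into the photoprotein budget and
#' the consumption-corrected, Ca2+-proportional signal. Per frame:
#' background-subtracted counts `raw[t] = max(signal[t] - background[t], 0)`;
#' luminescence rate `L[t] = raw[t] * sampling_rate` (counts/s); total
#' counts `Ltotal = sum(raw)` over the whole experiment (detergent-release
#' frames included); cumulative consumption `Lconsumed[t] = sum(raw[1..t])`;
#' remaining pool entering frame t `Lmax[t] = Ltotal - Lconsumed[t-1]`; and
#' `ratio[t] = L[t] / Lmax[t]` (1/s). The ratio is masked where the
#' remaining pool falls below `max(mask_floor_frac * Ltotal,
#' mask_floor_counts)`, where the signal is noise-dominated.
#'
#' The budget identity `Lmax[t] + Lconsumed[t-1] = Ltotal` holds for every
#' frame, and the ratio is invariant under scaling of the input trace:
#' L/Lmax does not depend on the total amount of functional aequorin.
#'
#' @param trace A [lum_trace()] of per-frame RLU counts covering the full
#'   experiment. If no `triton_index` is given the remaining pool at the end
#'   of the recording is unobserved and `Lmax` is underestimated; a warning
#'   is issued.
#' @param background Scalar, per-frame numeric vector, or [lum_trace()] of
#'   background counts to subtract; `0` (or `subtract_background = FALSE`)
#'   disables subtraction.
#' @param triton_index Frame index at which detergent lysis released the
#'   remaining pool, or `NULL`.
#' @param subtract_background Logical master switch for the subtraction.
#' @param mask_floor_frac,mask_floor_counts Masking floor for the remaining
#'   pool (fraction of `Ltotal`, and absolute counts).
#' @return An object of class `lum_calibration`: list with a `frames` data
#'   frame (`frame`, `time_s`, `raw_counts`, `L_cps`, `Lconsumed`, `Lmax`,
#'   `ratio_per_s`, `masked`), scalar `Ltotal`, `triton_index`,
#'   `sampling_rate`.
#' @examples
#' tr <- lum_trace(rep(1, 10), sampling_rate = 1)
#' cal <- calibrate_luminescence(tr, triton_index = 10)
#' cal$frames$Lmax      # 10, 9, ..., 1
#' @export
calibrate_luminescence <- function(trace, background = 0, triton_index = NULL,
                                   subtract_background = TRUE,
                                   mask_floor_frac = 0.001,
                                   mask_floor_counts = 10) {
  stopifnot(inherits(trace, "lum_trace"))
  v <- trace$values
  n <- length(v)
  bg <- if (inherits(background, "lum_trace")) background$values else background
  if (length(bg) == 1L) bg <- rep(bg, n)
  if (length(bg) != n)
    stop("`background` must be scalar or match the trace length", call. = FALSE)
  if (!subtract_background) bg <- rep(0, n)

  resid <- v - bg
  raw <- pmax(resid, 0)
  clipped <- mean(resid < 0)
  if (clipped > 0.5)
    warning(sprintf(
      "%.0f%% of frames fell below background and were clipped to 0",
      100 * clipped), call. = FALSE)

  ltotal <- sum(raw)
  if (ltotal == 0) stop("no luminescence: total counts are zero", call. = FALSE)
  if (is.null(triton_index))
    warning(paste("no detergent-release (Triton) segment: Lmax reflects only",
                  "the counts emitted during the recording and underestimates",
                  "the remaining aequorin pool"), call. = FALSE)

  lconsumed <- cumsum(raw)
  lmax <- ltotal - c(0, lconsumed[-n])
  l_cps <- raw * trace$sampling_rate
  ratio <- l_cps / lmax
  floor_counts <- max(mask_floor_frac * ltotal, mask_floor_counts)
  masked <- lmax < floor_counts
  ratio[masked] <- NA_real_

  structure(
    list(frames = data.frame(frame = seq_len(n),
                             time_s = trace_times(trace),
                             raw_counts = raw,
                             L_cps = l_cps,
                             Lconsumed = lconsumed,
                             Lmax = lmax,
                             ratio_per_s = ratio,
                             masked = masked),
         Ltotal = ltotal,
         triton_index = triton_index,
         sampling_rate = trace$sampling_rate),
    class = "lum_calibration"
  )
}

#' @export
print.lum_calibration <- function(x, ...) {
  cat(sprintf(
    "<lum_calibration> %d frames @ %g Hz | Ltotal %.0f RLU | %d masked | triton: %s\n",
    nrow(x$frames), x$sampling_rate, x$Ltotal, sum(x$frames$masked),
    if (is.null(x$triton_index)) "none" else x$triton_index))
  invisible(x)
}

#' Time-averaged L/Lmax over a window
#'
#' Arithmetic mean of the calibrated ratio over a time window, the
#' "time-averaged Ca2+ level" readout used at 1-2 Hz acquisition. Masked
#' frames are excluded; a fully masked window is an error.
#'
#' @param cal A [calibrate_luminescence()] result.
#' @param window `c(t0, t1)` in seconds (inclusive), or `NULL` for the whole
#'   recording.
#' @return Mean ratio (1/s).
#' @export
summarize_ratio <- function(cal, window = NULL) {
  stopifnot(inherits(cal, "lum_calibration"))
  f <- cal$frames
  keep <- !f$masked
  if (!is.null(window)) {
    stopifnot(length(window) == 2L, window[2L] >= window[1L])
    keep <- keep & f$time_s >= window[1L] & f$time_s <= window[2L]
  }
  if (!any(keep))
    stop("window contains no unmasked frames", call. = FALSE)
  mean(f$ratio_per_s[keep])
}

#' Write a calibration to CSV
#' @param cal A [calibrate_luminescence()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calibration_csv <- function(cal, path) {
  df <- cal$frames
  df$masked <- as.integer(df$masked)
  names(df)[names(df) == "masked"] <- "masked_flag"
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
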