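#' Render a luminescence recording as a 16-bit image stack
#'
#' Emulates the EM-CCD view of the larva: each frame is a 16-bit grayscale
#' image with elliptical ventricle and atrium regions. Each chamber's
#' expected per-frame counts are spread uniformly over its mask pixels and
#' drawn Poisson per pixel; per-pixel Poisson background is added everywhere
#' at `bg_rate / acq_freq` counts per ventricle-ROI-sized area, so any ROI of
#' that size collects the configured background. The ventricle ellipse can
#' pulsate between its diastolic and systolic axes in sync with beat times.
#' Camera gain and binning are not modelled; they are absorbed into the
#' configured detection efficiency and read noise.
#'
#' @param ventricle_counts Expected ventricle counts per frame (numeric,
#'   non-negative); typically the `expected` component of
#'   [simulate_luminescence()].
#' @param config A [sim_config()].
#' @param path Output TIFF path, or `NULL` to return frames only.
#' @param atrium_counts Optional expected atrial counts per frame.
#' @param dim Image size `(rows, cols)`, default 128 x 128.
#' @param beat_times Ventricular beat times (s) used when `pulsate = TRUE`.
#' @param pulsate Logical: shrink the ventricle axes by `fs_pulse` at
#'   systole following the beat kernel.
#' @param fs_pulse Fractional shortening of the pulsating ellipse axes.
#' @param roi_path Optional path for the emitted ROI JSON
#'   (ventricle, atrium, background_1..6).
#' @return Invisible list with `frames` (list of integer matrices), `rois`
#'   (list of [roi_spec()]s), `n_saturated` (pixels clamped at 65535), and
#'   the paths written.
#' @export
render_image_stack <- function(ventricle_counts, config, path = NULL,
                               atrium_counts = NULL, dim = c(128L, 128L),
                               beat_times = NULL, pulsate = FALSE,
                               fs_pulse = 0.25, roi_path = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (any(ventricle_counts < 0))
    stop("frame counts must be non-negative", call. = FALSE)
  n_frames <- length(ventricle_counts)
  nr <- dim[1L]; nc <- dim[2L]

  vent_center <- c(nr * 0.55, nc * 0.42)
  vent_axes_d <- c(nr * 0.12, nc * 0.16)
  atr_center <- c(nr * 0.38, nc * 0.62)
  atr_axes <- c(nr * 0.08, nc * 0.10)

  vent_roi <- roi_ellipse("ventricle", vent_center, vent_axes_d)
  atr_roi <- roi_ellipse("atrium", atr_center, atr_axes)
  vent_mask <- roi_mask(vent_roi, nr, nc)
  atr_mask <- roi_mask(atr_roi, nr, nc)
  n_vent_px <- sum(vent_mask)

  # background ROIs: six equal squares (same pixel area as the ventricle
  # mask, like-for-like with the chamber ROI), three along the top edge and
  # three along the bottom, clear of both chambers
  side <- max(3L, min(floor(sqrt(n_vent_px)), floor(nr / 4), floor((nc - 14L) / 3)))
  bg_rois <- lapply(seq_len(6L), function(i) {
    col_i <- (i - 1L) %% 3L
    x0 <- 2L + col_i * (side + 4L)
    y0 <- if (i <= 3L) 2L else nr - 2L - side
    roi_rect(paste0("background_", i), y0, y0 + side - 1L, x0, x0 + side - 1L,
             reduction = "sum")
  })

  bg_per_px <- config$bg_rate / config$acq_freq / n_vent_px
  if (!is.null(config$seed)) set.seed(config$seed + 7L)

  pulse <- NULL
  if (pulsate) {
    if (is.null(beat_times))
      stop("`beat_times` required when `pulsate = TRUE`", call. = FALSE)
    tmid <- (seq_len(n_frames) - 0.5) / config$acq_freq
    pulse <- vapply(tmid, function(t) {
      u <- t - beat_times[beat_times <= t]
      if (!length(u)) 0 else
        max(beat_kernel(u, config$tau_rise, config$tau_decay))
    }, numeric(1))
    pulse <- pmin(pulse, 1)
  }

  n_saturated <- 0L
  frames <- vector("list", n_frames)
  for (k in seq_len(n_frames)) {
    img <- matrix(stats::rpois(nr * nc, bg_per_px), nr, nc)
    vm <- vent_mask
    if (pulsate && pulse[k] > 0) {
      vm <- roi_mask(roi_ellipse("ventricle", vent_center,
                                 vent_axes_d * (1 - fs_pulse * pulse[k])),
                     nr, nc)
    }
    npx <- sum(vm)
    img[vm] <- img[vm] + stats::rpois(npx, ventricle_counts[k] / npx)
    if (!is.null(atrium_counts)) {
      na_px <- sum(atr_mask)
      img[atr_mask] <- img[atr_mask] +
        stats::rpois(na_px, atrium_counts[k] / na_px)
    }
    sat <- img > 65535L
    if (any(sat)) {
      n_saturated <- n_saturated + sum(sat)
      img[sat] <- 65535L
    }
    frames[[k]] <- img
  }
  if (n_saturated > 0L)
    warning(sprintf("%d pixels exceeded 65535 and were clamped", n_saturated),
            call. = FALSE)

  rois <- c(list(vent_roi, atr_roi), bg_rois)
  if (!is.null(path))
    tiff::writeTIFF(lapply(frames, function(f) f / 65535),
                    path, bits.per.sample = 16)
  if (!is.null(roi_path)) write_roi_json(rois, roi_path)

  invisible(list(frames = frames, rois = rois, n_saturated = n_saturated,
                 tiff_path = path, roi_path = roi_path))
}
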