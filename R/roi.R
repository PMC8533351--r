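#' Region-of-interest specification
#'
#' Polygonal region in 0-based, row-major pixel coordinates (y, x). Pixel
#' membership is decided by pixel-centre inclusion: pixel (r, c) of the
#' image (1-based R indexing) has centre (y, x) = (r - 1, c - 1).
#'
#' @param label ROI label: `"ventricle"`, `"atrium"`, `"background_1"` ..
#'   `"background_6"`, or a custom string.
#' @param polygon Numeric matrix with >= 3 rows and 2 columns `(y, x)`.
#' @param reduction Per-frame pixel reduction: `"sum"` (default, for
#'   luminescence budgets) or `"mean"` (for SNR inputs).
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(label, polygon, reduction = c("sum", "mean")) {
  reduction <- match.arg(reduction)
  polygon <- as.matrix(polygon)
  if (ncol(polygon) != 2L || nrow(polygon) < 3L)
    stop("`polygon` must be a (y, x) matrix with >= 3 vertices", call. = FALSE)
  if (any(!is.finite(polygon)) || any(polygon < -0.5))
    stop("polygon vertices must be finite and inside image bounds",
         call. = FALSE)
  structure(list(label = as.character(label)[1L],
                 polygon = unname(polygon),
                 reduction = reduction),
            class = "roi_spec")
}

#' Rectangular ROI covering whole pixels
#'
#' Convenience constructor: covers pixel centres `y0..y1` x `x0..x1`
#' (0-based, inclusive) with a half-pixel margin so inclusion is unambiguous.
#'
#' @param label ROI label.
#' @param y0,y1,x0,x1 0-based pixel index range (inclusive).
#' @param reduction `"sum"` or `"mean"`.
#' @return An [roi_spec()].
#' @export
roi_rect <- function(label, y0, y1, x0, x1, reduction = "sum") {
  roi_spec(label,
           rbind(c(y0 - 0.5, x0 - 0.5), c(y0 - 0.5, x1 + 0.5),
                 c(y1 + 0.5, x1 + 0.5), c(y1 + 0.5, x0 - 0.5)),
           reduction = reduction)
}

#' Elliptical ROI
#'
#' Polygonal approximation (default 48 vertices) of an ellipse.
#'
#' @param label ROI label.
#' @param center `(y, x)` centre in 0-based pixel coordinates.
#' @param semi_axes `(a_y, a_x)` semi-axes in pixels.
#' @param n_vertices Number of polygon vertices.
#' @param reduction `"sum"` or `"mean"`.
#' @return An [roi_spec()].
#' @export
roi_ellipse <- function(label, center, semi_axes, n_vertices = 48L,
                        reduction = "sum") {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  roi_spec(label,
           cbind(center[1L] + semi_axes[1L] * sin(th),
                 center[2L] + semi_axes[2L] * cos(th)),
           reduction = reduction)
}

# Logical mask of pixels whose centres fall inside the ROI polygon.
roi_mask <- function(roi, nrow, ncol) {
  stopifnot(inherits(roi, "roi_spec"))
  centers <- cbind(rep(seq_len(nrow) - 1, times = ncol),
                   rep(seq_len(ncol) - 1, each = nrow))
  inside <- mgcv::in.out(roi$polygon, centers)
  matrix(inside, nrow = nrow, ncol = ncol)
}

#' Write ROI specifications to JSON
#'
#' JSON list of `{label, polygon, reduction}` objects; polygons are lists of
#' `(y, x)` vertices in 0-based pixel coordinates (row-major convention).
#'
#' @param rois A list of [roi_spec()]s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_roi_json <- function(rois, path) {
  payload <- lapply(rois, function(r) {
    list(label = r$label,
         polygon = lapply(seq_len(nrow(r$polygon)),
                          function(i) as.numeric(r$polygon[i, ])),
         reduction = r$reduction)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read ROI specifications from JSON
#' @param path Path written by [write_roi_json()].
#' @return A list of [roi_spec()]s.
#' @export
read_roi_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(payload, function(r) {
    poly <- do.call(rbind, lapply(r$polygon, as.numeric))
    roi_spec(r$label, poly, reduction = r$reduction)
  })
}

#' Extract a per-frame trace from an image stack
#'
#' Reduces the pixels inside an ROI polygon (pixel-centre inclusion) to one
#' value per frame: `sum` by default for luminescence budgets, `mean` for
#' SNR inputs.
#'
#' @param stack Path to a multi-page TIFF, or a list of integer matrices.
#' @param roi An [roi_spec()].
#' @param sampling_rate Acquisition rate of the stack (Hz).
#' @param start_time Time of the first frame (s).
#' @return A [lum_trace()] in RLU.
#' @export
extract_trace <- function(stack, roi, sampling_rate, start_time = 0) {
  frames <- read_stack(stack)
  d <- dim(frames[[1L]])
  if (any(vapply(frames, function(f) !identical(dim(f), d), logical(1))))
    stop("frame shape mismatch in image stack", call. = FALSE)
  mask <- roi_mask(roi, d[1L], d[2L])
  if (!any(mask))
    stop("empty mask: ROI contains no pixel centres inside the image",
         call. = FALSE)
  red <- if (roi$reduction == "sum") sum else mean
  vals <- vapply(frames, function(f) red(f[mask]), numeric(1))
  lum_trace(vals, sampling_rate, start_time = start_time, units = "RLU")
}

# Read a stack as a list of numeric matrices (16-bit integer scale).
read_stack <- function(stack) {
  if (is.character(stack)) {
    frames <- tiff::readTIFF(stack, all = TRUE, as.is = TRUE)
    if (!is.list(frames)) frames <- list(frames)
    lapply(frames, function(f) {
      if (length(dim(f)) == 3L) f <- f[, , 1L]
      f
    })
  } else if (is.list(stack)) {
    stack
  } else if (is.matrix(stack)) {
    list(stack)
  } else {
    stop("`stack` must be a TIFF path or a list of matrices", call. = FALSE)
  }
}
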