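#' Uniformly sampled time-series trace
#'
#' The common currency of all pipeline stages: a numeric signal sampled at a
#' fixed rate, with a declared unit. Luminescence traces carry per-frame
#' counts (RLU); fluorescence traces carry arbitrary intensity units.
#'
#' @param values Numeric vector of per-frame values (length >= 2).
#' @param sampling_rate Sampling rate in Hz (frames per second), > 0.
#' @param start_time Time of the first frame in seconds.
#' @param units Unit label, e.g. `"RLU"`, `"counts_per_s"`, `"AU"`,
#'   `"per_s"`, `"dimensionless"`.
#' @return An object of class `lum_trace`.
#' @examples
#' tr <- lum_trace(c(5, 7, 6, 8), sampling_rate = 2, units = "RLU")
#' trace_times(tr)
#' @export
lum_trace <- function(values, sampling_rate, start_time = 0, units = "RLU") {
  if (!is.numeric(values) || length(values) < 2L)
    stop("`values` must be a numeric vector of length >= 2", call. = FALSE)
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0)
    stop("`sampling_rate` must be a single positive number (Hz)", call. = FALSE)
  structure(
    list(values = as.numeric(values),
         sampling_rate = as.numeric(sampling_rate),
         start_time = as.numeric(start_time),
         units = as.character(units)[1L]),
    class = "lum_trace"
  )
}

#' Frame times of a trace
#' @param trace A [lum_trace()].
#' @return Numeric vector of frame start times (s).
#' @export
trace_times <- function(trace) {
  stopifnot(inherits(trace, "lum_trace"))
  trace$start_time + (seq_along(trace$values) - 1L) / trace$sampling_rate
}

#' @export
length.lum_trace <- function(x) length(x$values)

#' @export
print.lum_trace <- function(x, ...) {
  cat(sprintf("<lum_trace> %d frames @ %g Hz, units = %s, t = [%.3f, %.3f] s\n",
              length(x$values), x$sampling_rate, x$units,
              x$start_time,
              x$start_time + (length(x$values) - 1L) / x$sampling_rate))
  invisible(x)
}

#' @export
as.data.frame.lum_trace <- function(x, ...) {
  data.frame(time_s = trace_times(x), value = x$values, units = x$units)
}

#' Read a trace from CSV
#'
#' Expects the shared headerful dialect: columns `time_s`, `value`, and
#' optionally `units`. The sampling rate is inferred from the (uniform)
#' time stamps.
#'
#' @param path Path to a CSV file.
#' @return A [lum_trace()].
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "value") %in% names(df)))
    stop("trace CSV must have columns `time_s` and `value`", call. = FALSE)
  dt <- diff(df$time_s)
  if (length(dt) < 1L || any(dt <= 0))
    stop("trace CSV time stamps must be strictly increasing", call. = FALSE)
  if (diff(range(dt)) > 1e-6 * mean(dt))
    stop("trace CSV is not uniformly sampled", call. = FALSE)
  units <- if ("units" %in% names(df)) df$units[1L] else "RLU"
  lum_trace(df$value, sampling_rate = 1 / mean(dt),
            start_time = df$time_s[1L], units = units)
}

#' Write a trace to CSV
#' @param trace A [lum_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
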