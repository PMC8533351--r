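#' Ventricular volume from the ellipsoid-of-revolution approximation
#'
#' `Volume = (pi/6) * major * minor^2` in cubic micrometres, reported in
#' picolitres (1 pL = 1000 um^3).
#'
#' @param major,minor Diameters (um), vectorised.
#' @param units `"pL"` (default) or `"um3"`.
#' @return Numeric volume(s).
#' @examples
#' ellipsoid_volume(130, 80)          # ~435 pL
#' ellipsoid_volume(100, 80, "um3")   # ~335103 um^3
#' @export
ellipsoid_volume <- function(major, minor, units = c("pL", "um3")) {
  units <- match.arg(units)
  if (any(major <= 0) || any(minor <= 0))
    stop("diameters must be positive", call. = FALSE)
  v <- pi / 6 * major * minor^2
  if (units == "pL") v / 1000 else v
}

#' Per-larva hemodynamic record
#'
#' Averages the end-diastolic and end-systolic diameters and areas over the
#' labelled frame pairs (three pairs by default, matching the three images
#' measured per larva), then derives fractional shortening along each axis,
#' fractional area change, ellipsoid volumes, stroke volume, ejection
#' fraction and cardiac output:
#' `FS = (D_dia - D_sys)/D_dia`, `FAC = (A_dia - A_sys)/A_dia`,
#' `SV = EDV - ESV`, `EF = SV/EDV`, `CO = SV * HR` (reported in nL/min).
#' Pairs where a systolic measure exceeds its diastolic one are flagged and
#' excluded with a warning.
#'
#' @param geom A `geometry_trace` (from [simulate_geometry()] or
#'   [read_geometry_csv()]) with labelled `end_diastole` / `end_systole`
#'   frames.
#' @param hr Ventricular heart rate (bpm).
#' @param atrial_hr Optional atrial heart rate (bpm) for the
#'   atrio-ventricular ratio; luminescence often cannot resolve the atrium,
#'   in which case the ratio is `NA`.
#' @param n_pairs Number of diastole/systole pairs to average (default 3;
#'   all available pairs if fewer).
#' @return An object of class `hemo_record`: list with `fs_major`,
#'   `fs_minor`, `fac`, `edv_pl`, `esv_pl`, `sv_pl`, `hr_bpm`, `co_nl_min`,
#'   `ef`, `av_ratio`, `n_pairs_used`.
#' @export
compute_record <- function(geom, hr, atrial_hr = NULL, n_pairs = 3L) {
  stopifnot(inherits(geom, "geometry_trace") || is.data.frame(geom))
  if (!is.numeric(hr) || hr <= 0) stop("`hr` must be > 0", call. = FALSE)
  dia_idx <- which(geom$phase == "end_diastole")
  sys_idx <- which(geom$phase == "end_systole")
  # pair each end-systole with the nearest preceding end-diastole
  pairs <- do.call(rbind, lapply(sys_idx, function(i) {
    prev <- dia_idx[dia_idx < i]
    if (!length(prev)) return(NULL)
    c(dia = max(prev), sys = i)
  }))
  if (is.null(pairs) || nrow(pairs) < 1L)
    stop("no end-diastole/end-systole pairs labelled in the geometry",
         call. = FALSE)
  pairs <- pairs[!duplicated(pairs[, "dia"]), , drop = FALSE]

  ok <- geom$major_um[pairs[, "sys"]] <= geom$major_um[pairs[, "dia"]] &
    geom$minor_um[pairs[, "sys"]] <= geom$minor_um[pairs[, "dia"]] &
    geom$area_um2[pairs[, "sys"]] <= geom$area_um2[pairs[, "dia"]]
  if (any(!ok)) {
    warning(sprintf("%d pair(s) with systolic > diastolic measure excluded",
                    sum(!ok)), call. = FALSE)
    pairs <- pairs[ok, , drop = FALSE]
  }
  if (nrow(pairs) < 1L)
    stop("no valid diastole/systole pairs remain", call. = FALSE)
  use <- utils::head(seq_len(nrow(pairs)), n_pairs)
  pairs <- pairs[use, , drop = FALSE]

  dd_maj <- mean(geom$major_um[pairs[, "dia"]])
  ds_maj <- mean(geom$major_um[pairs[, "sys"]])
  dd_min <- mean(geom$minor_um[pairs[, "dia"]])
  ds_min <- mean(geom$minor_um[pairs[, "sys"]])
  ad <- mean(geom$area_um2[pairs[, "dia"]])
  as_ <- mean(geom$area_um2[pairs[, "sys"]])

  edv <- ellipsoid_volume(dd_maj, dd_min)
  esv <- ellipsoid_volume(ds_maj, ds_min)
  sv <- edv - esv
  structure(
    list(fs_major = (dd_maj - ds_maj) / dd_maj,
         fs_minor = (dd_min - ds_min) / dd_min,
         fac = (ad - as_) / ad,
         edv_pl = edv,
         esv_pl = esv,
         sv_pl = sv,
         hr_bpm = hr,
         co_nl_min = sv * hr / 1000,
         ef = sv / edv,
         av_ratio = if (is.null(atrial_hr)) NA_real_ else hr / atrial_hr,
         n_pairs_used = nrow(pairs)),
    class = "hemo_record"
  )
}

#' @export
print.hemo_record <- function(x, ...) {
  cat(sprintf(paste0(
    "<hemo_record> FS %.2f/%.2f | FAC %.2f | EDV %.1f pL, ESV %.1f pL\n",
    "  SV %.1f pL/beat | HR %.0f bpm | CO %.1f nL/min | EF %.2f | A/V %.2f\n"),
    x$fs_major, x$fs_minor, x$fac, x$edv_pl, x$esv_pl,
    x$sv_pl, x$hr_bpm, x$co_nl_min, x$ef, x$av_ratio))
  invisible(x)
}

#' @export
as.data.frame.hemo_record <- function(x, ...) {
  as.data.frame(unclass(x), stringsAsFactors = FALSE)
}

#' Two-group comparison with fold change
#'
#' Group means, sample SDs (n - 1), fold change of means
#' (`treated / control`), and a two-tailed Student's t-test (pooled
#' variance when unpaired, paired when `paired = TRUE`). Paired groups of
#' identical values are reported as `t = 0`, `p = 1`.
#'
#' @param control,treated Numeric vectors of a per-larva metric (n >= 2).
#' @param paired Logical; paired requires equal lengths.
#' @return An object of class `group_comparison`: list with `control_mean`,
#'   `control_sd`, `control_n`, `treated_*`, `fold_change`, `t`, `df`, `p`,
#'   `paired`.
#' @examples
#' compare_groups(rnorm(10, 100, 5), rnorm(10, 80, 5))
#' @export
compare_groups <- function(control, treated, paired = FALSE) {
  control <- as.numeric(control); treated <- as.numeric(treated)
  if (length(control) < 2L || length(treated) < 2L)
    stop("each group needs n >= 2", call. = FALSE)
  if (paired && length(control) != length(treated))
    stop("paired comparison requires equal group sizes", call. = FALSE)
  if (stats::sd(control) == 0 && stats::sd(treated) == 0 && !paired)
    stop("zero variance in both groups", call. = FALSE)

  if (paired && stats::sd(treated - control) == 0) {
    tt <- list(statistic = c(t = 0),
               parameter = c(df = length(control) - 1L),
               p.value = 1)
  } else {
    tt <- stats::t.test(treated, control, paired = paired, var.equal = TRUE)
  }
  structure(
    list(control_mean = mean(control), control_sd = stats::sd(control),
         control_n = length(control),
         treated_mean = mean(treated), treated_sd = stats::sd(treated),
         treated_n = length(treated),
         fold_change = mean(treated) / mean(control),
         t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value, paired = paired),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(paste0(
    "<group_comparison> control %.3g +/- %.3g (n=%d) vs treated %.3g +/- %.3g (n=%d)\n",
    "  fold change %.3f | %s t = %.3f, df = %g, p = %.4g\n"),
    x$control_mean, x$control_sd, x$control_n,
    x$treated_mean, x$treated_sd, x$treated_n,
    x$fold_change, if (x$paired) "paired" else "unpaired", x$t, x$df, x$p))
  invisible(x)
}

#' Round half away from zero
#'
#' The rounding convention used when matching printed table cells
#' (`round()` in R rounds half to even).
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_away <- function(x, digits = 2L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Published reference group means
#'
#' Group means, SDs and sample sizes for hemodynamic and calcium metrics of
#' control, propranolol-treated (paired design) and terfenadine-treated
#' (unpaired design) zebrafish larvae, transcribed from the published table
#' of the cardioluminescence study this package operationalises. Used for
#' fold-change reporting; calcium metrics are in the study's arbitrary
#' consistent L/Lmax units.
#'
#' @return Data frame with columns `experiment`, `group`, `metric`, `mean`,
#'   `sd`, `n`.
#' @export
reference_group_means <- function() {
  path <- system.file("extdata", "reference_group_means.csv",
                      package = "cardiolum", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Fold changes of group means against control
#'
#' For every metric present in both groups of an experiment, the fold
#' change of the treated mean over the control mean, rounded half away from
#' zero to 2 decimal places for comparison against printed values.
#'
#' @param experiment `"propranolol"` or `"terfenadine"`.
#' @param ref Reference table (defaults to [reference_group_means()]); any
#'   data frame with the same columns works.
#' @return Data frame with `metric`, `control_mean`, `treated_mean`,
#'   `fold_change`, `fold_change_2dp`.
#' @examples
#' \dontrun{fold_change_table("propranolol")}
#' @export
fold_change_table <- function(experiment = c("propranolol", "terfenadine"),
                              ref = reference_group_means()) {
  experiment <- match.arg(experiment)
  sub <- ref[ref$experiment == experiment, ]
  ctrl <- sub[sub$group == "control", ]
  trt <- sub[sub$group == experiment, ]
  metrics <- intersect(ctrl$metric, trt$metric)
  cm <- ctrl$mean[match(metrics, ctrl$metric)]
  tm <- trt$mean[match(metrics, trt$metric)]
  keep <- is.finite(cm) & is.finite(tm)
  data.frame(metric = metrics[keep],
             control_mean = cm[keep],
             treated_mean = tm[keep],
             fold_change = tm[keep] / cm[keep],
             fold_change_2dp = round_half_away(tm[keep] / cm[keep], 2L))
}
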