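#' Read a run configuration file
#'
#' Structured YAML or JSON (by extension) mirroring the [sim_config()] and
#' analysis option names exactly. Unknown keys are rejected.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @param allowed Character vector of permitted keys (defaults to the
#'   [sim_config()] arguments plus shared run keys).
#' @return A named list.
#' @export
read_run_config <- function(path, allowed = NULL) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("config must be .yaml/.yml or .json", call. = FALSE)
  if (!is.list(cfg)) stop("config must be a mapping of keys to values",
                          call. = FALSE)
  if (is.null(allowed))
    allowed <- c(names(formals(sim_config)), "out_dir", "log_level",
                 "pulsate", "fs_pulse", "image_dim")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg
}

# Provenance block written alongside every run's outputs.
write_provenance <- function(out_dir, command, config) {
  info <- list(
    command = command,
    package = "cardiolum",
    version = as.character(utils::packageVersion("cardiolum")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = config
  )
  jsonlite::write_json(info, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(info)
}

#' Run a full forward simulation to disk
#'
#' Wraps the simulator end to end: ground-truth Ca2+ trace, luminescence
#' recording, rendered 16-bit TIFF stack with ROI JSON, and a per-frame
#' ground-truth CSV (`time_s`, `ca_uM`, `lambda_per_s`, `pool`, `counts`).
#' Deterministic under the configured seed.
#'
#' @param config A [sim_config()], a named list of its arguments, or a path
#'   to a YAML/JSON config file.
#' @param out_dir Output directory (created if needed).
#' @param render Logical: render the image stack (default `TRUE`).
#' @return Invisible list with the simulation objects and output paths.
#' @export
run_simulate <- function(config, out_dir, render = TRUE) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "sim_config")) {
    config <- config[setdiff(names(config),
                             c("out_dir", "log_level", "pulsate", "fs_pulse",
                               "image_dim"))]
    config <- do.call(sim_config, config)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  gt <- simulate_ca_trace(config)
  rec <- simulate_luminescence(gt, config)

  fsub <- fine_step(config$acq_freq)$n_sub
  n_frames <- gt$n_frames
  frame_of <- rep(seq_len(n_frames + 1L), each = fsub)[seq_along(gt$ca$values)]
  frame_of[frame_of > n_frames] <- n_frames
  ca_frame <- tapply(gt$ca$values, frame_of, mean)
  lam_frame <- tapply(gt$lambda$values, frame_of, mean)

  gt_csv <- file.path(out_dir, "ground_truth.csv")
  utils::write.csv(
    data.frame(time_s = (seq_len(n_frames) - 1L) / config$acq_freq,
               ca_uM = as.numeric(ca_frame),
               lambda_per_s = as.numeric(lam_frame),
               pool = rec$pool_at_frame,
               counts = rec$trace$values),
    gt_csv, row.names = FALSE, quote = FALSE)

  tiff_path <- roi_path <- NULL
  if (render) {
    tiff_path <- file.path(out_dir, "stack.tif")
    roi_path <- file.path(out_dir, "rois.json")
    render_image_stack(rec$expected, config, path = tiff_path,
                       roi_path = roi_path)
  }
  write_provenance(out_dir, "simulate", unclass(config))
  invisible(list(config = config, ground_truth = gt, recording = rec,
                 ground_truth_csv = gt_csv, tiff_path = tiff_path,
                 roi_path = roi_path))
}

#' Analyse a luminescence recording end to end
#'
#' Chains the analysis stages: ROI extraction (for stacks), per-frame SNR
#' from the background regions, aequorin budget calibration, beat detection
#' on the calibrated ratio, and summary output. Stage warnings (e.g. a
#' missing detergent-release segment) are collected into the returned
#' `warnings` field and the summary flag.
#'
#' @param stack Path to a multi-page TIFF, or `NULL` when `trace` is given.
#' @param rois ROI JSON path or list of [roi_spec()]s (must contain a
#'   `ventricle` ROI and `background_*` ROIs for stacks).
#' @param trace A [lum_trace()] or trace CSV path (pre-extracted ventricle
#'   counts), used instead of `stack`.
#' @param acq_freq Acquisition rate (Hz), required for stacks.
#' @param triton_index Frame index of the detergent release, or `NULL`.
#' @param background Background to subtract in the calibration; for stacks
#'   the default is the mean background ROI sum per frame.
#' @param out_dir Optional output directory for the calibration, per-beat
#'   feature and summary CSVs.
#' @param detect Logical: run beat detection (needs >= 3 beats in window).
#' @return Invisible list with `calibration`, `snr` (stacks only),
#'   `transients`, `summary` data frame, `warnings`.
#' @export
run_analyze_lum <- function(stack = NULL, rois = NULL, trace = NULL,
                            acq_freq = NULL, triton_index = NULL,
                            background = NULL, out_dir = NULL,
                            detect = TRUE) {
  warns <- character(0)
  collect <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warns <<- c(warns, conditionMessage(w))
    invokeRestart("muffleWarning")
  })

  snr <- NULL
  if (!is.null(stack)) {
    if (is.null(acq_freq)) stop("`acq_freq` is required for stacks",
                                call. = FALSE)
    if (is.character(rois)) rois <- read_roi_json(rois)
    labels <- vapply(rois, function(r) r$label, character(1))
    if (is.na(match("ventricle", labels)))
      stop("ROI set must contain a `ventricle` region", call. = FALSE)
    vent <- rois[[match("ventricle", labels)]]
    bg_idx <- grep("^background_", labels)
    if (length(bg_idx) < 2L)
      stop("ROI set must contain >= 2 `background_*` regions", call. = FALSE)

    frames <- read_stack(stack)
    sig <- collect(extract_trace(frames, vent, acq_freq))
    bgs <- lapply(bg_idx, function(i) extract_trace(frames, rois[[i]], acq_freq))
    snr <- collect(compute_snr(sig, bgs))
    if (is.null(background))
      background <- rowMeans(vapply(bgs, function(b) b$values,
                                    numeric(length(sig$values))))
    trace <- sig
  } else {
    if (is.null(trace)) stop("either `stack` or `trace` must be given",
                             call. = FALSE)
    if (is.character(trace)) trace <- read_trace_csv(trace)
    if (is.null(background)) background <- 0
  }

  cal <- collect(calibrate_luminescence(trace, background = background,
                                        triton_index = triton_index))
  # beats live in the physiological segment before the detergent release
  ratio <- cal$frames$ratio_per_s
  last <- if (is.null(triton_index)) length(ratio) else triton_index - 1L
  ratio <- ratio[seq_len(max(last, 2L))]
  ratio_trace <- lum_trace(ifelse(is.na(ratio), 0, ratio),
                           cal$sampling_rate, units = "per_s")
  transients <- NULL
  if (detect)
    transients <- tryCatch(collect(detect_beats(ratio_trace)),
                           error = function(e) {
                             warns <<- c(warns, conditionMessage(e))
                             NULL
                           })

  summary <- data.frame(
    Ltotal = cal$Ltotal,
    mean_ratio_per_s = mean(ratio, na.rm = TRUE),
    HR_bpm = if (is.null(transients)) NA_real_ else transients$heart_rate,
    systolic_level = if (is.null(transients)) NA_real_ else
      transients$systolic_level,
    diastolic_level = if (is.null(transients)) NA_real_ else
      transients$diastolic_level,
    mean_snr = if (is.null(snr)) NA_real_ else snr$summary_mean,
    max_snr = if (is.null(snr)) NA_real_ else snr$summary_max,
    has_triton = !is.null(triton_index),
    n_warnings = NA_integer_
  )
  summary$n_warnings <- length(warns)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_calibration_csv(cal, file.path(out_dir, "calibration.csv"))
    if (!is.null(transients))
      write_transients_csv(transients,
                           file.path(out_dir, "beat_features.csv"),
                           file.path(out_dir, "beat_summary.csv"))
    utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE, quote = FALSE)
    write_provenance(out_dir, "analyze-lum",
                     list(triton_index = triton_index,
                          acq_freq = if (is.null(acq_freq))
                            cal$sampling_rate else acq_freq))
  }
  invisible(list(calibration = cal, snr = snr, transients = transients,
                 summary = summary, warnings = warns))
}

#' Per-larva hemodynamics and group comparison
#'
#' Computes a [compute_record()] per larva from labelled geometry traces,
#' then compares every metric between two groups with [compare_groups()].
#'
#' @param larvae A named list; each element a list with `geometry` (a
#'   `geometry_trace` or CSV path), `hr` (bpm), optional `atrial_hr`, and
#'   `group` (character label).
#' @param paired Logical, passed to [compare_groups()] when two groups are
#'   present.
#' @param out_dir Optional output directory for records and comparison CSVs.
#' @return Invisible list with `records` (data frame, one row per larva)
#'   and `comparisons` (data frame, or `NULL` for a single group).
#' @export
run_hemodynamics <- function(larvae, paired = FALSE, out_dir = NULL) {
  recs <- lapply(names(larvae), function(id) {
    lv <- larvae[[id]]
    geom <- if (is.character(lv$geometry)) read_geometry_csv(lv$geometry) else
      lv$geometry
    rec <- compute_record(geom, hr = lv$hr,
                          atrial_hr = lv$atrial_hr)
    cbind(data.frame(larva = id, group = lv$group), as.data.frame(rec))
  })
  records <- do.call(rbind, recs)

  comparisons <- NULL
  groups <- unique(records$group)
  if (length(groups) == 2L) {
    metrics <- c("fs_major", "fs_minor", "fac", "edv_pl", "esv_pl", "sv_pl",
                 "hr_bpm", "co_nl_min", "ef")
    comparisons <- do.call(rbind, lapply(metrics, function(m) {
      a <- records[[m]][records$group == groups[1L]]
      b <- records[[m]][records$group == groups[2L]]
      gc <- tryCatch(compare_groups(a, b, paired = paired),
                     error = function(e) NULL)
      data.frame(metric = m, control_group = groups[1L],
                 treated_group = groups[2L],
                 control_mean = mean(a), treated_mean = mean(b),
                 fold_change = mean(b) / mean(a),
                 t = if (is.null(gc)) NA_real_ else gc$t,
                 p = if (is.null(gc)) NA_real_ else gc$p)
    }))
  } else if (length(groups) > 2L) {
    stop("at most two groups are supported", call. = FALSE)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(records, file.path(out_dir, "records.csv"),
                     row.names = FALSE, quote = FALSE)
    if (!is.null(comparisons))
      utils::write.csv(comparisons, file.path(out_dir, "comparisons.csv"),
                       row.names = FALSE, quote = FALSE)
    write_provenance(out_dir, "hemodynamics", list(paired = paired))
  }
  invisible(list(records = records, comparisons = comparisons))
}
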