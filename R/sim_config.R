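#' Configuration of a synthetic cardioluminescence recording
#'
#' Full ground-truth parameterisation of a simulated aequorin recording in a
#' beating larval heart. Defaults describe a 3-4 dpf larva imaged at 9 Hz:
#' atrial rate 180 bpm with 1:1 conduction, diastolic Ca2+ 0.1 uM with 1 uM
#' transient amplitude, and an aequorin pool of 1e6 emittable photons whose
#' fractional consumption rate follows Hill kinetics with cooperativity 3
#' (the bioluminescence reaction is triggered by three Ca2+ ions).
#'
#' @param duration Recording length (s).
#' @param acq_freq Image acquisition rate (Hz). The camera protocol uses
#'   25, 17, 12, 9, 2 or 1 Hz; any positive value is accepted.
#' @param atrial_rate Atrial pacing rate (beats per minute).
#' @param av_conduction Conduction rule: the ventricle follows every
#'   `av_conduction`-th atrial beat (1 = every beat, 2 = 2:1 block, ...).
#' @param ca_diastolic Diastolic free Ca2+ (uM).
#' @param ca_amplitude Peak transient amplitude above diastole (uM).
#' @param tau_rise,tau_decay Transient rise/decay time constants (s) of the
#'   difference-of-exponentials beat kernel.
#' @param hill_n Hill cooperativity of the Ca2+ -> light law (>= 1).
#' @param kd Half-saturating Ca2+ of the consumption rate (uM).
#' @param lambda_max Maximal fractional aequorin consumption rate (1/s).
#' @param pool0 Total emittable photons of the aequorin pool at t = 0.
#' @param detect_eff Fraction of emitted photons detected, in (0, 1].
#' @param bg_rate Camera background (counts/s per ROI).
#' @param read_noise_sd Gaussian read noise per frame (counts); 0 disables.
#' @param triton_time Time (s) at which detergent lysis releases the
#'   remaining pool, or `NULL` for no release segment.
#' @param triton_rate Release rate constant after lysis (1/s).
#' @param drug_event `NULL`, or a list with `time` (s), `ca_scale`
#'   (multiplier applied to the transient amplitude), `ramp_tau` (s,
#'   exponential onset) and optionally `scale_diastolic` (logical, default
#'   `FALSE`, whether diastolic Ca2+ is scaled too).
#' @param seed Integer seed making the stochastic stages reproducible,
#'   or `NULL`.
#' @return A validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(duration = 10, acq_freq = 9, seed = 1)
#' @export
sim_config <- function(duration = 60,
                       acq_freq = 9,
                       atrial_rate = 180,
                       av_conduction = 1,
                       ca_diastolic = 0.1,
                       ca_amplitude = 1,
                       tau_rise = 0.03,
                       tau_decay = 0.15,
                       hill_n = 3,
                       kd = 10,
                       lambda_max = 1,
                       pool0 = 1e6,
                       detect_eff = 1,
                       bg_rate = 50,
                       read_noise_sd = 0,
                       triton_time = NULL,
                       triton_rate = 2,
                       drug_event = NULL,
                       seed = NULL) {
  pos <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
      stop(sprintf("`%s` must be a single positive finite number", nm),
           call. = FALSE)
    as.numeric(x)
  }
  cfg <- list(
    duration = pos(duration, "duration"),
    acq_freq = pos(acq_freq, "acq_freq"),
    atrial_rate = pos(atrial_rate, "atrial_rate"),
    av_conduction = av_conduction,
    ca_diastolic = pos(ca_diastolic, "ca_diastolic"),
    ca_amplitude = pos(ca_amplitude, "ca_amplitude"),
    tau_rise = pos(tau_rise, "tau_rise"),
    tau_decay = pos(tau_decay, "tau_decay"),
    hill_n = hill_n,
    kd = pos(kd, "kd"),
    lambda_max = pos(lambda_max, "lambda_max"),
    pool0 = pos(pool0, "pool0"),
    detect_eff = detect_eff,
    bg_rate = bg_rate,
    read_noise_sd = read_noise_sd,
    triton_time = triton_time,
    triton_rate = pos(triton_rate, "triton_rate"),
    drug_event = drug_event,
    seed = seed
  )
  if (!is.numeric(bg_rate) || length(bg_rate) != 1L || bg_rate < 0)
    stop("`bg_rate` must be >= 0", call. = FALSE)
  cfg$bg_rate <- as.numeric(bg_rate)
  if (!is.numeric(read_noise_sd) || read_noise_sd < 0)
    stop("`read_noise_sd` must be >= 0", call. = FALSE)
  if (!is.numeric(av_conduction) || length(av_conduction) != 1L ||
      av_conduction < 1 || av_conduction != round(av_conduction))
    stop("`av_conduction` must be a positive integer (every Nth atrial beat)",
         call. = FALSE)
  cfg$av_conduction <- as.integer(av_conduction)
  if (!is.numeric(hill_n) || length(hill_n) != 1L || hill_n < 1)
    stop("`hill_n` must be >= 1", call. = FALSE)
  cfg$hill_n <- as.numeric(hill_n)
  if (!is.numeric(detect_eff) || length(detect_eff) != 1L ||
      detect_eff <= 0 || detect_eff > 1)
    stop("`detect_eff` must lie in (0, 1]", call. = FALSE)
  cfg$detect_eff <- as.numeric(detect_eff)
  if (!is.null(triton_time)) {
    tt <- pos(triton_time, "triton_time")
    if (tt >= cfg$duration)
      stop("`triton_time` must lie inside [0, duration)", call. = FALSE)
    cfg$triton_time <- tt
  }
  if (!is.null(drug_event)) {
    if (!is.list(drug_event) || !all(c("time", "ca_scale", "ramp_tau") %in%
                                     names(drug_event)))
      stop("`drug_event` must be a list with `time`, `ca_scale`, `ramp_tau`",
           call. = FALSE)
    drug_event$time <- pos(drug_event$time, "drug_event$time")
    drug_event$ca_scale <- pos(drug_event$ca_scale, "drug_event$ca_scale")
    drug_event$ramp_tau <- pos(drug_event$ramp_tau, "drug_event$ramp_tau")
    if (is.null(drug_event$scale_diastolic)) drug_event$scale_diastolic <- FALSE
    cfg$drug_event <- drug_event
  }
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || seed != round(seed))
      stop("`seed` must be a single integer", call. = FALSE)
    cfg$seed <- as.integer(seed)
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<sim_config> %g s @ %g Hz | atrium %g bpm, conduction 1:%d\n",
    "  Ca2+: dia %g uM + amp %g uM, tau_rise %g s, tau_decay %g s\n",
    "  light: Hill n = %g, Kd = %g uM, lambda_max = %g /s, pool0 = %g\n"),
    x$duration, x$acq_freq, x$atrial_rate, x$av_conduction,
    x$ca_diastolic, x$ca_amplitude, x$tau_rise, x$tau_decay,
    x$hill_n, x$kd, x$lambda_max, x$pool0))
  invisible(x)
}

# Fine integration step: frame interval subdivided so the step is <= 1/(20 f)
# and <= 1 ms, while dividing the frame interval exactly (frame boundaries
# fall on grid nodes).
fine_step <- function(acq_freq) {
  frame_dt <- 1 / acq_freq
  n_sub <- ceiling(frame_dt / min(frame_dt / 20, 1e-3))
  list(dt = frame_dt / n_sub, n_sub = as.integer(n_sub))
}
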