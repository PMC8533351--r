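# Beat kernel: difference of exponentials rescaled to unit peak.
# g(u) = (1 - exp(-u/tau_r)) * exp(-u/tau_d) for u >= 0, 0 otherwise.
# Peak at u* = tau_r * log((tau_r + tau_d)/tau_r), peak value
# (tau_d/(tau_r+tau_d)) * (tau_r/(tau_r+tau_d))^(tau_r/tau_d).
beat_kernel_peak <- function(tau_rise, tau_decay) {
  u_star <- tau_rise * log((tau_rise + tau_decay) / tau_rise)
  g_star <- (tau_decay / (tau_rise + tau_decay)) *
    (tau_rise / (tau_rise + tau_decay))^(tau_rise / tau_decay)
  list(u_peak = u_star, g_peak = g_star)
}

#' Unit-peak calcium transient kernel
#'
#' Difference-of-exponentials waveform rescaled so its maximum is exactly 1.
#'
#' @param u Time since beat onset (s); values < 0 give 0.
#' @param tau_rise,tau_decay Rise/decay time constants (s).
#' @return Numeric vector, same length as `u`, in \[0, 1\].
#' @export
beat_kernel <- function(u, tau_rise, tau_decay) {
  if (tau_rise <= 0 || tau_decay <= 0)
    stop("time constants must be strictly positive", call. = FALSE)
  pk <- beat_kernel_peak(tau_rise, tau_decay)
  g <- ifelse(u >= 0, (1 - exp(-u / tau_rise)) * exp(-u / tau_decay), 0)
  g / pk$g_peak
}

#' Simulate the ground-truth calcium trace of a beating heart
#'
#' Generates atrial and ventricular beat times, the fine-grid free Ca2+
#' concentration, the resulting fractional aequorin consumption rate
#' (Hill law, `lambda_max * Ca^n / (Kd^n + Ca^n)`), and the photoprotein
#' pool depletion driven by it (without any detergent-release segment).
#'
#' Ventricular beat times are the atrial beat grid thinned by the conduction
#' rule (every `av_conduction`-th beat), the substrate of a 2:1
#' atrio-ventricular block when `av_conduction = 2`. A drug event scales the
#' transient amplitude (and optionally the diastolic level) towards
#' `ca_scale` with an exponential ramp.
#'
#' @param config A [sim_config()].
#' @return An object of class `aeq_ground_truth`: list with `ca` (uM),
#'   `lambda` (1/s) and `pool` (photons) fine-grid [lum_trace()]s,
#'   `beat_times_atrium`, `beat_times_ventricle` (s), the fine step `dt`,
#'   and the `config`.
#' @examples
#' gt <- simulate_ca_trace(sim_config(duration = 5, acq_freq = 9))
#' length(gt$beat_times_ventricle)
#' @export
simulate_ca_trace <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  fs <- fine_step(config$acq_freq)
  n_frames <- floor(config$duration * config$acq_freq)
  if (n_frames < 2L) stop("recording too short for its acquisition rate",
                          call. = FALSE)
  t_end <- n_frames / config$acq_freq
  tt <- seq(0, t_end, by = fs$dt)

  ibi <- 60 / config$atrial_rate
  # beats fall in [0, duration): k = 0 .. n-1 with k*ibi < duration
  n_beats_a <- ceiling(config$duration / ibi - 1e-9)
  beats_a <- (seq_len(n_beats_a) - 1L) * ibi
  beats_v <- beats_a[seq(1L, length(beats_a), by = config$av_conduction)]

  pk <- beat_kernel_peak(config$tau_rise, config$tau_decay)
  # support window beyond which the kernel is < 1e-8 of its peak
  u_max <- pk$u_peak + config$tau_decay * log(1e8)
  wave <- numeric(length(tt))
  for (tk in beats_v) {
    i0 <- max(1L, floor(tk / fs$dt) + 1L)
    i1 <- min(length(tt), ceiling((tk + u_max) / fs$dt) + 1L)
    if (i0 > length(tt)) next
    u <- tt[i0:i1] - tk
    wave[i0:i1] <- wave[i0:i1] +
      ifelse(u >= 0, (1 - exp(-u / config$tau_rise)) *
               exp(-u / config$tau_decay), 0) / pk$g_peak
  }

  amp_scale <- rep(1, length(tt))
  dia_scale <- rep(1, length(tt))
  de <- config$drug_event
  if (!is.null(de)) {
    on <- tt >= de$time
    ramp <- 1 + (de$ca_scale - 1) * (1 - exp(-(tt[on] - de$time) / de$ramp_tau))
    amp_scale[on] <- ramp
    if (isTRUE(de$scale_diastolic)) dia_scale[on] <- ramp
  }

  ca <- config$ca_diastolic * dia_scale + config$ca_amplitude * amp_scale * wave
  lam <- config$lambda_max * ca^config$hill_n /
    (config$kd^config$hill_n + ca^config$hill_n)
  # stepwise pool decay A(t+dt) = A(t) * exp(-lambda(t) dt)
  n <- length(tt)
  cum_lam <- c(0, cumsum(lam[-n] * fs$dt))
  pool <- config$pool0 * exp(-cum_lam)

  structure(
    list(ca = lum_trace(ca, 1 / fs$dt, units = "uM"),
         lambda = lum_trace(lam, 1 / fs$dt, units = "per_s"),
         pool = lum_trace(pool, 1 / fs$dt, units = "photons"),
         beat_times_atrium = beats_a,
         beat_times_ventricle = beats_v,
         dt = fs$dt,
         n_frames = n_frames,
         config = config),
    class = "aeq_ground_truth"
  )
}

#' @export
print.aeq_ground_truth <- function(x, ...) {
  cat(sprintf(
    "<aeq_ground_truth> %g s | %d atrial / %d ventricular beats | fine dt = %g s\n",
    x$n_frames / x$config$acq_freq, length(x$beat_times_atrium),
    length(x$beat_times_ventricle), x$dt))
  invisible(x)
}

#' Simulate an aequorin luminescence recording
#'
#' Integrates photoprotein pool depletion between frame boundaries on the
#' fine grid and draws per-frame detected counts. The expected detected
#' counts in a frame are `detect_eff * (pool at frame start - pool at frame
#' end)` plus `bg_rate / acq_freq`; observed counts are Poisson with that
#' mean, plus optional Gaussian read noise, clamped at zero. From
#' `triton_time` onwards the consumption rate is replaced by the detergent
#' release constant `triton_rate` so the remaining pool is emitted.
#'
#' @param gt An [simulate_ca_trace()] ground truth.
#' @param config The [sim_config()] used to generate `gt` (or a modified
#'   copy with the same timing fields).
#' @param noise `"poisson"` (default; Poisson counts plus optional read
#'   noise) or `"none"` (expected counts, for noise-free analyses).
#' @return An object of class `lum_recording`: list with `trace` (observed
#'   per-frame RLU counts as a [lum_trace()]), `expected` (noise-free frame
#'   means excluding background), `background_per_frame`,
#'   `pool_at_frame` (pool entering each frame), `triton_index` (frame index
#'   of the release, or `NULL`), and `config`.
#' @examples
#' cfg <- sim_config(duration = 5, acq_freq = 9, triton_time = 4, seed = 1)
#' rec <- simulate_luminescence(simulate_ca_trace(cfg), cfg)
#' @export
simulate_luminescence <- function(gt, config = gt$config,
                                  noise = c("poisson", "none")) {
  stopifnot(inherits(gt, "aeq_ground_truth"), inherits(config, "sim_config"))
  noise <- match.arg(noise)
  if (config$detect_eff * config$pool0 < 100)
    stop("detectable photon budget below 100 counts: recording would be empty",
         call. = FALSE)
  fs <- fine_step(config$acq_freq)
  lam <- gt$lambda$values
  n <- length(lam)
  tt <- trace_times(gt$lambda)
  triton_index <- NULL
  if (!is.null(config$triton_time)) {
    lam[tt >= config$triton_time] <- config$triton_rate
    triton_index <- floor(config$triton_time * config$acq_freq) + 1L
  }
  cum_lam <- c(0, cumsum(lam[-n] * fs$dt))
  pool <- config$pool0 * exp(-cum_lam)

  n_frames <- gt$n_frames
  bound_idx <- seq(1L, n, by = fs$n_sub)      # frame boundary grid nodes
  stopifnot(length(bound_idx) == n_frames + 1L)
  a_start <- pool[bound_idx[-length(bound_idx)]]
  a_end <- pool[bound_idx[-1L]]
  expected <- config$detect_eff * (a_start - a_end)
  bg_per_frame <- config$bg_rate / config$acq_freq
  mu <- expected + bg_per_frame

  if (noise == "poisson") {
    if (!is.null(config$seed)) set.seed(config$seed)
    obs <- stats::rpois(n_frames, mu)
    if (config$read_noise_sd > 0)
      obs <- obs + stats::rnorm(n_frames, 0, config$read_noise_sd)
    obs <- pmax(obs, 0)
  } else {
    obs <- mu
  }

  structure(
    list(trace = lum_trace(obs, config$acq_freq, units = "RLU"),
         expected = expected,
         background_per_frame = bg_per_frame,
         pool_at_frame = a_start,
         triton_index = triton_index,
         config = config),
    class = "lum_recording"
  )
}

#' @export
print.lum_recording <- function(x, ...) {
  cat(sprintf(
    "<lum_recording> %d frames @ %g Hz | total %.0f RLU | triton frame: %s\n",
    length(x$trace$values), x$config$acq_freq, sum(x$trace$values),
    if (is.null(x$triton_index)) "none" else x$triton_index))
  invisible(x)
}

#' Simulate background region traces
#'
#' Draws `n_rois` independent Poisson background traces at the configured
#' background rate, mimicking equal-sized regions placed far from the larva
#' for the SNR protocol.
#'
#' @param config A [sim_config()].
#' @param n_frames Number of frames.
#' @param n_rois Number of background regions (default 6).
#' @param noise `"poisson"` or `"none"`.
#' @return List of `n_rois` [lum_trace()]s (RLU per frame).
#' @export
simulate_background_rois <- function(config, n_frames, n_rois = 6L,
                                     noise = c("poisson", "none")) {
  stopifnot(inherits(config, "sim_config"), n_frames >= 2L, n_rois >= 2L)
  noise <- match.arg(noise)
  mu <- config$bg_rate / config$acq_freq
  lapply(seq_len(n_rois), function(i) {
    v <- if (noise == "poisson") stats::rpois(n_frames, mu) else rep(mu, n_frames)
    if (noise == "poisson" && config$read_noise_sd > 0)
      v <- pmax(v + stats::rnorm(n_frames, 0, config$read_noise_sd), 0)
    lum_trace(v, config$acq_freq, units = "RLU")
  })
}

#' Simulate a GCaMP-style fluorescence trace
#'
#' `F(t) = (f0 + amp * sum g(t - t_k)) * exp(-t / bleach_tau)` plus Gaussian
#' noise, sampled at a confocal-style high rate (200 Hz default), with beat
#' times taken from the configured conduction pattern.
#'
#' @param config A [sim_config()].
#' @param f0 Baseline fluorescence (AU), > 0.
#' @param amp Transient amplitude (AU).
#' @param bleach_tau Photobleaching time constant (s); `Inf` disables.
#' @param noise_sd Gaussian noise SD (AU).
#' @param sampling_rate Sampling rate (Hz), default 200.
#' @param chamber `"ventricle"` (conducted beats) or `"atrium"` (all atrial
#'   beats).
#' @return A [lum_trace()] in AU.
#' @export
simulate_gcamp <- function(config, f0 = 100, amp = 50, bleach_tau = Inf,
                           noise_sd = 0, sampling_rate = 200,
                           chamber = c("ventricle", "atrium")) {
  stopifnot(inherits(config, "sim_config"))
  chamber <- match.arg(chamber)
  if (!is.numeric(f0) || f0 <= 0) stop("`f0` must be > 0", call. = FALSE)
  gt <- simulate_ca_trace(config)
  beats <- if (chamber == "ventricle") gt$beat_times_ventricle else
    gt$beat_times_atrium
  t_end <- gt$n_frames / config$acq_freq
  tt <- seq(0, t_end, by = 1 / sampling_rate)
  pk <- beat_kernel_peak(config$tau_rise, config$tau_decay)
  u_max <- pk$u_peak + config$tau_decay * log(1e8)
  wave <- numeric(length(tt))
  for (tk in beats) {
    i0 <- max(1L, floor(tk * sampling_rate) + 1L)
    i1 <- min(length(tt), ceiling((tk + u_max) * sampling_rate) + 1L)
    if (i0 > length(tt)) next
    u <- tt[i0:i1] - tk
    wave[i0:i1] <- wave[i0:i1] +
      ifelse(u >= 0, (1 - exp(-u / config$tau_rise)) *
               exp(-u / config$tau_decay), 0) / pk$g_peak
  }
  f <- (f0 + amp * wave) * exp(-tt / bleach_tau)
  if (noise_sd > 0) {
    if (!is.null(config$seed)) set.seed(config$seed + 1L)
    f <- f + stats::rnorm(length(f), 0, noise_sd)
  }
  lum_trace(f, sampling_rate, units = "AU")
}
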