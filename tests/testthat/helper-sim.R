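# Shared fixtures: small, fast simulation configs built in code.

quick_cfg <- function(...) {
  args <- list(...)
  defaults <- list(duration = 10, acq_freq = 9, atrial_rate = 180,
                   bg_rate = 0, pool0 = 1e5, seed = 42L)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# A recording whose ratio trace has clear beats: higher consumption so each
# transient burns a visible pool fraction, with a detergent release at the end.
beat_cfg <- function(duration = 30, acq_freq = 25, seed = 1L, ...) {
  quick_cfg(duration = duration, acq_freq = acq_freq,
            lambda_max = 5, pool0 = 2e6, bg_rate = 50,
            triton_time = duration - 5, seed = seed, ...)
}

# Calibrated ratio trace (unmasked pre-release window) from a config.
ratio_trace_of <- function(cfg, noise = "poisson") {
  gt <- simulate_ca_trace(cfg)
  rec <- simulate_luminescence(gt, cfg, noise = noise)
  cal <- calibrate_luminescence(rec$trace,
                                background = cfg$bg_rate / cfg$acq_freq,
                                triton_index = rec$triton_index)
  keep <- which(!cal$frames$masked &
                  cal$frames$time_s < (cfg$triton_time %||% Inf) - 0.5)
  list(trace = lum_trace(cal$frames$ratio_per_s[keep], cfg$acq_freq,
                         units = "per_s"),
       cal = cal, gt = gt, rec = rec, keep = keep)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Frame-averaged ground-truth lambda (left-endpoint fine-grid convention,
# matching the simulator's stepwise pool decay).
frame_lambda <- function(gt, cfg) {
  ns <- cardiolum:::fine_step(cfg$acq_freq)$n_sub
  lam <- gt$lambda$values
  frame_of <- rep(seq_len(gt$n_frames + 1L), each = ns)[seq_along(lam)]
  as.numeric(tapply(lam[-length(lam)], frame_of[-length(lam)], mean))
}
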