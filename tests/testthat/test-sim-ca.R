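test_that("beat grids follow the pacing rate and conduction rule", {
  # 180 bpm for 60 s: 180 ventricular beats at 1/3 s spacing
  cfg <- quick_cfg(duration = 60, atrial_rate = 180)
  gt <- simulate_ca_trace(cfg)
  expect_length(gt$beat_times_ventricle, 180L)
  expect_equal(unique(round(diff(gt$beat_times_ventricle), 10)), 1 / 3)

  # every-2nd-beat conduction: ventricular rate 90 bpm, AV ratio 0.5
  cfg2 <- quick_cfg(duration = 60, atrial_rate = 180, av_conduction = 2)
  gt2 <- simulate_ca_trace(cfg2)
  expect_length(gt2$beat_times_ventricle, 90L)
  v_rate <- 60 * length(gt2$beat_times_ventricle) / 60
  a_rate <- 60 * length(gt2$beat_times_atrium) / 60
  expect_equal(v_rate, 90)
  expect_equal(v_rate / a_rate, 0.5)

  # thinning property: ventricular count = floor(atrial/N) +/- 1, many cases
  for (N in c(1L, 2L, 3L, 5L, 7L)) {
    for (rate in c(120, 180, 233)) {
      g <- simulate_ca_trace(quick_cfg(duration = 17, atrial_rate = rate,
                                       av_conduction = N))
      na <- length(g$beat_times_atrium)
      nv <- length(g$beat_times_ventricle)
      expect_lte(abs(nv - floor(na / N)), 1L)
    }
  }
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(tau_rise = 0), "positive")
  expect_error(sim_config(tau_decay = -1), "positive")
  expect_error(sim_config(av_conduction = 0), "positive integer")
  expect_error(sim_config(detect_eff = 0), "\\(0, 1\\]")
  expect_error(sim_config(detect_eff = 1.2), "\\(0, 1\\]")
  expect_error(sim_config(hill_n = 0.5), ">= 1")
  expect_error(sim_config(duration = 10, triton_time = 12), "inside")
})

test_that("kernel rise time matches a dense-grid brute force", {
  tau_r <- 0.02; tau_d <- 0.2
  # independent oracle: evaluate the unnormalised waveform on a 10 us grid
  u <- seq(0, 3, by = 1e-5)
  g <- (1 - exp(-u / tau_r)) * exp(-u / tau_d)
  gn <- g / max(g)
  rise_oracle <- u[which(gn >= 0.9)[1]] - u[which(gn >= 0.1)[1]]
  expect_equal(rise_oracle, 0.02508, tolerance = 1e-3)

  # package kernel agrees with the oracle pointwise and peaks at 1
  expect_equal(max(beat_kernel(u, tau_r, tau_d)), 1, tolerance = 1e-9)
  expect_equal(beat_kernel(u, tau_r, tau_d), gn, tolerance = 1e-9)

  # single simulated beat: numeric 10-90% rise from the fine-grid Ca trace
  cfg <- sim_config(duration = 2, acq_freq = 25, atrial_rate = 40,
                    tau_rise = tau_r, tau_decay = tau_d, bg_rate = 0)
  gt <- simulate_ca_trace(cfg)
  ca <- gt$ca$values
  tt <- (seq_along(ca) - 1) * gt$dt
  win <- tt < 1.4  # isolate the first beat
  x <- (ca[win] - cfg$ca_diastolic) / cfg$ca_amplitude
  r10 <- tt[win][which(x >= 0.1)[1]]
  r90 <- tt[win][which(x >= 0.9)[1]]
  expect_equal(r90 - r10, rise_oracle, tolerance = 0.05)
})

test_that("ground truth obeys the Hill law and pool monotonicity", {
  cfg <- quick_cfg(duration = 8, hill_n = 3)
  gt <- simulate_ca_trace(cfg)
  ca <- gt$ca$values
  expect_equal(gt$lambda$values,
               cfg$lambda_max * ca^3 / (cfg$kd^3 + ca^3), tolerance = 1e-12)
  expect_true(all(gt$lambda$values >= 0))
  expect_true(all(diff(gt$pool$values) <= 0))
  # fine step respects both caps and divides the frame interval
  fs <- cardiolum:::fine_step(cfg$acq_freq)
  expect_lte(fs$dt, 1 / (20 * cfg$acq_freq))
  expect_lte(fs$dt, 1e-3 + 1e-12)
})

test_that("drug events ramp the transient amplitude by ca_scale", {
  cfg <- quick_cfg(duration = 40, acq_freq = 9,
                   drug_event = list(time = 15, ca_scale = 2, ramp_tau = 2))
  gt <- simulate_ca_trace(cfg)
  tt <- (seq_along(gt$ca$values) - 1) * gt$dt
  peak_pre <- max(gt$ca$values[tt < 14])
  peak_post <- max(gt$ca$values[tt > 30])  # ramp fully on (>7 tau)
  amp_pre <- peak_pre - cfg$ca_diastolic
  amp_post <- peak_post - cfg$ca_diastolic
  expect_equal(amp_post / amp_pre, 2, tolerance = 0.01)
})

test_that("identical config and seed give bit-identical recordings", {
  cfg <- beat_cfg(duration = 6, seed = 99L)
  r1 <- simulate_luminescence(simulate_ca_trace(cfg), cfg)
  r2 <- simulate_luminescence(simulate_ca_trace(cfg), cfg)
  expect_identical(r1$trace$values, r2$trace$values)
  g1 <- simulate_gcamp(cfg, noise_sd = 2)
  g2 <- simulate_gcamp(cfg, noise_sd = 2)
  expect_identical(g1$values, g2$values)
})
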