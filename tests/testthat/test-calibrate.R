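test_that("a fully consumed constant trace yields the textbook budget", {
  # 1 RLU/frame, 10 frames at 1 Hz, no background:
  # Ltotal = 10, Lmax = 10, 9, ..., 1, ratio = 1/10, 1/9, ..., 1
  tr <- lum_trace(rep(1, 10), sampling_rate = 1)
  # the noise floor is for real recordings; disable it to follow the toy
  # budget to full exhaustion
  cal <- calibrate_luminescence(tr, triton_index = 10L, mask_floor_counts = 0)
  expect_equal(cal$Ltotal, 10)
  expect_equal(cal$frames$Lmax, 10:1)
  expect_equal(cal$frames$Lconsumed, 1:10)
  expect_equal(cal$frames$ratio_per_s, 1 / (10:1))
  expect_false(any(cal$frames$masked))
})

test_that("the budget identity holds frame by frame on noisy recordings", {
  set.seed(21)
  for (i in 1:20) {
    v <- rpois(50, exp(runif(1, 2, 6)))
    v[1] <- v[1] + 1  # guard against an all-zero draw
    cal <- calibrate_luminescence(lum_trace(v, sampling_rate = 9),
                                  triton_index = 50L)
    lc_prev <- c(0, cal$frames$Lconsumed[-50])
    expect_identical(cal$frames$Lmax + lc_prev, rep(cal$Ltotal, 50))
  }
})

test_that("the ratio is invariant to the total amount of aequorin", {
  set.seed(33)
  v <- rpois(200, 500) + 1
  cal1 <- calibrate_luminescence(lum_trace(v, 9), triton_index = 200L)
  calk <- calibrate_luminescence(lum_trace(v * 1000, 9), triton_index = 200L)
  expect_equal(calk$frames$ratio_per_s, cal1$frames$ratio_per_s,
               tolerance = 1e-12)
  expect_identical(calk$frames$masked, cal1$frames$masked)
})

test_that("noise-free ratio encodes the ground-truth consumption rate", {
  # ratio/f = 1 - exp(-integral of lambda over the frame)
  cfg <- quick_cfg(duration = 12, acq_freq = 25, lambda_max = 2,
                   triton_time = 9)
  res <- ratio_trace_of(cfg, noise = "none")
  f <- cfg$acq_freq
  lam_frame <- frame_lambda(res$gt, cfg)
  pre <- res$keep
  lhs <- res$cal$frames$ratio_per_s[pre] / f
  rhs <- 1 - exp(-lam_frame[pre] / f)
  expect_equal(lhs, rhs, tolerance = 1e-4)
})

test_that("degenerate traces error and biased traces warn", {
  expect_error(
    suppressWarnings(
      calibrate_luminescence(lum_trace(c(0, 0, 0), 1), triton_index = 3L)),
    "no luminescence")
  # missing detergent release -> Lmax bias warning
  expect_warning(calibrate_luminescence(lum_trace(c(5, 4, 3), 1)),
                 "underestimates")
  # mostly sub-background trace -> clipping warning
  expect_warning(
    calibrate_luminescence(lum_trace(c(10, rep(0, 9)), 1), background = 1,
                           triton_index = 10L),
    "clipped")
})

test_that("windowed ratio means track drug-scaled calcium via the Hill law", {
  cfg <- quick_cfg(duration = 60, acq_freq = 2, pool0 = 5e6, bg_rate = 10,
                   triton_time = 55, seed = 17L,
                   drug_event = list(time = 25, ca_scale = 2, ramp_tau = 1))
  gt <- simulate_ca_trace(cfg)
  rec <- simulate_luminescence(gt, cfg)
  cal <- calibrate_luminescence(rec$trace, background = cfg$bg_rate / 2,
                                triton_index = rec$triton_index)
  m_pre <- summarize_ratio(cal, c(0, 20))
  m_post <- summarize_ratio(cal, c(35, 54))
  # oracle: predicted mean lambda from the ground-truth Ca trace and the
  # Hill law over the same windows
  tt <- cardiolum::trace_times(gt$lambda)
  pred_pre <- mean(gt$lambda$values[tt >= 0 & tt <= 20])
  pred_post <- mean(gt$lambda$values[tt >= 35 & tt <= 54])
  expect_equal(m_post / m_pre, pred_post / pred_pre, tolerance = 0.05)

  # a geometrically decaying trace has constant ratio (1 - q) * f away from
  # the exhausted tail; the windowed mean returns that constant
  q <- 0.9
  geo <- lum_trace(1e6 * q^(0:99) * (1 - q), sampling_rate = 1)
  cal_g <- calibrate_luminescence(geo, triton_index = 100L)
  expect_equal(summarize_ratio(cal_g, c(0, 40)), 1 - q, tolerance = 1e-3)
})

test_that("summarize_ratio rejects fully masked windows", {
  tr <- lum_trace(c(rep(100, 5), rep(1, 5)), 1)
  cal <- calibrate_luminescence(tr, triton_index = 10L)
  expect_true(any(cal$frames$masked))
  masked_window <- range(cal$frames$time_s[cal$frames$masked])
  expect_error(summarize_ratio(cal, masked_window), "no unmasked")
})
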