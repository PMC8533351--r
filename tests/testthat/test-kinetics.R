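test_that("EWMA smoothing follows the recursive definition", {
  # constant trace is a fixed point
  expect_equal(ewma_smooth(rep(3, 10), 0.7), rep(3, 10))
  # unit step at t = 2, factor 0.7 -> geometric approach 0, .7, .91, .973
  s <- ewma_smooth(c(0, 1, 1, 1), 0.7)
  expect_equal(s, c(0, 0.7, 0.91, 0.973))
  # factor 1 is the identity
  x <- rnorm(20)
  expect_identical(ewma_smooth(x, 1), x)
  # opposite weight convention
  expect_equal(ewma_smooth(c(0, 1, 1, 1), 0.3, current_weight = FALSE),
               c(0, 0.7, 0.91, 0.973))
  expect_error(ewma_smooth(x, 0), "\\(0, 1\\]")
  # DC gain 1: long stationary trace keeps its mean within 1%
  set.seed(4)
  y <- 10 + rnorm(5000)
  expect_equal(mean(ewma_smooth(y, 0.7)), mean(y), tolerance = 0.01)
})

test_that("dF/F0 normalisation anchors at the recording minimum", {
  tr <- lum_trace(c(120, 100, 150, 110, 100, 140), 10)
  norm <- delta_f_over_f0(tr, smooth = FALSE)
  expect_equal(norm$f0, 100)
  expect_equal(max(norm$dff$values), 0.5)
  expect_equal(min(norm$dff$values), 0)
  expect_error(delta_f_over_f0(lum_trace(c(-1, 0, 2), 1), smooth = FALSE),
               "F0 <= 0")
})

test_that("a symmetric triangular pulse has an 80 ms 10-90% rise", {
  # 100 ms linear rise sampled at 1 kHz: linear interpolation makes the
  # 10-90% crossing span exactly 0.8 of the ramp
  fs <- 1000
  up <- seq(0, 1, length.out = 101)
  tri <- c(rep(0, 200), up, rev(up)[-1], rep(0, 200))
  x <- rep(c(tri, rep(0, 100)), 4)[1:2000]
  ts <- suppressWarnings(detect_beats(lum_trace(x, fs), refine = FALSE))
  expect_equal(stats::median(ts$features$rise_10_90_s, na.rm = TRUE), 0.080,
               tolerance = 0.01)
  expect_equal(stats::median(ts$features$decay_90_10_s, na.rm = TRUE), 0.080,
               tolerance = 0.01)
})

test_that("rise and decay times are invariant under affine transforms", {
  cfg <- quick_cfg(duration = 8, atrial_rate = 120, seed = 6L)
  g <- simulate_gcamp(cfg, f0 = 100, amp = 60, noise_sd = 0.5)
  ts1 <- detect_beats(g)
  g2 <- g; g2$values <- 3.7 * g$values + 55
  ts2 <- detect_beats(g2)
  expect_equal(ts2$features$rise_10_90_s, ts1$features$rise_10_90_s,
               tolerance = 1e-8)
  expect_equal(ts2$features$decay_90_10_s, ts1$features$decay_90_10_s,
               tolerance = 1e-8)
  expect_equal(ts2$heart_rate, ts1$heart_rate, tolerance = 1e-8)
})

test_that("beat detection recovers count, rate and amplitude on clean trains", {
  # 3 Hz train, 60 s: 180 +/- 1 beats, HR 180 +/- 1 bpm
  cfg <- beat_cfg(duration = 60, acq_freq = 25, seed = 13L)
  res <- ratio_trace_of(cfg)
  ts <- detect_beats(res$trace)
  dur <- length(res$trace$values) / 25
  expect_lte(abs(ts$n_beats - 3 * dur), 1)
  expect_lte(abs(ts$heart_rate_span - 180), 1)
  expect_lte(abs(ts$heart_rate - 180), 3)

  # amplitude within 5% of ground truth on a noise-free ratio trace
  cfg_nf <- quick_cfg(duration = 20, acq_freq = 25, lambda_max = 2,
                      triton_time = 16)
  res_nf <- ratio_trace_of(cfg_nf, noise = "none")
  ts_nf <- detect_beats(res_nf$trace)
  lam_frame <- frame_lambda(res_nf$gt, cfg_nf)[res_nf$keep]
  # ground-truth amplitude of the frame-integrated consumption-rate signal
  truth_amp <- max(lam_frame) - min(lam_frame)
  got_amp <- stats::median(ts_nf$features$amplitude)
  expect_equal(got_amp, truth_amp, tolerance = 0.05)
})

test_that("flat or aperiodic traces are handled explicitly", {
  expect_error(detect_beats(lum_trace(rep(1, 100), 10)), "no peaks")
  set.seed(2)
  expect_warning(try(detect_beats(lum_trace(rnorm(300), 10)), silent = TRUE),
                 "aperiodic")
})

test_that("the AV ratio flags conduction blocks", {
  expect_equal(av_ratio(120, 120), 1)
  expect_error(av_ratio(120, 0), "zero")

  for (N in c(2L, 3L)) {
    cfg <- beat_cfg(duration = 30, acq_freq = 25, seed = 20L + N,
                    av_conduction = N)
    vent <- detect_beats(ratio_trace_of(cfg)$trace)
    atr <- detect_beats(simulate_gcamp(cfg, noise_sd = 1, chamber = "atrium"))
    expect_equal(av_ratio(vent, atr), 1 / N, tolerance = 0.02 * N)
  }
})
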