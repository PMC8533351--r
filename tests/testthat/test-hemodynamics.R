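test_that("ellipsoid volumes follow the revolution formula", {
  # sphere: major = minor = 10 um
  expect_equal(ellipsoid_volume(10, 10, "um3"), pi / 6 * 1000)
  expect_equal(ellipsoid_volume(10, 10), pi / 6 * 1000 / 1000)
  # diastolic pair (100, 80)
  expect_equal(ellipsoid_volume(100, 80, "um3"), 335103.2, tolerance = 1e-6)
  # doubling the minor diameter quadruples the volume
  expect_equal(ellipsoid_volume(120, 160) / ellipsoid_volume(120, 80), 4)
  # random pairs against an independent re-evaluation
  set.seed(14)
  maj <- runif(1e4, 50, 200); mnr <- runif(1e4, 30, 150)
  oracle <- vapply(seq_along(maj),
                   function(i) maj[i] * mnr[i] * mnr[i] * pi / 6 / 1000,
                   numeric(1))
  expect_equal(ellipsoid_volume(maj, mnr), oracle, tolerance = 1e-12)
  expect_error(ellipsoid_volume(-1, 10), "positive")
})

test_that("records reproduce published stroke-volume worked examples", {
  # EDV 422.1, ESV 109.3 -> SV 312.8, EF 0.74; EDV 518.7, ESV 108.8 -> SV 409.9
  expect_equal(422.1 - 109.3, 312.8)
  expect_equal(round_half_away(312.8 / 422.1, 2), 0.74)
  expect_equal(518.7 - 108.8, 409.9)

  # Dd = 100, Ds = 77 on both axes: FS = 0.23
  geom <- data.frame(frame = 1:2, time_s = c(0, 0.1),
                     major_um = c(100, 77), minor_um = c(100, 77),
                     area_um2 = pi / 4 * c(100^2, 77^2),
                     phase = c("end_diastole", "end_systole"))
  class(geom) <- c("geometry_trace", "data.frame")
  rec <- compute_record(geom, hr = 200)
  expect_equal(rec$fs_major, 0.23)
  expect_equal(rec$fs_minor, 0.23)
  expect_equal(rec$sv_pl, rec$edv_pl - rec$esv_pl)
  expect_equal(rec$ef, rec$sv_pl / rec$edv_pl)
  expect_equal(rec$co_nl_min, rec$sv_pl * 200 / 1000)
})

test_that("geometry round trip recovers the generating parameters exactly", {
  cfg <- quick_cfg(duration = 6, atrial_rate = 150)
  fs_maj <- 0.28; fs_min <- 0.33; dd_maj <- 130; dd_min <- 80
  geom <- simulate_geometry(cfg, fs_maj, fs_min, dd_maj, dd_min)
  rec <- compute_record(geom, hr = 150, atrial_hr = 150, n_pairs = 3L)
  expect_equal(rec$fs_major, fs_maj, tolerance = 1e-12)
  expect_equal(rec$fs_minor, fs_min, tolerance = 1e-12)
  fac_expected <- 1 - (1 - fs_maj) * (1 - fs_min)
  expect_equal(rec$fac, fac_expected, tolerance = 1e-12)
  expect_equal(rec$edv_pl, ellipsoid_volume(dd_maj, dd_min), tolerance = 1e-12)
  expect_equal(rec$esv_pl,
               ellipsoid_volume(dd_maj * (1 - fs_maj), dd_min * (1 - fs_min)),
               tolerance = 1e-12)
  expect_equal(rec$av_ratio, 1)

  # systolic > diastolic pairs are excluded with a warning
  bad <- geom
  i_sys <- which(bad$phase == "end_systole")[1]
  bad$major_um[i_sys] <- dd_maj * 1.5
  expect_warning(rec2 <- compute_record(bad, hr = 150), "excluded")
  expect_equal(rec2$fs_major, fs_maj, tolerance = 1e-12)
})

test_that("group comparisons report means, fold change and Student's t", {
  # published worked example: treated 26.1 vs control 56.8 -> fold 0.46
  expect_equal(round_half_away(26.1 / 56.8, 2), 0.46)

  set.seed(3)
  ctrl <- rnorm(12, 100, 10); trt <- rnorm(12, 80, 10)
  gc <- compare_groups(ctrl, trt)
  expect_equal(gc$fold_change, mean(trt) / mean(ctrl))
  expect_equal(gc$control_sd, sd(ctrl))
  # oracle: base R pooled-variance t-test
  tt <- t.test(trt, ctrl, var.equal = TRUE)
  expect_equal(gc$t, unname(tt$statistic))
  expect_equal(gc$p, tt$p.value)

  # identical paired groups: fold change 1, p = 1
  same <- c(1, 2, 3, 4)
  gci <- compare_groups(same, same, paired = TRUE)
  expect_equal(gci$fold_change, 1)
  expect_equal(gci$p, 1)
  expect_equal(gci$t, 0)

  expect_error(compare_groups(c(1, 1), c(1, 1)), "zero variance")
  expect_error(compare_groups(1:3, 1:4, paired = TRUE), "equal group sizes")
})

test_that("the unpaired t-test holds its nominal type-I error rate", {
  set.seed(8)
  reps <- 2000
  hits <- 0L
  for (i in seq_len(reps)) {
    p <- compare_groups(rnorm(10, 50, 5), rnorm(10, 50, 5))$p
    hits <- hits + (p < 0.05)
  }
  rate <- hits / reps
  # binomial 99.7% band around 0.05 for 2000 draws: +/- 3*sqrt(.05*.95/2000)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("rounding matches the printed-table convention", {
  # binary-exact halves round away from zero (round() would go to even)
  expect_equal(round_half_away(0.125, 2), 0.13)
  expect_equal(round_half_away(-0.125, 2), -0.13)
})
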