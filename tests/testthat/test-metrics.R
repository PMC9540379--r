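# Analytic traces for metric checks are built directly from angle
# matrices via cilium_trace().

test_that("amplitude is the population SD of pooled middle angles", {
  # constant angles: amplitude zero
  tr <- cilium_trace(matrix(0.7, 30, 5), 2, 0.35, 2)
  expect_equal(compute_amplitude(tr), 0)
  # two pooled values {-0.1, +0.1}: population SD is 0.1
  th <- matrix(c(-0.1, 0.1), 2, 5)
  tr2 <- cilium_trace(th, 2, 0.35, 2)
  expect_equal(compute_amplitude(tr2), 0.1, tolerance = 1e-12)
  # sinusoidal sweep over whole periods: A / sqrt(2)
  t_s <- seq(0, by = 2, length.out = 300)
  phi <- 0.3 * sin(2 * pi * t_s / 24)
  tr3 <- cilium_trace(matrix(phi, 300, 9), 2, 0.35, 2)
  expect_equal(compute_amplitude(tr3), 0.3 / sqrt(2), tolerance = 0.01)
})

test_that("amplitude is invariant under a global rotation offset", {
  t_s <- seq(0, by = 2, length.out = 120)
  phi <- 0.25 * sin(2 * pi * t_s / 24)
  a0 <- compute_amplitude(cilium_trace(matrix(phi, 120, 9), 2, 0.35, 2))
  for (off in c(1.3, -2.6, pi - 0.05)) {  # last one straddles the cut
    a <- compute_amplitude(cilium_trace(matrix(phi + off, 120, 9),
                                        2, 0.35, 2))
    expect_equal(a, a0, tolerance = 1e-9)
  }
})

test_that("period estimation finds the beat and scores its regularity", {
  t_s <- seq(0, by = 2, length.out = 300)
  phi <- sin(2 * pi * t_s / 24)
  tr <- cilium_trace(matrix(phi, 300, 9), 2, 0.35, 2)
  per <- estimate_period(tr)
  expect_false(per$period_unreliable)
  expect_lte(abs(per$period_s - 24), 2)
  expect_gte(per$periodicity, 0.95)
  expect_equal(per$frequency_hz, 1 / per$period_s)
  # invariant under amplitude scaling
  per2 <- estimate_period(cilium_trace(matrix(7.3 * phi, 300, 9),
                                       2, 0.35, 2))
  expect_equal(per2$period_s, per$period_s)
  # constant series: flagged, no period
  perc <- estimate_period(cilium_trace(matrix(1, 60, 9), 2, 0.35, 2))
  expect_true(perc$period_unreliable)
  expect_true(is.na(perc$period_s))
  # white noise: flagged as unreliable
  set.seed(4)
  pern <- estimate_period(rnorm(300), frame_interval_s = 2)
  expect_true(pern$period_unreliable)
  # too-short series errors
  expect_error(estimate_period(cilium_trace(matrix(1, 10, 9), 2, 0.35, 2)),
               "20 frames")
})

test_that("length is the segment count times calibrated segment length", {
  tr <- cilium_trace(matrix(0, 3, 20), 2, 0.25, 2)
  expect_equal(compute_length_um(tr), 10)
})

test_that("curvature matches hand computations and circle geometry", {
  # straight filament: zero curvature
  tr <- cilium_trace(matrix(0.4, 5, 8), 2, 0.35, 2)
  expect_equal(compute_max_curvature(tr), 0)
  # two segments differing by 0.1 rad over 1 um: 0.1 per um
  tr2 <- cilium_trace(matrix(c(0, 0.1), 1, 2, byrow = TRUE), 4, 0.25, 2)
  expect_equal(compute_max_curvature(tr2, middle_fraction = 1), 0.1,
               tolerance = 1e-12)
  # arc of radius 5 um traced exactly: kappa = 0.2 per um within 5%
  ds_um <- 2 * 0.35
  n <- 16
  theta_arc <- (seq_len(n) - 0.5) * ds_um / 5
  tr3 <- cilium_trace(matrix(theta_arc, 1, n, byrow = TRUE), 2, 0.35, 2)
  expect_equal(compute_max_curvature(tr3), 0.2, tolerance = 0.05)
})

test_that("length and curvature are invariant under rigid motion", {
  set.seed(2)
  th <- matrix(rnorm(8 * 40, sd = 0.2), 40, 8) +
    matrix(seq(0, 0.6, length.out = 8), 40, 8, byrow = TRUE)
  tr <- cilium_trace(th, 2, 0.35, 2, base_xy = c(10, 10))
  rot <- cilium_trace(th + 1.1, 2, 0.35, 2, base_xy = c(40, 3))
  expect_equal(compute_length_um(rot), compute_length_um(tr))
  expect_equal(compute_max_curvature(rot), compute_max_curvature(tr),
               tolerance = 1e-12)
})

test_that("summary assembles coherent waveform metrics", {
  t_s <- seq(0, by = 2, length.out = 120)
  phi <- -0.6 + 0.3 * sin(2 * pi * t_s / 24)
  tr <- cilium_trace(matrix(phi, 120, 11), 2, 0.35, 2)
  m <- summary(tr)
  expect_s3_class(m, "waveform_metrics")
  expect_equal(m$amplitude_rad, 0.3 / sqrt(2), tolerance = 0.01)
  expect_equal(m$period_s, 24, tolerance = 2)
  expect_equal(m$length_um, 11 * 2 * 0.35)
  expect_equal(m$n_frames_used, 120)
  expect_false("period_unreliable" %in% m$flags)
  # identical input, identical metrics
  expect_identical(m, summary(tr))
  # static filament: amplitude ~ 0 and unreliable period flag
  ms <- summary(cilium_trace(matrix(0.2, 60, 11), 2, 0.35, 2))
  expect_equal(ms$amplitude_rad, 0)
  expect_true("period_unreliable" %in% ms$flags)
  expect_true(is.na(ms$period_s))
})

test_that("middle-80% banding excludes base and tip segments", {
  # N = 11: midpoints at (i - 0.5)/11 of length; segments 1 and 11 fall
  # outside [0.1, 0.9]
  th <- matrix(0, 4, 11)
  th[, 1] <- 5   # wild base angle must not affect amplitude
  th[, 11] <- -5
  tr <- cilium_trace(th, 2, 0.35, 2)
  expect_equal(compute_amplitude(tr), 0)
})
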