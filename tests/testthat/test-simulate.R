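test_that("static noiseless filament renders identical frames", {
  sim <- small_scene(noise_sigma = 0, amplitude_rad = 0, n_frames = 4,
                     n_blobs = 0)
  fr <- sim$stack$frames
  for (t in 2:4) expect_equal(fr[, , t], fr[, , 1], tolerance = 0)
})

test_that("ground-truth angles follow the traveling-wave closed form", {
  mdl <- waveform_model(base_xy = c(40, 40), base_angle_rad = 0.4,
                        length_um = 6, amplitude_rad = 0.3, period_s = 24,
                        wavenumber_per_um = 0.2, phase0_rad = 0.5)
  rp <- render_params(noise_sigma = 0, n_blobs = 0)
  sim <- simulate_cilium_movie(mdl, rp, n_frames = 8,
    geometry = list(H = 96, W = 96, pixel_size_um = 0.35,
                    frame_interval_s = 2))
  tr <- sim$truth
  for (t in seq_len(8)) {
    expected <- 0.4 + 0.3 * sin(2 * pi * (t - 1) * 2 / 24 + 0.5 -
                                  0.2 * tr$s_um)
    expect_equal(tr$theta[t, ], expected, tolerance = 1e-12)
  }
  # rigid pivot at frame 3: theta = theta0 + A sin(2 pi 6 / 24)
  sim2 <- small_scene(noise_sigma = 0, n_frames = 4, n_blobs = 0)
  expect_equal(unique(round(sim2$truth$theta[4, ], 12)),
               round(-0.6 + 0.3 * sin(2 * pi * 6 / 24), 12))
})

test_that("rendered peak intensity matches the configured scene", {
  sim <- small_scene(noise_sigma = 0, amplitude_rad = 0, n_frames = 1,
                     n_blobs = 0)
  fr <- sim$stack$frames[, , 1]
  # centreline may pass between pixel centres: peak attenuated at most
  # by exp(-(1/2)^2 / (2 sigma^2)) with sigma = 0.25/0.35 px
  sigma_px <- 0.25 / 0.35
  lower <- 50 + 100 * exp(-0.25 / (2 * sigma_px^2))
  expect_gte(max(fr), lower)
  expect_lte(max(fr), 150 + 1e-9)
  expect_equal(min(fr), 50)
})

test_that("identical seeds give bit-identical movies", {
  a <- small_scene(n_frames = 5, rng_seed = 7, drift_sigma_px = 1)
  b <- small_scene(n_frames = 5, rng_seed = 7, drift_sigma_px = 1)
  expect_identical(a$stack$frames, b$stack$frames)
  expect_identical(a$truth$drift, b$truth$drift)
  c <- small_scene(n_frames = 5, rng_seed = 8, drift_sigma_px = 1)
  expect_false(identical(a$stack$frames, c$stack$frames))
})

test_that("truth and stack are shape-consistent and drift starts at zero", {
  sim <- small_scene(n_frames = 7, drift_sigma_px = 0.5)
  expect_equal(nrow(sim$truth$theta), 7L)
  expect_equal(length(sim$truth$centerline), 7L)
  expect_equal(dim(sim$truth$drift), c(7L, 2L))
  expect_equal(sim$truth$drift[1, ], c(dx = 0, dy = 0))
})

test_that("with a static filament the temporal variance is noise only", {
  sim <- small_scene(noise_sigma = 8, amplitude_rad = 0, n_frames = 40,
                     n_blobs = 0)
  fr <- sim$stack$frames
  d <- dim(fr)
  v <- apply(matrix(fr, d[1] * d[2], d[3]), 1, var)
  # background is at 50 counts, so zero-clipping is negligible
  expect_equal(mean(v), 64, tolerance = 0.05)
})

test_that("the filament must stay inside the frame", {
  mdl <- waveform_model(base_xy = c(90, 48), base_angle_rad = 0,
                        length_um = 8)
  rp <- render_params(noise_sigma = 0, n_blobs = 0)
  expect_error(simulate_cilium_movie(mdl, rp, n_frames = 1,
    geometry = list(H = 96, W = 96, pixel_size_um = 0.35,
                    frame_interval_s = 2)),
    "leaves the frame")
})

test_that("add_noise is deterministic, clipped, and well-calibrated", {
  fr <- matrix(100, 512, 512)
  expect_identical(add_noise(fr, 0, 1), fr)
  a <- add_noise(fr, 5, 42)
  b <- add_noise(fr, 5, 42)
  expect_identical(a, b)
  expect_error(add_noise(fr, -1, 1), ">= 0")
  # sample SD over 512^2 pixels within 2% of sigma
  expect_equal(sd(a), 5, tolerance = 0.02)
  expect_gte(min(add_noise(matrix(0.1, 64, 64), 10, 1)), 0)
})

test_that("apply_drift translates frames as specified", {
  fr <- textured_frame()
  st <- cilium_stack(array(c(fr, fr), c(dim(fr), 2)), 0.35, 2)
  # zero drift is the identity
  expect_equal(apply_drift(st, matrix(0, 2, 2))$frames, st$frames,
               tolerance = 0)
  # integer shift with wrap boundary equals an index roll
  sh <- apply_drift(st, rbind(c(0, 0), c(3, -2)), boundary = "wrap")
  rolled <- fr[c(3:nrow(fr), 1:2), c((ncol(fr) - 2):ncol(fr),
                                     1:(ncol(fr) - 3))]
  expect_equal(sh$frames[, , 2], rolled, tolerance = 1e-12)
  # subpixel shift then unshift correlates >= 0.99 on a smooth image
  fwd <- apply_drift(st, rbind(c(0, 0), c(1.3, -0.7)))
  bwd <- apply_drift(fwd, rbind(c(0, 0), c(-1.3, 0.7)))
  inner <- as.vector(fr[6:90, 6:90])
  expect_gte(cor(inner, as.vector(bwd$frames[6:90, 6:90, 2])), 0.99)
  expect_error(apply_drift(st, matrix(0, 3, 2)), "T x 2")
})
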