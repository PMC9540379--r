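# Renders a single straight filament at a given angle into a frame
# (local helper, independent of the simulator).
straight_filament_frame <- function(h = 64, w = 64, base = c(12, 32),
                                    theta = 0, len = 40, sigma = 0.8,
                                    peak = 100, bg = 10) {
  fr <- matrix(bg, h, w)
  s <- seq(0, len, by = 0.25)
  cx <- base[1] + s * cos(theta)
  cy <- base[2] + s * sin(theta)
  for (x in 0:(w - 1)) for (y in 0:(h - 1)) {
    d2 <- min((x - cx)^2 + (y - cy)^2)
    fr[y + 1, x + 1] <- fr[y + 1, x + 1] + peak * exp(-d2 / (2 * sigma^2))
  }
  fr
}

test_that("init_seed resamples the polyline into exact equal segments", {
  fr <- matrix(0, 64, 64)
  cfg <- trace_config(segment_length_px = 4)
  sd45 <- cilium_seed(c(10, 10),
                      rbind(c(10, 10), c(10 + 20 / sqrt(2), 10 + 20 / sqrt(2))))
  tr <- init_seed(fr, sd45, cfg)
  expect_equal(length(tr$theta), 5L)
  expect_equal(tr$theta, rep(pi / 4, 5), tolerance = 1e-12)
  seg_len <- sqrt(rowSums(diff(tr$nodes)^2))
  expect_equal(seg_len, rep(4, 5), tolerance = 1e-12)
  expect_equal(tr$nodes[1, ], c(10, 10))
  # floor rule: 10 px polyline at segment length 4 gives 2 segments
  sd10 <- cilium_seed(c(5, 5), rbind(c(5, 5), c(15, 5)))
  expect_equal(length(init_seed(fr, sd10, cfg)$theta), 2L)
  # too-short polyline errors
  sd3 <- cilium_seed(c(5, 5), rbind(c(5, 5), c(8, 5)))
  expect_error(init_seed(fr, sd3, cfg), "too short")
  # polyline outside the image errors
  sd_out <- cilium_seed(c(60, 60), rbind(c(60, 60), c(80, 60)))
  expect_error(init_seed(fr, sd_out, cfg), "leaves the image")
})

test_that("seed constructor enforces base/polyline consistency", {
  expect_error(cilium_seed(c(1, 1), rbind(c(2, 2), c(3, 3))),
               "start at the base")
  expect_error(cilium_seed(c(1, 1), rbind(c(1, 1))), ">= 2 points")
})

test_that("segment_cost components behave as defined", {
  cfg <- trace_config(segment_length_px = 4)
  ctx <- list(prev_theta_in_frame = 0.1, prev_frame_theta_i = 0.2,
              prev_frame_node_i = c(24, 32), prev_frame_theta_prev = 0.15)
  cands <- seq(-0.3, 0.7, by = 0.05)
  # constant image with zero penalty weights: cost identical for all
  cfg0 <- trace_config(segment_length_px = 4, w_curv = 0, w_tvel = 0,
                       w_rvel = 0, w_dcurv = 0)
  cc <- segment_cost(matrix(5, 64, 64), c(20, 32), cands, ctx, cfg0, dt = 2)
  expect_equal(length(unique(round(cc$total, 12))), 1L)
  # total is the exact sum of the five components
  fr <- straight_filament_frame()
  cc2 <- segment_cost(fr / max(fr), c(20, 32), cands, ctx, cfg, dt = 2)
  expect_equal(cc2$total,
               cc2$intensity + cc2$curvature + cc2$tvel + cc2$rvel +
                 cc2$dcurv, tolerance = 1e-15)
  # noiseless filament along theta = 0, penalties off: argmin at 0
  cc3 <- segment_cost(fr / max(fr), c(20, 32), cands, ctx, cfg0, dt = 2)
  expect_equal(cands[which.min(cc3$total)], 0)
  # dominant curvature penalty forces the candidate nearest the
  # in-frame previous angle
  cfg_curv <- trace_config(segment_length_px = 4, w_intensity = 0,
                           w_curv = 1e6, w_tvel = 0, w_rvel = 0,
                           w_dcurv = 0)
  cc4 <- segment_cost(fr / max(fr), c(20, 32), cands, ctx, cfg_curv, dt = 2)
  expect_equal(cands[which.min(cc4$total)], 0.1)
})

test_that("trace_frame is a fixed point on an unchanged scene", {
  fr <- straight_filament_frame(theta = 0.3)
  cfg <- trace_config(segment_length_px = 4)
  seed <- cilium_seed(c(12, 32),
                      rbind(c(12, 32),
                            c(12 + 30 * cos(0.3), 32 + 30 * sin(0.3))))
  tr0 <- init_seed(fr, seed, cfg)
  res <- trace_frame(fr, tr0, cfg, theta0 = tr0$theta[1], dt = 2)
  # seed angles snap to the fixed candidate lattice (half a step) and
  # pixel-sampling asymmetry of the rendered tube can move the optimum
  # a further lattice step or two
  expect_lte(max(abs(res$trace$theta - tr0$theta)),
             2.5 * cfg$angle_step_rad + 1e-12)
  # exact segment length and anchored base survive tracing
  seg_len <- sqrt(rowSums(diff(res$trace$nodes)^2))
  expect_equal(seg_len, rep(4, length(tr0$theta)), tolerance = 1e-12)
  expect_equal(res$trace$nodes[1, ], c(12, 32))
})

test_that("ties on a constant image break toward the grid centre", {
  fr <- matrix(1, 64, 64)
  cfg <- trace_config(segment_length_px = 4, w_curv = 0, w_tvel = 0,
                      w_rvel = 0, w_dcurv = 0)
  seed <- cilium_seed(c(20, 32), rbind(c(20, 32), c(40, 32)))
  tr0 <- init_seed(fr, seed, cfg)
  res <- trace_frame(fr, tr0, cfg, theta0 = tr0$theta[1], dt = 2)
  # min-max normalization maps a constant frame to all-zero: every
  # candidate costs the same, so the lattice angle nearest the previous
  # angle must be returned (here the previous angle, 0, is on-lattice)
  expect_equal(res$trace$theta, tr0$theta, tolerance = 0)
  # off-lattice previous angle: tie-break picks its nearest lattice point
  tr_off <- tr0
  tr_off$theta <- tr0$theta + 0.3 * cfg$angle_step_rad
  res2 <- trace_frame(fr, tr_off, cfg, theta0 = tr_off$theta[1], dt = 2)
  expect_equal(res2$trace$theta, tr0$theta, tolerance = 1e-12)
})

test_that("trace_movie is deterministic and static scenes stay put", {
  sim <- small_scene(noise_sigma = 0, amplitude_rad = 0, n_frames = 6,
                     n_blobs = 2)
  sd <- seed_from_truth(sim$truth)
  fit1 <- trace_movie(sim$stack, sd)
  fit2 <- trace_movie(sim$stack, sd)
  expect_identical(fit1$theta, fit2$theta)
  expect_identical(fit1$costs, fit2$costs)
  # static noiseless filament: the trace settles onto the candidate
  # lattice within two frames (frame 0 is the off-lattice seed) and is
  # then identical in every frame
  for (t in 4:6) expect_equal(fit1$theta[t, ], fit1$theta[3, ],
                              tolerance = 1e-12)
  expect_lte(max(abs(fit1$theta[3, ] - fit1$theta[1, ])),
             4 * fit1$config$angle_step_rad + 1e-12)
  # cost breakdown has one entry per frame and finite bands
  expect_equal(nrow(fit1$costs), 6L)
})

test_that("tracing recovers ground truth across amplitude and SNR", {
  cases <- expand.grid(A = c(0.1, 0.3, 0.5), noise = c(10, 20))
  for (i in seq_len(nrow(cases))) {
    sim <- small_scene(noise_sigma = cases$noise[i], n_frames = 40,
                       amplitude_rad = cases$A[i], rng_seed = 20 + i)
    fit <- trace_movie(sim$stack, seed_from_truth(sim$truth))
    err <- median_angle_error_deg(fit, sim$truth)
    limit <- if (cases$noise[i] == 10) 2 else 5
    expect_lte(err, limit)
  }
})

test_that("a trace that runs off the image is truncated and flagged", {
  fr <- straight_filament_frame(h = 48, w = 48, base = c(30, 24),
                                theta = 0, len = 17)
  cfg <- trace_config(segment_length_px = 4)
  seed <- cilium_seed(c(30, 24), rbind(c(30, 24), c(46, 24)))
  tr0 <- init_seed(fr, seed, cfg)
  # push the previous trace so far right that the last probe leaves
  tr_shift <- tr0
  tr_shift$nodes <- tr0$nodes + cbind(rep(10, 5), 0)
  tr_shift$nodes[1, ] <- tr0$nodes[1, ] + c(10, 0)
  expect_warning(res <- trace_frame(fr, tr_shift, cfg,
                                    theta0 = tr0$theta[1], dt = 2),
                 "truncated")
  expect_false(is.na(res$trace$truncated_at))
})

test_that("cost diagnostics match the hand-computed population bands", {
  costs <- data.frame(frame = 0:4, intensity = 0, curvature = 0,
                      tvel = 0, rvel = 0, dcurv = 0,
                      total = c(1, 2, 3, 4, 5))
  d <- cost_diagnostics(costs)
  expect_equal(d$mean, 3)
  expect_equal(d$upper, 3 + 2 * sqrt(2))
  expect_equal(d$lower, 3 - 2 * sqrt(2))
  expect_length(d$outlier_frames, 0)
  # constant series: bands collapse, no outliers
  costs$total <- rep(2, 5)
  d2 <- cost_diagnostics(costs)
  expect_equal(d2$upper, 2)
  expect_equal(d2$lower, 2)
  # a spiking frame is flagged (6 frames: a lone spike sits at
  # z = sqrt(5) > 2 population SDs)
  costs6 <- rbind(costs, costs[5, ])
  costs6$frame <- 0:5
  costs6$total <- c(1, 1, 1, 1, 1, 40)
  expect_equal(cost_diagnostics(costs6)$outlier_frames, 5)
  expect_error(cost_diagnostics(costs[1, ]), "at least 2")
})
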