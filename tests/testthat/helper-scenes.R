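# Shared scene builders for the test suite. All scenes are generated in
# code at test time; geometry is kept small where the property under
# test does not depend on field size.

# Default small beating-cilium scene: 8 um cilium pivoting at 0.3 rad
# amplitude, 24 s period, 0.35 um/px, 2 s/frame.
small_scene <- function(noise_sigma = 10, n_frames = 60, rng_seed = 11,
                        amplitude_rad = 0.3, drift_sigma_px = 0,
                        n_blobs = 6, H = 160, W = 160,
                        base_xy = c(50, 80), length_um = 8,
                        wavenumber_per_um = 0) {
  mdl <- waveform_model(base_xy = base_xy, base_angle_rad = -0.6,
                        length_um = length_um,
                        amplitude_rad = amplitude_rad, period_s = 24,
                        wavenumber_per_um = wavenumber_per_um)
  rp <- render_params(noise_sigma = noise_sigma, n_blobs = n_blobs,
                      drift_sigma_px = drift_sigma_px, rng_seed = rng_seed)
  simulate_cilium_movie(mdl, rp, n_frames = n_frames,
                        geometry = list(H = H, W = W, pixel_size_um = 0.35,
                                        frame_interval_s = 2))
}

# Median per-segment angular error (degrees) of a fit vs ground truth.
median_angle_error_deg <- function(fit, truth) {
  s_mid <- (seq_len(fit$n_segments) - 0.5) *
    fit$config$segment_length_px * fit$pixel_size_um
  tt <- truth_theta_at(truth, s_mid)
  median(abs(atan2(sin(fit$theta - tt), cos(fit$theta - tt)))) * 180 / pi
}

# A smooth textured frame (sum of Gaussian bumps) for registration
# tests.
textured_frame <- function(h = 96, w = 96, n = 15, seed = 5) {
  set.seed(seed)
  fr <- matrix(10, h, w)
  for (i in seq_len(n)) {
    cx <- runif(1, 8, w - 9); cy <- runif(1, 8, h - 9)
    s <- runif(1, 2, 6); a <- runif(1, 20, 60)
    xs <- 0:(w - 1); ys <- 0:(h - 1)
    fr <- fr + a * outer(exp(-(ys - cy)^2 / (2 * s^2)),
                         exp(-(xs - cx)^2 / (2 * s^2)))
  }
  fr
}

# Rotate a square frame by +90 degrees in pixel coordinates
# (x' = -(y - c) + c, y' = (x - c) + c with y pointing down), so a
# structure at tangent angle theta appears at theta + pi/2.
rot90_frame <- function(m) t(m)[, ncol(m):1]

rot90_xy <- function(p, size) {
  c0 <- (size - 1) / 2
  cbind(-(p[, 2] - c0) + c0, (p[, 1] - c0) + c0)
}
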