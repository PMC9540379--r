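# Synthetic beating-cilium movies with exact ground truth.
#
# The generator emulates the acquisition regime of live islet-cilium
# recordings: a single fluorescently labelled primary cilium (5-10 um
# long, sub-micron wide) anchored at a fixed basal body, beating slowly
# (periods of order 20-30 s) inside a larger tissue context, imaged at
# >= 1 frame / 2 s on a 512 x 512 grid at 0.26-0.44 um/px.

#' Describe the true waveform of a simulated cilium
#'
#' The tangent angle follows a single-harmonic traveling wave
#' \deqn{\theta(s, t) = \theta_0 + A \sin(2\pi t / T - k s + \phi_0),}
#' where `s` is arc length from the base (um) and `t` time (s).
#' `wavenumber_per_um = 0` gives a rigid pivot (the whole cilium sweeps
#' as a stiff rod); `k > 0` sends a bending wave from base to tip.
#' Optional per-cycle multiplicative period jitter emulates the
#' irregular beat of real islet cilia.
#'
#' @param base_xy pixel coordinates `c(x, y)` of the fixed base.
#' @param base_angle_rad mean orientation theta0 (radians from +x axis).
#' @param length_um filament length L in micrometres (> 0).
#' @param amplitude_rad angular beat amplitude A in radians (>= 0).
#' @param period_s beat period in seconds (> 0).
#' @param wavenumber_per_um spatial wavenumber k (1/um, >= 0).
#' @param phase0_rad initial phase.
#' @param period_jitter_sd SD of the multiplicative Gaussian jitter
#'   applied to each beat cycle's period (0 = strictly periodic).
#' @return an object of class `waveform_model`.
#' @export
waveform_model <- function(base_xy, base_angle_rad = 0, length_um = 8,
                           amplitude_rad = 0.3, period_s = 24,
                           wavenumber_per_um = 0, phase0_rad = 0,
                           period_jitter_sd = 0) {
  stopifnot(length(base_xy) == 2, length_um > 0, amplitude_rad >= 0,
            period_s > 0, wavenumber_per_um >= 0, period_jitter_sd >= 0)
  structure(list(base_xy = as.numeric(base_xy),
                 base_angle_rad = base_angle_rad, length_um = length_um,
                 amplitude_rad = amplitude_rad, period_s = period_s,
                 wavenumber_per_um = wavenumber_per_um,
                 phase0_rad = phase0_rad,
                 period_jitter_sd = period_jitter_sd),
            class = "waveform_model")
}

#' Rendering and nuisance parameters for the simulator
#'
#' The filament is drawn with a Gaussian transverse profile of width
#' `psf_sigma_um` (default 0.25 um: a diffraction-limited, sub-micron
#' apparent width). `n_blobs` large dim Gaussian blobs emulate the
#' surrounding out-of-focus islet tissue; they are static in specimen
#' coordinates and move only with drift, which is what makes whole-field
#' drift a recoverable quantity, exactly as tissue autofluorescence does
#' in real recordings. Drift is a cumulative 2-D Gaussian random walk
#' with per-frame step SD `drift_sigma_px`. Noise is additive Gaussian
#' (clipped at zero), so SNR = (peak_intensity - background) /
#' noise_sigma.
#'
#' @param psf_sigma_um transverse Gaussian sigma of the filament (um).
#' @param peak_intensity filament centreline intensity above zero (a.u.).
#' @param background uniform background level (a.u.);
#'   `peak_intensity > background >= 0`.
#' @param noise_sigma additive Gaussian noise SD (a.u., >= 0).
#' @param drift_sigma_px per-frame random-walk drift step SD (px, >= 0).
#' @param n_blobs number of background tissue blobs.
#' @param blob_rel_intensity range of blob peak intensities relative to
#'   (peak_intensity - background).
#' @param blob_sigma_um range of blob Gaussian sigmas (um).
#' @param rng_seed integer seed; identical seeds give bit-identical
#'   movies.
#' @return an object of class `render_params`.
#' @export
render_params <- function(psf_sigma_um = 0.25, peak_intensity = 150,
                          background = 50, noise_sigma = 10,
                          drift_sigma_px = 0, n_blobs = 12,
                          blob_rel_intensity = c(0.15, 0.5),
                          blob_sigma_um = c(1.5, 4), rng_seed = 1L) {
  stopifnot(psf_sigma_um > 0, peak_intensity > background, background >= 0,
            noise_sigma >= 0, drift_sigma_px >= 0, n_blobs >= 0)
  structure(list(psf_sigma_um = psf_sigma_um,
                 peak_intensity = peak_intensity, background = background,
                 noise_sigma = noise_sigma, drift_sigma_px = drift_sigma_px,
                 n_blobs = n_blobs, blob_rel_intensity = blob_rel_intensity,
                 blob_sigma_um = blob_sigma_um,
                 rng_seed = as.integer(rng_seed)),
            class = "render_params")
}

# True tangent angle theta(s, t) for a vector of arc lengths (um) at one
# phase value (phase = 2*pi*t/T + phi0 for the jitter-free model).
.theta_of_s <- function(model, s_um, phase) {
  model$base_angle_rad +
    model$amplitude_rad * sin(phase - model$wavenumber_per_um * s_um)
}

# Integrate the tangent field from the base at arc-length step ds_px,
# returning node coordinates in pixels (drift-free). Midpoint rule keeps
# the chord length within O(ds^2) of ds.
.integrate_centerline <- function(model, phase, pixel_size_um, ds_px = 0.25) {
  len_px <- model$length_um / pixel_size_um
  n <- ceiling(len_px / ds_px)
  ds_px <- len_px / n
  s_mid_um <- (seq_len(n) - 0.5) * ds_px * pixel_size_um
  th <- .theta_of_s(model, s_mid_um, phase)
  x <- model$base_xy[1] + c(0, cumsum(cos(th) * ds_px))
  y <- model$base_xy[2] + c(0, cumsum(sin(th) * ds_px))
  cbind(x = x, y = y)
}

# Per-frame phase series. With jitter = 0 this is 2*pi*t/T + phi0;
# otherwise the instantaneous period of each beat cycle is scaled by an
# independent factor (1 + eps), eps ~ N(0, sd), drawn once per cycle.
.phase_series <- function(model, times_s) {
  if (model$period_jitter_sd == 0)
    return(2 * pi * times_s / model$period_s + model$phase0_rad)
  n_cycles <- ceiling(max(times_s) / model$period_s) + 2L
  fac <- pmax(0.2, 1 + stats::rnorm(n_cycles, sd = model$period_jitter_sd))
  periods <- model$period_s * fac
  bounds <- c(0, cumsum(periods))
  phase <- numeric(length(times_s))
  for (i in seq_along(times_s)) {
    cyc <- findInterval(times_s[i], bounds)
    frac <- (times_s[i] - bounds[cyc]) / periods[cyc]
    phase[i] <- 2 * pi * (cyc - 1 + frac) + model$phase0_rad
  }
  phase
}

# Add one Gaussian spot into `frame` (modified in place semantics via
# return), restricted to a +/- 4 sigma bounding box.
.add_gaussian_spot <- function(frame, cx, cy, sigma_px, amp) {
  h <- nrow(frame); w <- ncol(frame)
  r <- ceiling(4 * sigma_px)
  x0 <- max(0, floor(cx - r)); x1 <- min(w - 1, ceiling(cx + r))
  y0 <- max(0, floor(cy - r)); y1 <- min(h - 1, ceiling(cy + r))
  if (x0 > x1 || y0 > y1) return(frame)
  xs <- x0:x1; ys <- y0:y1
  gx <- exp(-(xs - cx)^2 / (2 * sigma_px^2))
  gy <- exp(-(ys - cy)^2 / (2 * sigma_px^2))
  frame[ys + 1, xs + 1] <- frame[ys + 1, xs + 1] + amp * outer(gy, gx)
  frame
}

# Render a filament (dense centerline in px, possibly drifted) into a
# frame: tube profile peak * exp(-d^2 / 2 sigma^2) from the minimum
# distance d of each pixel to the centerline samples.
.render_filament <- function(frame, nodes, sigma_px, peak) {
  h <- nrow(frame); w <- ncol(frame)
  r <- ceiling(4 * sigma_px)
  x0 <- max(0, floor(min(nodes[, 1]) - r))
  x1 <- min(w - 1, ceiling(max(nodes[, 1]) + r))
  y0 <- max(0, floor(min(nodes[, 2]) - r))
  y1 <- min(h - 1, ceiling(max(nodes[, 2]) + r))
  if (x0 > x1 || y0 > y1) return(frame)
  xs <- x0:x1; ys <- y0:y1
  # squared distance of every bbox pixel to every centerline sample
  dx2 <- outer(xs, nodes[, 1], function(a, b) (a - b)^2)  # nx x K
  dy2 <- outer(ys, nodes[, 2], function(a, b) (a - b)^2)  # ny x K
  nx <- length(xs); ny <- length(ys)
  dmin2 <- matrix(Inf, ny, nx)
  for (k in seq_len(nrow(nodes))) {
    d2 <- outer(dy2[, k], dx2[, k], `+`)
    dmin2 <- pmin(dmin2, d2)
  }
  frame[ys + 1, xs + 1] <- frame[ys + 1, xs + 1] +
    peak * exp(-dmin2 / (2 * sigma_px^2))
  frame
}

#' Simulate a ground-truthed beating-cilium movie
#'
#' Renders one cilium following a [waveform_model()] traveling wave into
#' a calibrated time-lapse stack, with background tissue blobs,
#' whole-field random-walk drift and additive noise per
#' [render_params()]. The exact tangent-angle field, centreline and
#' drift are returned alongside the movie so that tracing and waveform
#' metrics can be validated by parameter recovery.
#'
#' @param model a [waveform_model()].
#' @param render a [render_params()].
#' @param n_frames number of frames (>= 1).
#' @param geometry list with `H`, `W` (pixels), `pixel_size_um`,
#'   `frame_interval_s`. Defaults give a 512 x 512 field at 0.35 um/px
#'   sampled every 2 s.
#' @return a list with elements
#'   \describe{
#'     \item{stack}{the rendered [cilium_stack()];}
#'     \item{truth}{a `cilium_truth` list: `s_um` (arc-length grid),
#'       `theta` (n_frames x length(s_um) matrix of true tangent
#'       angles), `centerline` (list of drift-free node matrices),
#'       `drift` (n_frames x 2 cumulative drift, first row zero),
#'       `phase` (per-frame phase) and `model`.}
#'   }
#' @examples
#' mdl <- waveform_model(base_xy = c(40, 40), length_um = 6,
#'                       amplitude_rad = 0.3)
#' rp <- render_params(noise_sigma = 5, n_blobs = 0, rng_seed = 7)
#' sim <- simulate_cilium_movie(mdl, rp, n_frames = 12,
#'                              geometry = list(H = 80, W = 80,
#'                                              pixel_size_um = 0.35,
#'                                              frame_interval_s = 2))
#' sim$stack
#' @export
simulate_cilium_movie <- function(model, render, n_frames,
                                  geometry = list(H = 512, W = 512,
                                                  pixel_size_um = 0.35,
                                                  frame_interval_s = 2)) {
  stopifnot(inherits(model, "waveform_model"),
            inherits(render, "render_params"), n_frames >= 1)
  H <- geometry$H; W <- geometry$W
  px <- geometry$pixel_size_um; dt <- geometry$frame_interval_s
  if (H <= 0 || W <= 0 || px <= 0 || dt <= 0)
    stop("non-positive stack geometry")
  with_seed(render$rng_seed, {
    times <- (seq_len(n_frames) - 1) * dt
    phase <- .phase_series(model, times)
    drift <- matrix(0, n_frames, 2, dimnames = list(NULL, c("dx", "dy")))
    if (n_frames > 1 && render$drift_sigma_px > 0) {
      steps <- matrix(stats::rnorm(2 * (n_frames - 1),
                                   sd = render$drift_sigma_px),
                      n_frames - 1, 2)
      drift[-1, ] <- apply(steps, 2, cumsum)
    }
    blobs <- NULL
    if (render$n_blobs > 0) {
      margin <- 4
      blobs <- data.frame(
        cx = stats::runif(render$n_blobs, margin, W - 1 - margin),
        cy = stats::runif(render$n_blobs, margin, H - 1 - margin),
        sigma_px = stats::runif(render$n_blobs, render$blob_sigma_um[1],
                                render$blob_sigma_um[2]) / px,
        amp = stats::runif(render$n_blobs, render$blob_rel_intensity[1],
                           render$blob_rel_intensity[2]) *
          (render$peak_intensity - render$background))
    }
    sigma_px <- render$psf_sigma_um / px
    s_grid_um <- seq(0, model$length_um, length.out = 65)
    theta_truth <- matrix(0, n_frames, length(s_grid_um))
    centerline <- vector("list", n_frames)
    frames <- array(0, c(H, W, n_frames))
    for (t in seq_len(n_frames)) {
      nodes <- .integrate_centerline(model, phase[t], px)
      centerline[[t]] <- nodes
      theta_truth[t, ] <- .theta_of_s(model, s_grid_um, phase[t])
      shifted <- sweep(nodes, 2, drift[t, ], `+`)
      if (any(shifted[, 1] < 0) || any(shifted[, 1] > W - 1) ||
          any(shifted[, 2] < 0) || any(shifted[, 2] > H - 1))
        stop("filament leaves the frame at frame ", t - 1)
      fr <- matrix(render$background, H, W)
      if (!is.null(blobs)) {
        for (b in seq_len(nrow(blobs)))
          fr <- .add_gaussian_spot(fr, blobs$cx[b] + drift[t, 1],
                                   blobs$cy[b] + drift[t, 2],
                                   blobs$sigma_px[b], blobs$amp[b])
      }
      fr <- .render_filament(fr, shifted, sigma_px,
                             render$peak_intensity - render$background)
      if (render$noise_sigma > 0)
        fr <- pmax(fr + stats::rnorm(H * W, sd = render$noise_sigma), 0)
      frames[, , t] <- fr
    }
    truth <- structure(list(s_um = s_grid_um, theta = theta_truth,
                            centerline = centerline, drift = drift,
                            phase = phase, model = model),
                       class = "cilium_truth")
    list(stack = cilium_stack(frames, px, dt), truth = truth)
  })
}

#' True tangent angles interpolated at given arc lengths
#'
#' Convenience accessor for comparing a traced angle field against the
#' simulator's ground truth at the tracer's segment midpoints.
#'
#' @param truth the `truth` element returned by
#'   [simulate_cilium_movie()].
#' @param s_um arc lengths from the base, in micrometres.
#' @return an n_frames x length(s_um) matrix of true angles.
#' @export
truth_theta_at <- function(truth, s_um) {
  stopifnot(inherits(truth, "cilium_truth"))
  out <- matrix(0, nrow(truth$theta), length(s_um))
  for (t in seq_len(nrow(truth$theta)))
    out[t, ] <- stats::approx(truth$s_um, truth$theta[t, ], xout = s_um,
                              rule = 2)$y
  out
}

#' Add Gaussian noise to a single frame
#'
#' @param frame numeric matrix.
#' @param sigma noise SD (>= 0).
#' @param seed integer seed; the operation is deterministic per seed.
#' @return the noisy frame, clipped at zero.
#' @export
add_noise <- function(frame, sigma, seed) {
  if (sigma < 0) stop("`sigma` must be >= 0")
  if (sigma == 0) return(frame)
  with_seed(seed, {
    noisy <- frame + stats::rnorm(length(frame), sd = sigma)
    matrix(pmax(noisy, 0), nrow(frame), ncol(frame))
  })
}

#' Translate every frame of a stack by a per-frame shift
#'
#' Fabricates the whole-islet motion that occurs during live imaging
#' (treatments, osmotic pressure changes) so that stabilization can be
#' tested against known drift. Frame `t` is translated by
#' `drift[t, ] = (dx, dy)` with bilinear interpolation.
#'
#' @param stack a [cilium_stack()].
#' @param drift numeric T x 2 matrix of (dx, dy) shifts in pixels.
#' @param boundary `"fill"` (constant fill with the frame median, or
#'   `fill`) or `"wrap"` (periodic); with `"wrap"`, integer shifts equal
#'   an exact index roll.
#' @param fill fill value for `boundary = "fill"`; default frame median.
#' @return the drifted [cilium_stack()].
#' @export
apply_drift <- function(stack, drift, boundary = c("fill", "wrap"),
                        fill = NULL) {
  boundary <- match.arg(boundary)
  T <- n_frames(stack)
  drift <- as.matrix(drift)
  if (nrow(drift) != T || ncol(drift) != 2)
    stop("`drift` must be a T x 2 matrix matching the stack")
  out <- stack$frames
  for (t in seq_len(T))
    out[, , t] <- translate_frame(stack$frames[, , t], drift[t, 1],
                                  drift[t, 2], boundary = boundary,
                                  fill = fill)
  cilium_stack(out, stack$pixel_size_um, stack$frame_interval_s)
}
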