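# Seeded frame-by-frame cilium tracing.
#
# The cilium is represented per frame as a chain of N equal-length
# segments anchored at a stationary base. For each frame, segment
# angles are chosen in order from base to tip by exhaustive grid search
# over candidate angles centred on the previous frame's angle, each
# candidate scored by a penalized intensity cost: the (negative)
# weighted mean image intensity under a rotating rectangular probe
# array spanning the segment, plus quadratic penalties on curvature,
# translational velocity, rotational velocity and the rate of change of
# curvature. The penalties keep the trace on track where focus,
# contrast, noise or nearby objects make the local angle ambiguous.

#' Tracing configuration
#'
#' @param segment_length_px arc-length step (chain segment length) in
#'   pixels. The default 2 px (~0.7 um at 0.35 um/px) resolves ~11
#'   segments on an 8 um cilium, keeping the length quantization of the
#'   seed below 5 percent while leaving enough probe support per
#'   segment.
#' @param probe_width_px transverse extent w of the probe array (px).
#'   The default 2 px keeps the probe comparable to the sub-micron
#'   apparent width of a diffraction-limited cilium, which sharpens the
#'   intensity cost as a function of candidate angle.
#' @param probe_samples integer `c(n_along, n_across)` sample counts of
#'   the probe array.
#' @param angle_halfwidth_rad half-width of the candidate-angle grid
#'   around the previous frame's segment angle (default 30 degrees);
#'   doubles as a hard limit on per-frame rotational velocity.
#' @param angle_step_rad candidate grid step (default 0.5 degree).
#' @param w_intensity weight of the (negative) probe intensity term;
#'   intensities are min-max normalized per frame, so the term lies in
#'   [-w_intensity, 0].
#' @param w_curv weight of the within-frame curvature penalty
#'   (rad^-2): (theta_i - theta_{i-1})^2 against the previous segment
#'   in the same frame.
#' @param w_tvel weight of the translational-velocity penalty
#'   (s^2 px^-2): squared displacement of the segment end node since
#'   the previous frame over dt^2.
#' @param w_rvel weight of the rotational-velocity penalty (s^2
#'   rad^-2): squared angular change since the previous frame over
#'   dt^2.
#' @param w_dcurv weight of the rate-of-change-of-curvature penalty
#'   (s^2 rad^-2): squared temporal change of the local curvature
#'   angle difference over dt^2.
#' @param transverse_profile `"gaussian"` (sigma = w/4, favouring
#'   centreline alignment) or `"uniform"` transverse weighting of probe
#'   samples.
#' @return an object of class `trace_config`.
#' @export
trace_config <- function(segment_length_px = 2, probe_width_px = 2,
                         probe_samples = c(9L, 7L),
                         angle_halfwidth_rad = pi / 6,
                         angle_step_rad = pi / 360,
                         w_intensity = 1, w_curv = 0.4, w_tvel = 0.002,
                         w_rvel = 0.3, w_dcurv = 0.01,
                         transverse_profile = c("gaussian", "uniform")) {
  transverse_profile <- match.arg(transverse_profile)
  stopifnot(segment_length_px > 0, probe_width_px > 0,
            length(probe_samples) == 2, all(probe_samples >= 1),
            angle_step_rad > 0, angle_halfwidth_rad >= angle_step_rad,
            w_intensity >= 0, w_curv >= 0, w_tvel >= 0, w_rvel >= 0,
            w_dcurv >= 0)
  structure(list(segment_length_px = segment_length_px,
                 probe_width_px = probe_width_px,
                 probe_samples = as.integer(probe_samples),
                 angle_halfwidth_rad = angle_halfwidth_rad,
                 angle_step_rad = angle_step_rad,
                 w_intensity = w_intensity, w_curv = w_curv,
                 w_tvel = w_tvel, w_rvel = w_rvel, w_dcurv = w_dcurv,
                 transverse_profile = transverse_profile),
            class = "trace_config")
}

#' User seed for tracing
#'
#' On the first analyzed frame the user identifies the stationary
#' ciliary base and clicks a polyline from the base toward the tip;
#' this fixes the traced length and the initial angle for automatic
#' tracing.
#'
#' @param base_xy pixel coordinates `c(x, y)` of the base.
#' @param polyline M x 2 matrix of (x, y) points starting at the base.
#' @return an object of class `cilium_seed`.
#' @export
cilium_seed <- function(base_xy, polyline) {
  base_xy <- as.numeric(base_xy)
  polyline <- as.matrix(polyline)
  if (length(base_xy) != 2 || ncol(polyline) != 2 || nrow(polyline) < 2)
    stop("seed needs base c(x, y) and a polyline of >= 2 points")
  if (max(abs(polyline[1, ] - base_xy)) > 1e-6)
    stop("seed polyline must start at the base point")
  structure(list(base_xy = base_xy, polyline = polyline),
            class = "cilium_seed")
}

# Total arc length of a polyline.
.polyline_length <- function(p) sum(sqrt(rowSums(diff(p)^2)))

#' Resample the seed polyline into an equal-segment frame trace
#'
#' The user polyline is resampled at equal arc-length steps into
#' `N = floor(length / segment_length_px)` segments (the tip remainder
#' is dropped); nodes are then rebuilt from the base with exactly
#' `segment_length_px` steps along the resampled tangent angles, so the
#' equal-segment-length invariant holds to machine precision.
#'
#' @param first_frame numeric matrix, the first analyzed frame.
#' @param seed a [cilium_seed()].
#' @param config a [trace_config()].
#' @return a `frame_trace` list: `nodes` ((N+1) x 2, node 0 = base),
#'   `theta` (N tangent angles, radians from the +x axis),
#'   `frame_index` (= the first analyzed frame).
#' @export
init_seed <- function(first_frame, seed, config) {
  stopifnot(inherits(seed, "cilium_seed"), inherits(config, "trace_config"))
  p <- seed$polyline
  ds <- config$segment_length_px
  h <- nrow(first_frame); w <- ncol(first_frame)
  if (any(p[, 1] < 0 | p[, 1] > w - 1 | p[, 2] < 0 | p[, 2] > h - 1))
    stop("seed polyline leaves the image")
  seg <- sqrt(rowSums(diff(p)^2))
  L <- sum(seg)
  N <- floor(L / ds + 1e-9)
  if (N < 1)
    stop(sprintf("seed polyline too short: %.2f px < one segment (%g px)",
                 L, ds))
  cum <- c(0, cumsum(seg))
  s_target <- (0:N) * ds
  s_target[N + 1] <- min(s_target[N + 1], L)
  rx <- stats::approx(cum, p[, 1], xout = s_target, ties = "ordered")$y
  ry <- stats::approx(cum, p[, 2], xout = s_target, ties = "ordered")$y
  theta <- atan2(diff(ry), diff(rx))
  nodes <- matrix(0, N + 1, 2)
  nodes[1, ] <- seed$base_xy
  for (i in seq_len(N))
    nodes[i + 1, ] <- nodes[i, ] + ds * c(cos(theta[i]), sin(theta[i]))
  structure(list(nodes = nodes, theta = theta, frame_index = 0L),
            class = "frame_trace")
}

# Probe array sample offsets in the segment's local frame: `along` runs
# 0..ds (cell-centred), `across` spans [-w/2, w/2]; returns the flat
# offset vectors and transverse weights.
.probe_layout <- function(config) {
  n_along <- config$probe_samples[1]
  n_across <- config$probe_samples[2]
  ds <- config$segment_length_px
  w <- config$probe_width_px
  s_off <- (seq_len(n_along) - 0.5) / n_along * ds
  c_off <- if (n_across == 1) 0 else
    seq(-w / 2, w / 2, length.out = n_across)
  wt <- if (config$transverse_profile == "gaussian")
    exp(-c_off^2 / (2 * (w / 4)^2)) else rep(1, n_across)
  list(s = rep(s_off, times = n_across),
       c = rep(c_off, each = n_along),
       wt = rep(wt, each = n_along))
}

#' Penalized cost of candidate segment angles
#'
#' Evaluates, for each candidate angle, the five cost components used
#' by the tracer (all angle differences wrapped to (-pi, pi]):
#' \describe{
#'   \item{intensity}{`-w_intensity` times the transverse-weighted mean
#'     of bilinearly interpolated frame intensities over the
#'     `n_along x n_across` rectangular probe array spanning one
#'     segment length along the candidate direction and
#'     `probe_width_px` across it;}
#'   \item{curvature}{`w_curv * (theta - prev_theta_in_frame)^2`;}
#'   \item{tvel}{`w_tvel * ||endnode(theta) - prev_frame_node_i||^2 / dt^2`;}
#'   \item{rvel}{`w_rvel * (theta - prev_frame_theta_i)^2 / dt^2`;}
#'   \item{dcurv}{`w_dcurv * ((theta - prev_theta_in_frame) -
#'     (prev_frame_theta_i - prev_frame_theta_prev))^2 / dt^2`.}
#' }
#' Probe samples falling outside the image take `background` (the frame
#' median by default).
#'
#' @param frame numeric matrix (normalize beforehand if desired;
#'   [trace_frame()] min-max normalizes per frame).
#' @param start_node `c(x, y)` segment start in pixels.
#' @param theta numeric vector of candidate angles (radians).
#' @param context list with `prev_theta_in_frame` (angle of the
#'   previous segment in this frame; the seed initial angle for the
#'   first segment), `prev_frame_theta_i`, `prev_frame_node_i` (end
#'   node of this segment in the previous frame) and
#'   `prev_frame_theta_prev`.
#' @param config a [trace_config()].
#' @param dt frame interval in seconds.
#' @param background fill intensity for out-of-image probe samples.
#' @return data.frame with one row per candidate: `theta`, `intensity`,
#'   `curvature`, `tvel`, `rvel`, `dcurv`, `total`, `n_inside` (probe
#'   samples inside the image).
#' @export
segment_cost <- function(frame, start_node, theta, context, config,
                         dt = 1, background = stats::median(frame)) {
  stopifnot(inherits(config, "trace_config"))
  lay <- .probe_layout(config)
  ds <- config$segment_length_px
  ct <- cos(theta); st <- sin(theta)
  # sample coordinates: start + s*u + c*v, u = (cos, sin), v = (-sin, cos)
  x <- start_node[1] + outer(lay$s, ct) - outer(lay$c, st)
  y <- start_node[2] + outer(lay$s, st) + outer(lay$c, ct)
  vals <- interp_bilinear(frame, as.vector(x), as.vector(y))
  n_inside <- colSums(matrix(!is.na(vals), nrow = length(lay$s)))
  vals[is.na(vals)] <- background
  vm <- matrix(vals, nrow = length(lay$s))
  intensity <- -config$w_intensity *
    as.vector(crossprod(lay$wt, vm)) / sum(lay$wt)
  dth_frame <- wrap_angle(theta - context$prev_theta_in_frame)
  curvature <- config$w_curv * dth_frame^2
  ex <- start_node[1] + ds * ct
  ey <- start_node[2] + ds * st
  tvel <- config$w_tvel *
    ((ex - context$prev_frame_node_i[1])^2 +
     (ey - context$prev_frame_node_i[2])^2) / dt^2
  rvel <- config$w_rvel *
    wrap_angle(theta - context$prev_frame_theta_i)^2 / dt^2
  prev_dth <- wrap_angle(context$prev_frame_theta_i -
                           context$prev_frame_theta_prev)
  dcurv <- config$w_dcurv * (dth_frame - prev_dth)^2 / dt^2
  data.frame(theta = theta, intensity = intensity, curvature = curvature,
             tvel = tvel, rvel = rvel, dcurv = dcurv,
             total = intensity + curvature + tvel + rvel + dcurv,
             n_inside = n_inside)
}

# Argmin with deterministic tie-breaking: exact ties go to the
# candidate nearest the grid centre, then to the numerically smaller
# angle.
.pick_candidate <- function(total, theta, theta_center) {
  best <- min(total)
  tied <- which(total == best)
  if (length(tied) > 1) {
    d <- abs(wrap_angle(theta[tied] - theta_center))
    tied <- tied[d == min(d)]
    if (length(tied) > 1) tied <- tied[which.min(theta[tied])]
  }
  tied[1]
}

# Cost components of an existing frame trace (used for the seed frame,
# whose temporal penalties are zero by definition).
.trace_static_cost <- function(frame_norm, trace, config, theta0, bg) {
  comp <- c(intensity = 0, curvature = 0, tvel = 0, rvel = 0, dcurv = 0)
  prev_th <- theta0
  for (i in seq_along(trace$theta)) {
    ctx <- list(prev_theta_in_frame = prev_th,
                prev_frame_theta_i = trace$theta[i],
                prev_frame_node_i = trace$nodes[i + 1, ],
                prev_frame_theta_prev = prev_th)
    cc <- segment_cost(frame_norm, trace$nodes[i, ], trace$theta[i], ctx,
                       config, dt = 1, background = bg)
    comp["intensity"] <- comp["intensity"] + cc$intensity
    comp["curvature"] <- comp["curvature"] + cc$curvature
    prev_th <- trace$theta[i]
  }
  comp
}

#' Trace one frame given the previous frame's trace
#'
#' Segments are fitted in order from base to tip. For segment i the
#' candidate grid spans `theta_{i,t-1} +/- angle_halfwidth` in steps of
#' `angle_step`, with grid points snapped to absolute multiples of
#' `angle_step` (a fixed lattice): re-centring the lattice on the
#' previous angle would let quantization drift accumulate frame to
#' frame, whereas on the fixed lattice a static scene reproduces the
#' identical trace every frame. The minimizer of [segment_cost()] is
#' taken (ties break toward the
#' grid centre, then the smaller angle) and the next node is advanced
#' by one segment length. The within-frame curvature terms (curvature
#' and rate of change of curvature) are omitted for the first segment,
#' which has no preceding segment in the frame: anchoring them to the
#' fixed seed angle would systematically shrink the sweep of a pivoting
#' cilium. `theta0`, the seed initial angle, remains the in-frame
#' reference used when evaluating the seed frame itself. If the probe
#' array falls entirely outside the image for every candidate, the
#' trace is truncated at the previous segment and flagged; remaining
#' segments carry the previous frame's angles.
#'
#' @param frame numeric matrix (raw intensities; min-max normalized
#'   internally).
#' @param prev_trace the previous frame's `frame_trace`.
#' @param config a [trace_config()].
#' @param theta0 seed initial angle (radians).
#' @param dt frame interval in seconds.
#' @return list with `trace` (the new `frame_trace`, possibly carrying
#'   a `truncated_at` field) and `cost` (named numeric: summed
#'   intensity, curvature, tvel, rvel, dcurv, total).
#' @export
trace_frame <- function(frame, prev_trace, config, theta0, dt = 1) {
  rng <- range(frame)
  fnorm <- if (rng[2] > rng[1]) (frame - rng[1]) / (rng[2] - rng[1])
           else frame * 0
  bg <- stats::median(fnorm)
  N <- length(prev_trace$theta)
  K <- floor(config$angle_halfwidth_rad / config$angle_step_rad + 1e-9)
  grid_off <- (-K:K) * config$angle_step_rad
  nodes <- prev_trace$nodes
  nodes[1, ] <- prev_trace$nodes[1, ]   # base is anchored
  theta <- prev_trace$theta
  comp <- c(intensity = 0, curvature = 0, tvel = 0, rvel = 0, dcurv = 0)
  truncated_at <- NA_integer_
  prev_th_in_frame <- theta0
  cfg_first <- config
  cfg_first$w_curv <- 0
  cfg_first$w_dcurv <- 0
  for (i in seq_len(N)) {
    theta_center <- prev_trace$theta[i]
    cands <- round(theta_center / config$angle_step_rad) *
      config$angle_step_rad + grid_off
    ctx <- list(
      prev_theta_in_frame = prev_th_in_frame,
      prev_frame_theta_i = prev_trace$theta[i],
      prev_frame_node_i = prev_trace$nodes[i + 1, ],
      prev_frame_theta_prev = if (i == 1) theta0 else prev_trace$theta[i - 1])
    cc <- segment_cost(fnorm, nodes[i, ], cands, ctx,
                       if (i == 1) cfg_first else config, dt = dt,
                       background = bg)
    if (all(cc$n_inside == 0)) {
      truncated_at <- i - 1L
      break
    }
    j <- .pick_candidate(cc$total, cands, theta_center)
    theta[i] <- cands[j]
    nodes[i + 1, ] <- nodes[i, ] + config$segment_length_px *
      c(cos(theta[i]), sin(theta[i]))
    comp <- comp + c(cc$intensity[j], cc$curvature[j], cc$tvel[j],
                     cc$rvel[j], cc$dcurv[j])
    prev_th_in_frame <- theta[i]
  }
  if (!is.na(truncated_at)) {
    # carry the previous frame's geometry for the unreachable tip
    for (i in (truncated_at + 1):N) {
      theta[i] <- prev_trace$theta[i]
      nodes[i + 1, ] <- nodes[i, ] + config$segment_length_px *
        c(cos(theta[i]), sin(theta[i]))
    }
    warning("probe array left the image; trace truncated at segment ",
            truncated_at)
  }
  tr <- structure(list(nodes = nodes, theta = theta,
                       frame_index = prev_trace$frame_index + 1L,
                       truncated_at = truncated_at),
                  class = "frame_trace")
  list(trace = tr, cost = c(comp, total = sum(comp)))
}

#' Trace a cilium through a movie
#'
#' The main fitting function. The seed polyline is resampled into the
#' first analyzed frame's trace ([init_seed()]); subsequent frames are
#' traced sequentially with [trace_frame()]. The movie should be
#' drift-stabilized first (see [estimate_drift()]); the base is held
#' fixed at the seed position throughout. The result is the raw
#' tangent-angle field theta(segment, frame) plus the per-frame cost
#' breakdown; waveform metrics are obtained with
#' [summary.cilium_trace()].
#'
#' @param stack a [cilium_stack()].
#' @param seed a [cilium_seed()] clicked on the first analyzed frame.
#' @param config a [trace_config()].
#' @param frames optional `c(start, end)` half-open 0-based frame
#'   range; default all frames.
#' @return an object of class `cilium_trace`: list with `theta`
#'   (T x N matrix), `nodes` ((N+1) x 2 x T array), `frames` (analyzed
#'   0-based indices), `costs` (data.frame frame/intensity/curvature/
#'   tvel/rvel/dcurv/total; the seed frame has zero temporal
#'   penalties), `config`, `seed`, `theta0`, `truncated` (logical per
#'   frame), and the stack calibration.
#' @examples
#' mdl <- waveform_model(base_xy = c(30, 40), length_um = 5,
#'                       amplitude_rad = 0.25, period_s = 24)
#' rp <- render_params(noise_sigma = 0, n_blobs = 0)
#' sim <- simulate_cilium_movie(mdl, rp, n_frames = 6,
#'   geometry = list(H = 80, W = 80, pixel_size_um = 0.35,
#'                   frame_interval_s = 2))
#' sd <- seed_from_truth(sim$truth)
#' fit <- trace_movie(sim$stack, sd)
#' fit
#' summary(fit)
#' @export
trace_movie <- function(stack, seed, config = trace_config(),
                        frames = NULL) {
  stopifnot(inherits(stack, "cilium_stack"), inherits(seed, "cilium_seed"),
            inherits(config, "trace_config"))
  T_all <- n_frames(stack)
  if (is.null(frames)) frames <- c(0L, T_all)
  sub <- select_frames(stack, frames)
  T <- n_frames(sub)
  dt <- stack$frame_interval_s
  tr0 <- init_seed(sub$frames[, , 1], seed, config)
  tr0$frame_index <- frames[1]
  theta0 <- tr0$theta[1]
  N <- length(tr0$theta)
  theta <- matrix(0, T, N)
  nodes <- array(0, c(N + 1, 2, T))
  truncated <- logical(T)
  costs <- matrix(0, T, 6,
                  dimnames = list(NULL, c("intensity", "curvature", "tvel",
                                          "rvel", "dcurv", "total")))
  theta[1, ] <- tr0$theta
  nodes[, , 1] <- tr0$nodes
  f1 <- sub$frames[, , 1]
  rng <- range(f1)
  f1n <- if (rng[2] > rng[1]) (f1 - rng[1]) / (rng[2] - rng[1]) else f1 * 0
  cc0 <- .trace_static_cost(f1n, tr0, config, theta0, stats::median(f1n))
  costs[1, ] <- c(cc0, total = sum(cc0))
  prev <- tr0
  if (T > 1) {
    for (t in 2:T) {
      res <- trace_frame(sub$frames[, , t], prev, config, theta0, dt = dt)
      theta[t, ] <- res$trace$theta
      nodes[, , t] <- res$trace$nodes
      truncated[t] <- !is.na(res$trace$truncated_at)
      costs[t, ] <- res$cost
      prev <- res$trace
    }
  }
  structure(list(theta = theta, nodes = nodes,
                 frames = seq.int(frames[1], frames[2] - 1L),
                 costs = data.frame(frame = seq.int(frames[1],
                                                    frames[2] - 1L),
                                    costs),
                 config = config, seed = seed, theta0 = theta0,
                 truncated = truncated,
                 n_segments = N,
                 pixel_size_um = stack$pixel_size_um,
                 frame_interval_s = stack$frame_interval_s),
            class = "cilium_trace")
}

#' Build a tracing seed from simulator ground truth
#'
#' Emulates a careful user click along the true centreline of the first
#' frame of a simulated movie.
#'
#' @param truth the `truth` element of [simulate_cilium_movie()].
#' @param n_points number of polyline points.
#' @return a [cilium_seed()].
#' @export
seed_from_truth <- function(truth, n_points = 16L) {
  stopifnot(inherits(truth, "cilium_truth"))
  cl <- truth$centerline[[1]]
  idx <- unique(round(seq(1, nrow(cl), length.out = n_points)))
  cilium_seed(base_xy = cl[1, ], polyline = cl[idx, ])
}

#' Construct a cilium trace from an angle matrix
#'
#' Builds the node geometry implied by a tangent-angle field; useful
#' for computing waveform metrics on externally produced or analytic
#' angle data.
#'
#' @param theta T x N matrix of tangent angles (radians).
#' @param segment_length_px segment length in pixels.
#' @param pixel_size_um,frame_interval_s calibration.
#' @param base_xy base position (pixels).
#' @return a `cilium_trace`.
#' @export
cilium_trace <- function(theta, segment_length_px, pixel_size_um,
                         frame_interval_s, base_xy = c(0, 0)) {
  theta <- as.matrix(theta)
  T <- nrow(theta); N <- ncol(theta)
  nodes <- array(0, c(N + 1, 2, T))
  for (t in seq_len(T)) {
    nodes[1, , t] <- base_xy
    for (i in seq_len(N))
      nodes[i + 1, , t] <- nodes[i, , t] + segment_length_px *
        c(cos(theta[t, i]), sin(theta[t, i]))
  }
  cfg <- trace_config(segment_length_px = segment_length_px)
  costs <- data.frame(frame = seq_len(T) - 1L, intensity = 0,
                      curvature = 0, tvel = 0, rvel = 0, dcurv = 0,
                      total = 0)
  structure(list(theta = theta, nodes = nodes, frames = seq_len(T) - 1L,
                 costs = costs, config = cfg, seed = NULL,
                 theta0 = theta[1, 1], truncated = logical(T),
                 n_segments = N, pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s),
            class = "cilium_trace")
}

#' @export
print.cilium_trace <- function(x, ...) {
  cat(sprintf(
    "<cilium_trace> %d frames x %d segments (segment %g px, %.3g um/px)\n",
    nrow(x$theta), x$n_segments, x$config$segment_length_px,
    x$pixel_size_um))
  cat(sprintf("  length %.2f um, theta range [%.3f, %.3f] rad\n",
              x$n_segments * x$config$segment_length_px * x$pixel_size_um,
              min(x$theta), max(x$theta)))
  if (any(x$truncated))
    cat(sprintf("  %d frame(s) truncated at the image border\n",
                sum(x$truncated)))
  invisible(x)
}

#' @export
coef.cilium_trace <- function(object, ...) object$theta

#' Cost-series diagnostics
#'
#' Summarizes the per-frame total tracing cost: mean, bands at two
#' population standard deviations above/below the mean, and the frames
#' whose total cost exceeds the upper band (candidate tracking failures
#' for manual review).
#'
#' @param costs a `cilium_trace` or its `costs` data.frame.
#' @return list with `mean`, `sd`, `upper`, `lower`, `outlier_frames`
#'   (0-based frame indices).
#' @export
cost_diagnostics <- function(costs) {
  if (inherits(costs, "cilium_trace")) costs <- costs$costs
  if (nrow(costs) < 2) stop("need at least 2 frames of costs")
  tot <- costs$total
  m <- mean(tot)
  s <- sd_pop(tot)
  list(mean = m, sd = s, upper = m + 2 * s, lower = m - 2 * s,
       outlier_frames = costs$frame[tot > m + 2 * s])
}
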