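# Waveform metrics computed from the raw tangent-angle field.
#
# All metrics restrict to the middle 80 percent of the cilium length,
# excluding the clamped base and the noisy tip, mirroring how beat
# amplitude is defined for islet cilia.

# Segment indices whose arc-length midpoint falls inside the middle
# fraction of the cilium length (boundaries inclusive).
.middle_segments <- function(N, middle_fraction = 0.8) {
  mid <- (seq_len(N) - 0.5) / N          # midpoints in units of L
  lo <- (1 - middle_fraction) / 2
  hi <- 1 - lo
  which(mid >= lo - 1e-12 & mid <= hi + 1e-12)
}

#' Beat amplitude: SD of the tangent angle over the middle of the cilium
#'
#' Pools theta over all analyzed frames and all segments whose midpoint
#' lies within the middle `middle_fraction` of the cilium length
#' (excluding base and tip), and returns the population standard
#' deviation. Angles are unwrapped about their circular mean first, so
#' cilia oriented near the +/- pi branch cut are handled correctly, and
#' the result is invariant under a global rotation of the coordinate
#' frame. For a pure sinusoidal sweep of angular amplitude A sampled
#' over whole periods this equals A / sqrt(2).
#'
#' @param trace a `cilium_trace`.
#' @param middle_fraction fraction of the length retained (default 0.8,
#'   i.e. arc lengths in [0.1 L, 0.9 L]).
#' @param pooling `"pooled"` (default; one SD over the segments x
#'   frames set), `"per_segment_temporal"` (temporal SD per segment,
#'   then averaged) or `"per_frame_spatial"` (spatial SD per frame,
#'   then averaged).
#' @return amplitude in radians.
#' @export
compute_amplitude <- function(trace, middle_fraction = 0.8,
                              pooling = c("pooled", "per_segment_temporal",
                                          "per_frame_spatial")) {
  pooling <- match.arg(pooling)
  th <- trace$theta
  idx <- .middle_segments(ncol(th), middle_fraction)
  if (length(idx) == 0) stop("no segments in the middle region; N too small")
  th <- th[, idx, drop = FALSE]
  if (length(th) < 2) stop("fewer than 2 pooled angle values")
  dev <- function(v) wrap_angle(v - circ_mean(v))
  switch(pooling,
         pooled = sd_pop(dev(as.vector(th))),
         per_segment_temporal = mean(apply(th, 2, function(v)
           sd_pop(dev(v)))),
         per_frame_spatial = mean(apply(th, 1, function(v)
           sd_pop(dev(v)))))
}

#' Beat period, periodicity and frequency from the mean-angle series
#'
#' Forms phi(t), the mean tangent angle over the middle-80-percent
#' segments, removes its mean, and computes the normalized
#' autocorrelation. The period is the lag (in seconds) of the first
#' local autocorrelation maximum at lag >= `min_lag_frames` whose value
#' exceeds `reliability_threshold`; periodicity is the autocorrelation
#' value at that lag clipped to [0, 1] — a bounded score of beat
#' regularity. If no local maximum exceeds the threshold the period is
#' reported as NA with the `period_unreliable` flag set.
#'
#' @param trace a `cilium_trace` (or a numeric phi series).
#' @param frame_interval_s frame interval; taken from the trace when
#'   omitted.
#' @param middle_fraction see [compute_amplitude()].
#' @param min_lag_frames smallest admissible period in frames.
#' @param reliability_threshold minimum autocorrelation peak height.
#' @return list with `period_s`, `periodicity`, `frequency_hz`,
#'   `period_unreliable`.
#' @export
estimate_period <- function(trace, frame_interval_s = NULL,
                            middle_fraction = 0.8, min_lag_frames = 2L,
                            reliability_threshold = 0.2) {
  if (inherits(trace, "cilium_trace")) {
    if (is.null(frame_interval_s)) frame_interval_s <- trace$frame_interval_s
    idx <- .middle_segments(ncol(trace$theta), middle_fraction)
    phi <- rowMeans(trace$theta[, idx, drop = FALSE])
  } else {
    phi <- as.numeric(trace)
    if (is.null(frame_interval_s))
      stop("`frame_interval_s` required for a plain series")
  }
  T <- length(phi)
  if (T < 20) stop("period estimation needs at least 20 frames")
  unreliable <- list(period_s = NA_real_, periodicity = NA_real_,
                     frequency_hz = NA_real_, period_unreliable = TRUE)
  if (sd_pop(phi) == 0) return(unreliable)
  lag_max <- T - 2L
  r <- as.vector(stats::acf(phi, lag.max = lag_max, plot = FALSE,
                            demean = TRUE)$acf)   # r[1] = lag 0
  lags <- seq_along(r) - 1L
  n <- length(r)
  is_max <- logical(n)
  if (n >= 3) {
    interior <- 2:(n - 1)
    is_max[interior] <- r[interior] > r[interior - 1] &
      r[interior] >= r[interior + 1]
  }
  cand <- which(is_max & lags >= min_lag_frames)
  if (length(cand) == 0) return(unreliable)
  good <- cand[r[cand] > reliability_threshold]
  if (length(good) == 0) {
    out <- unreliable
    out$periodicity <- max(0, min(1, max(r[cand])))
    return(out)
  }
  k <- good[1]
  period <- lags[k] * frame_interval_s
  list(period_s = period,
       periodicity = max(0, min(1, r[k])),
       frequency_hz = 1 / period,
       period_unreliable = FALSE)
}

#' Traced cilium length in micrometres
#'
#' The traced length is fixed by the seed: N segments of
#' `segment_length_px` pixels.
#'
#' @param trace a `cilium_trace`.
#' @param pixel_size_um pixel size; taken from the trace when omitted.
#' @return length in micrometres.
#' @export
compute_length_um <- function(trace, pixel_size_um = NULL) {
  if (is.null(pixel_size_um)) pixel_size_um <- trace$pixel_size_um
  trace$n_segments * trace$config$segment_length_px * pixel_size_um
}

#' Maximal curvature of the traced cilium
#'
#' Discrete curvature at each interior joint is the wrapped angle
#' difference between adjacent segments divided by the segment length
#' in micrometres; the maximum is taken over all joints in the
#' middle-80-percent region and all frames.
#'
#' @param trace a `cilium_trace` with at least 2 segments.
#' @param middle_fraction fraction of the length retained.
#' @param pixel_size_um pixel size; taken from the trace when omitted.
#' @return maximal curvature in 1/um.
#' @export
compute_max_curvature <- function(trace, middle_fraction = 0.8,
                                  pixel_size_um = NULL) {
  if (is.null(pixel_size_um)) pixel_size_um <- trace$pixel_size_um
  th <- trace$theta
  N <- ncol(th)
  if (N < 2) stop("curvature needs at least 2 segments")
  ds_um <- trace$config$segment_length_px * pixel_size_um
  joints <- seq_len(N - 1)                 # joint j between segments j, j+1
  pos <- joints / N                        # joint arc position in units of L
  lo <- (1 - middle_fraction) / 2
  keep <- joints[pos >= lo - 1e-12 & pos <= 1 - lo + 1e-12]
  if (length(keep) == 0) keep <- joints
  dth <- abs(wrap_angle(th[, keep + 1, drop = FALSE] -
                          th[, keep, drop = FALSE]))
  max(dth) / ds_um
}

#' Waveform metrics for one traced cilium
#'
#' Assembles the quantities of interest from the raw angle data: beat
#' amplitude, period, frequency, periodicity, cilium length and maximal
#' curvature.
#'
#' @param object a `cilium_trace`.
#' @param middle_fraction fraction of the cilium length used by the
#'   angle-based metrics.
#' @param ... unused.
#' @return an object of class `waveform_metrics`: list with
#'   `amplitude_rad`, `period_s`, `frequency_hz`, `periodicity`,
#'   `length_um`, `max_curvature_per_um`, `n_frames_used`, `flags`
#'   (character vector, e.g. "period_unreliable", "truncated_frames").
#' @export
summary.cilium_trace <- function(object, middle_fraction = 0.8, ...) {
  flags <- character()
  per <- tryCatch(estimate_period(object, middle_fraction = middle_fraction),
                  error = function(e) list(period_s = NA_real_,
                                           periodicity = NA_real_,
                                           frequency_hz = NA_real_,
                                           period_unreliable = TRUE))
  if (isTRUE(per$period_unreliable)) flags <- c(flags, "period_unreliable")
  if (any(object$truncated)) flags <- c(flags, "truncated_frames")
  structure(list(amplitude_rad = compute_amplitude(object, middle_fraction),
                 period_s = per$period_s,
                 frequency_hz = per$frequency_hz,
                 periodicity = per$periodicity,
                 length_um = compute_length_um(object),
                 max_curvature_per_um =
                   compute_max_curvature(object, middle_fraction),
                 n_frames_used = nrow(object$theta),
                 flags = flags),
            class = "waveform_metrics")
}

#' @export
print.waveform_metrics <- function(x, ...) {
  cat("Waveform metrics (one cilium)\n")
  cat(sprintf("  amplitude     : %.4f rad\n", x$amplitude_rad))
  if (is.na(x$period_s)) {
    cat("  period        : not detected (unreliable)\n")
  } else {
    cat(sprintf("  period        : %.2f s  (frequency %.4f Hz)\n",
                x$period_s, x$frequency_hz))
    cat(sprintf("  periodicity   : %.3f\n", x$periodicity))
  }
  cat(sprintf("  length        : %.2f um\n", x$length_um))
  cat(sprintf("  max curvature : %.4f 1/um\n", x$max_curvature_per_um))
  cat(sprintf("  frames used   : %d\n", x$n_frames_used))
  if (length(x$flags))
    cat("  flags         :", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
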