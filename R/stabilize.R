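# FFT phase-correlation drift estimation and correction.
#
# Whole-islet translation during live imaging (treatments, osmotic
# pressure) is not modelled by the tracer, so it must be removed first.
# Registration is between consecutive frames (robust when the scene
# deforms slowly while drift is smooth), with shifts accumulated
# relative to frame 0. Only translation is estimated; rotation and
# scaling are left alone.

#' Per-frame drift track
#'
#' @param shifts numeric T x 2 matrix of (dx, dy) shifts in pixels
#'   relative to the reference frame.
#' @param reference_index 0-based index of the anchor frame.
#' @return an object of class `drift_track`.
#' @export
drift_track <- function(shifts, reference_index = 0L) {
  shifts <- as.matrix(shifts)
  if (ncol(shifts) != 2 || !all(is.finite(shifts)))
    stop("`shifts` must be a finite T x 2 matrix")
  if (reference_index < 0 || reference_index >= nrow(shifts))
    stop("reference index out of range")
  if (any(abs(shifts[reference_index + 1, ]) > 1e-12))
    stop("shift at the reference frame must be (0, 0)")
  colnames(shifts) <- c("dx", "dy")
  structure(list(shifts = shifts,
                 reference_index = as.integer(reference_index)),
            class = "drift_track")
}

#' @export
print.drift_track <- function(x, ...) {
  cat(sprintf("<drift_track> %d frames, reference frame %d\n",
              nrow(x$shifts), x$reference_index))
  cat(sprintf("  max |dx| = %.3f px, max |dy| = %.3f px\n",
              max(abs(x$shifts[, 1])), max(abs(x$shifts[, 2]))))
  invisible(x)
}

#' @export
as.data.frame.drift_track <- function(x, ...) {
  data.frame(frame = seq_len(nrow(x$shifts)) - 1L,
             dx_px = x$shifts[, 1], dy_px = x$shifts[, 2])
}

# 2-D Hann window, outer product of 1-D raised cosines.
.hann2 <- function(h, w) {
  wy <- 0.5 - 0.5 * cos(2 * pi * (0:(h - 1)) / (h - 1))
  wx <- 0.5 - 0.5 * cos(2 * pi * (0:(w - 1)) / (w - 1))
  outer(wy, wx)
}

# FFT correlation between two frames; returns the shift (dx, dy) that
# maps `a` onto `b`, i.e. b(x) ~= a(x - d). Both frames are
# mean-subtracted, optionally Hann-windowed, and low-pass filtered at
# scale `blur_sigma_px` in the Fourier domain so that registration is
# driven by the large-scale tissue rather than by fine structure (the
# thin beating cilium itself, or pixel noise). `normalization`
# "magnitude" keeps the cross-power magnitude (a matched filter, the
# right weighting for smooth low-contrast scenes); "phase" fully
# whitens the spectrum (classic phase correlation, best for rich rigid
# texture). Subpixel refinement evaluates the inverse transform on a
# 1/upsample grid within +/- 1 px of the integer peak (matrix-multiply
# DFT, no iterative fitting).
.fft_register <- function(a, b, upsample = 1L, window = TRUE,
                          blur_sigma_px = 0,
                          normalization = c("magnitude", "phase")) {
  normalization <- match.arg(normalization)
  h <- nrow(a); w <- ncol(a)
  if (window) {
    win <- .hann2(h, w)
    a <- (a - mean(a)) * win
    b <- (b - mean(b)) * win
  }
  R <- stats::fft(a) * Conj(stats::fft(b))
  if (blur_sigma_px > 0) {
    fy <- fft_freq_index(h) / h
    fx <- fft_freq_index(w) / w
    G <- exp(-4 * pi^2 * blur_sigma_px^2 *
               outer(fy^2, rep(1, w)) -
             4 * pi^2 * blur_sigma_px^2 *
               outer(rep(1, h), fx^2))   # = gaussian blur of both frames
    R <- R * G
  }
  if (normalization == "phase")
    R <- R / pmax(Mod(R), .Machine$double.eps)
  r <- Re(stats::fft(R, inverse = TRUE)) / (h * w)
  peak <- which.max(r)
  py <- (peak - 1) %% h
  px <- (peak - 1) %/% h
  # wrap to signed displacement; the correlation peaks at -d
  if (py > h / 2) py <- py - h
  if (px > w / 2) px <- px - w
  dx <- -px
  dy <- -py
  if (upsample > 1) {
    ky <- fft_freq_index(h)
    kx <- fft_freq_index(w)
    gy <- -dy + seq(-1, 1, by = 1 / upsample)
    gx <- -dx + seq(-1, 1, by = 1 / upsample)
    # r(u) = sum_k R[k] exp(+i 2 pi k u / n), evaluated on the fine grid
    Ey <- exp(2i * pi * outer(gy, ky) / h)     # |gy| x h
    Ex <- exp(2i * pi * outer(kx, gx) / w)     # w x |gx|
    rr <- Re(Ey %*% R %*% Ex)
    pk <- which(rr == max(rr), arr.ind = TRUE)[1, ]
    dy <- -gy[pk[1]]
    dx <- -gx[pk[2]]
  }
  c(dx, dy)
}

# Pixelwise temporal median of a stack (background template; a beating
# cilium smears out, stationary tissue stays).
.temporal_median <- function(frames) {
  d <- dim(frames)
  matrix(apply(matrix(frames, d[1] * d[2], d[3]), 1, stats::median),
         d[1], d[2])
}

# Stationarity weight for template registration: pixels whose temporal
# variance around the median template is large (the beating cilium, or
# anything else that moves on its own) are downweighted so that only
# stationary tissue drives the fit.
.stationarity_weight <- function(frames, template) {
  d <- dim(frames)
  vmap <- matrix(rowMeans((matrix(frames, d[1] * d[2], d[3]) -
                             as.vector(template))^2), d[1], d[2])
  v0 <- stats::median(vmap)
  if (!is.finite(v0) || v0 <= 0) return(matrix(1, d[1], d[2]))
  v0 / (v0 + vmap)
}

#' Estimate whole-field drift by FFT registration
#'
#' Two passes. First, translation between consecutive frames is found
#' from the peak of the inverse transform of the cross-power spectrum
#' of low-pass-filtered frames, refined to 1/`upsample` pixel by a
#' locally upsampled correlation, and accumulated relative to frame 0.
#' Second (`refine_iters` times), the coarsely corrected stack is
#' collapsed to its pixelwise temporal median — a template in which
#' stationary tissue stays sharp while the beating cilium averages out
#' — and every frame is re-registered against that template with
#' pixels downweighted by their temporal variance, so that only
#' stationary structure drives the fit. This removes the error
#' accumulation of the consecutive pass and the bias a bright moving
#' cilium would otherwise exert. A Hann window (on by default)
#' suppresses wrap-around edge artifacts in the consecutive pass; the
#' template pass runs unwindowed because any static taper, window or
#' mask alike, biases residual shifts toward zero, and the variance
#' mask already suppresses the problematic content. Only translation
#' is estimated.
#'
#' @param stack a [cilium_stack()] with at least 2 frames.
#' @param upsample integer >= 1; subpixel precision is 1/upsample px.
#' @param window apply a raised-cosine (Hann) window before the FFT.
#' @param blur_sigma_px Gaussian low-pass scale (px) applied in the
#'   Fourier domain; 4 px keeps registration anchored to tissue-scale
#'   structure. Set 0 to disable.
#' @param refine_iters number of median-template refinement passes
#'   (0 = consecutive-only).
#' @param template_blur_px Gaussian low-pass scale for the template
#'   pass.
#' @param normalization `"magnitude"` (matched-filter weighting,
#'   default) or `"phase"` (fully whitened cross-power spectrum).
#' @return a [drift_track()] with `shifts[t, ]` the cumulative (dx, dy)
#'   of frame t relative to frame 0.
#' @export
estimate_drift <- function(stack, upsample = 10L, window = TRUE,
                           blur_sigma_px = 4, refine_iters = 3L,
                           template_blur_px = 6,
                           normalization = c("magnitude", "phase")) {
  normalization <- match.arg(normalization)
  T <- n_frames(stack)
  if (T < 2) stop("need at least 2 frames to estimate drift")
  if (upsample < 1) stop("`upsample` must be >= 1")
  shifts <- matrix(0, T, 2)
  step <- c(0, 0)
  constant <- vapply(seq_len(T), function(t)
    stats::sd(stack$frames[, , t]) == 0, logical(1))
  for (t in 2:T) {
    if (constant[t - 1] || constant[t]) {
      warning("constant frame at index ", t - 1,
              "; carrying previous drift step")
    } else {
      step <- .fft_register(stack$frames[, , t - 1], stack$frames[, , t],
                            upsample = upsample, window = window,
                            blur_sigma_px = blur_sigma_px,
                            normalization = normalization)
    }
    shifts[t, ] <- shifts[t - 1, ] + step
  }
  if (refine_iters > 0 && !any(constant)) {
    for (it in seq_len(refine_iters)) {
      corrected <- apply_correction(stack, shifts)
      template <- .temporal_median(corrected$frames)
      wmask <- .stationarity_weight(corrected$frames, template)
      for (t in seq_len(T))
        shifts[t, ] <- shifts[t, ] +
          .fft_register(template * wmask,
                        corrected$frames[, , t] * wmask,
                        upsample = upsample, window = FALSE,
                        blur_sigma_px = template_blur_px,
                        normalization = normalization)
      shifts <- sweep(shifts, 2, shifts[1, ])
    }
  }
  drift_track(shifts, reference_index = 0L)
}

#' Remove estimated drift from a stack
#'
#' Frame t is translated by `-shifts[t, ]` with bilinear interpolation;
#' pixels pulled in from outside the frame are filled with the frame
#' median (a background estimate).
#'
#' @param stack a [cilium_stack()].
#' @param drift a [drift_track()] (or T x 2 matrix) of the same length.
#' @return the corrected [cilium_stack()].
#' @export
apply_correction <- function(stack, drift) {
  shifts <- if (inherits(drift, "drift_track")) drift$shifts
            else as.matrix(drift)
  T <- n_frames(stack)
  if (nrow(shifts) != T)
    stop("drift length (", nrow(shifts), ") does not match stack (", T, ")")
  out <- stack$frames
  for (t in seq_len(T))
    out[, , t] <- translate_frame(stack$frames[, , t],
                                  -shifts[t, 1], -shifts[t, 2],
                                  boundary = "fill")
  cilium_stack(out, stack$pixel_size_um, stack$frame_interval_s)
}
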