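# Internal geometry / interpolation helpers shared across modules.
#
# Pixel coordinate convention (used everywhere): pixel (0, 0) is the
# top-left pixel centre, x increases along columns, y along rows, so the
# intensity at integer coordinates (x, y) is frame[y + 1, x + 1].

#' Wrap angles to (-pi, pi]
#'
#' @param a numeric vector of angles in radians.
#' @return angles wrapped to the principal branch.
#' @keywords internal
#' @noRd
wrap_angle <- function(a) atan2(sin(a), cos(a))

#' Circular mean of a set of angles
#' @noRd
circ_mean <- function(a) atan2(mean(sin(a)), mean(cos(a)))

#' Population standard deviation
#' @noRd
sd_pop <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

#' Bilinear interpolation of a single frame at continuous pixel coordinates
#'
#' Coordinates are 0-based (see convention above). Points outside the
#' image support return NA; the caller decides the boundary policy.
#'
#' @param frame numeric H x W matrix.
#' @param x,y numeric vectors of equal length.
#' @return numeric vector of interpolated intensities (NA outside).
#' @keywords internal
#' @noRd
interp_bilinear <- function(frame, x, y) {
  h <- nrow(frame)
  w <- ncol(frame)
  out <- rep(NA_real_, length(x))
  ok <- x >= 0 & x <= w - 1 & y >= 0 & y <= h - 1 & is.finite(x) & is.finite(y)
  if (!any(ok)) return(out)
  xs <- x[ok]
  ys <- y[ok]
  x0 <- pmin(floor(xs), w - 2)
  y0 <- pmin(floor(ys), h - 2)
  x0 <- pmax(x0, 0)
  y0 <- pmax(y0, 0)
  fx <- xs - x0
  fy <- ys - y0
  i00 <- y0 + 1 + x0 * h
  v00 <- frame[i00]
  v10 <- frame[i00 + h]       # (x0+1, y0)
  v01 <- frame[i00 + 1]       # (x0,   y0+1)
  v11 <- frame[i00 + h + 1]
  out[ok] <- (1 - fx) * (1 - fy) * v00 + fx * (1 - fy) * v10 +
    (1 - fx) * fy * v01 + fx * fy * v11
  out
}

#' Translate one frame by (dx, dy) pixels
#'
#' Content moves by +dx to the right and +dy downward. `boundary`
#' selects periodic wrap-around or constant fill; `fill = NULL` uses the
#' frame median.
#' @keywords internal
#' @noRd
translate_frame <- function(frame, dx, dy, boundary = c("fill", "wrap"),
                            fill = NULL) {
  boundary <- match.arg(boundary)
  h <- nrow(frame)
  w <- ncol(frame)
  if (dx == 0 && dy == 0) return(frame)
  xs <- rep(0:(w - 1), each = h) - dx
  ys <- rep(0:(h - 1), times = w) - dy
  if (boundary == "wrap") {
    xs <- xs %% w
    ys <- ys %% h
    # bilinear with periodic neighbours
    x0 <- floor(xs); y0 <- floor(ys)
    fx <- xs - x0;   fy <- ys - y0
    x1 <- (x0 + 1) %% w
    y1 <- (y0 + 1) %% h
    x0 <- x0 %% w
    y0 <- y0 %% h
    v00 <- frame[y0 + 1 + x0 * h]
    v10 <- frame[y0 + 1 + x1 * h]
    v01 <- frame[y1 + 1 + x0 * h]
    v11 <- frame[y1 + 1 + x1 * h]
    out <- (1 - fx) * (1 - fy) * v00 + fx * (1 - fy) * v10 +
      (1 - fx) * fy * v01 + fx * fy * v11
  } else {
    if (is.null(fill)) fill <- stats::median(frame)
    out <- interp_bilinear(frame, xs, ys)
    out[is.na(out)] <- fill
  }
  matrix(out, nrow = h, ncol = w)
}

#' Signed FFT frequency indices, numpy fftfreq style
#' @noRd
fft_freq_index <- function(n) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  k
}

#' Evaluate an expression with a temporary RNG seed, restoring state
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
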