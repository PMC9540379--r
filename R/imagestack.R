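# Calibrated time-lapse image stacks: construction, TIFF I/O, frame
# selection.

#' Construct a calibrated image stack
#'
#' A `cilium_stack` holds a single-channel time-lapse movie as an
#' H x W x T numeric array together with its physical calibration. Pixel
#' (0, 0) is the top-left pixel, x runs along columns and y along rows.
#' Pixels are assumed square (isotropic `pixel_size_um`); all downstream
#' geometry relies on this.
#'
#' @param frames numeric array. Either H x W (a single frame) or
#'   H x W x T. All intensities must be finite and non-negative.
#' @param pixel_size_um pixel size in micrometres per pixel (scalar > 0).
#' @param frame_interval_s time between consecutive frames in seconds
#'   (scalar > 0).
#' @return an object of class `cilium_stack` with elements `frames`,
#'   `pixel_size_um` and `frame_interval_s`.
#' @examples
#' st <- cilium_stack(array(0, c(32, 32, 4)), pixel_size_um = 0.35,
#'                    frame_interval_s = 2)
#' n_frames(st)
#' @export
cilium_stack <- function(frames, pixel_size_um, frame_interval_s) {
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("`frames` must be an H x W or H x W x T numeric array")
  if (!all(is.finite(frames)))
    stop("stack intensities must be finite")
  if (any(frames < 0))
    stop("stack intensities must be non-negative")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      pixel_size_um <= 0)
    stop("`pixel_size_um` must be a positive scalar")
  if (!is.numeric(frame_interval_s) || length(frame_interval_s) != 1L ||
      frame_interval_s <= 0)
    stop("`frame_interval_s` must be a positive scalar")
  structure(list(frames = frames,
                 pixel_size_um = as.numeric(pixel_size_um),
                 frame_interval_s = as.numeric(frame_interval_s)),
            class = "cilium_stack")
}

#' @export
print.cilium_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<cilium_stack> %d frame(s), %d x %d px, %.4g um/px, %.4g s/frame\n",
    d[3], d[1], d[2], x$pixel_size_um, x$frame_interval_s))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$frames), max(x$frames)))
  invisible(x)
}

#' Number of frames in a stack
#' @param stack a `cilium_stack`.
#' @return integer frame count.
#' @export
n_frames <- function(stack) dim(stack$frames)[3]

#' Extract one frame as a matrix
#' @param stack a `cilium_stack`.
#' @param t 0-based frame index.
#' @return numeric H x W matrix.
#' @export
get_frame <- function(stack, t) {
  T <- n_frames(stack)
  if (t < 0 || t >= T) stop("frame index out of range")
  stack$frames[, , t + 1L]
}

.sidecar_path <- function(path) paste0(path, ".json")

# Calibration keys embedded free-form in a TIFF description tag, e.g. by
# ImageJ macros or tifffile: "pixel_size_um=0.35\nframe_interval_s=2".
.parse_calibration_description <- function(desc) {
  out <- list()
  if (is.null(desc) || !nzchar(desc)) return(out)
  for (line in strsplit(desc, "\n", fixed = TRUE)[[1]]) {
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) == 2 &&
        kv[1] %in% c("pixel_size_um", "frame_interval_s", "value_scale")) {
      v <- suppressWarnings(as.numeric(kv[2]))
      if (is.finite(v)) out[[kv[1]]] <- v
    }
  }
  out
}

#' Read a time-lapse stack from a multi-page grayscale TIFF
#'
#' Pages are interpreted as time points. Calibration is looked up, in
#' order of precedence: explicit arguments, the JSON sidecar written by
#' [write_stack()] (`<path>.json`), then `pixel_size_um` /
#' `frame_interval_s` keys embedded in the TIFF description tag (the
#' convention used by e.g. ImageJ macros). Explicit arguments override
#' file metadata with a warning when the two disagree, since acquisition
#' metadata is frequently wrong or absent.
#'
#' @param path path to a single-channel multi-page TIFF.
#' @param pixel_size_um,frame_interval_s calibration overrides; required
#'   when the file carries no metadata.
#' @return a [cilium_stack()].
#' @export
read_stack <- function(path, pixel_size_um = NULL, frame_interval_s = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- .parse_calibration_description(attr(pages[[1]], "description"))
  sc <- .sidecar_path(path)
  if (file.exists(sc)) {
    side <- jsonlite::read_json(sc, simplifyVector = TRUE)
    for (k in c("pixel_size_um", "frame_interval_s", "value_scale"))
      if (!is.null(side[[k]])) meta[[k]] <- as.numeric(side[[k]])
  }
  for (key in c("pixel_size_um", "frame_interval_s")) {
    arg <- get(key)
    if (!is.null(arg) && !is.null(meta[[key]]) &&
        abs(arg - meta[[key]]) > 1e-9 * max(abs(arg), 1)) {
      warning(sprintf(
        "file metadata has %s=%.6g but argument says %.6g; using the argument",
        key, meta[[key]], arg))
    }
  }
  if (is.null(pixel_size_um)) pixel_size_um <- meta$pixel_size_um
  if (is.null(frame_interval_s)) frame_interval_s <- meta$frame_interval_s
  if (is.null(pixel_size_um) || is.null(frame_interval_s))
    stop("calibration (pixel_size_um, frame_interval_s) not found in file ",
         "metadata; pass it explicitly")
  for (p in pages) {
    if (length(dim(p)) > 2)
      stop("multi-channel/RGB TIFF page found; expected single-channel ",
           "grayscale pages with the first dimension of the file = time")
  }
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("TIFF pages differ in size")
  frames <- array(unlist(pages, use.names = FALSE),
                  c(dims[1, 1], dims[2, 1], length(pages)))
  # readTIFF maps sample values to [0,1]; undo the mapping. 8/16-bit
  # pages are integer counts; 32-bit pages are floats scaled by the
  # value_scale recorded at write time (1 if absent).
  bps <- attr(pages[[1]], "bits.per.sample")
  if (is.null(bps)) bps <- 16L
  if (bps <= 16) {
    frames <- round(frames * (2^bps - 1))
  } else {
    scale <- if (is.null(meta$value_scale)) 1 else meta$value_scale
    frames <- frames * scale
  }
  cilium_stack(frames, pixel_size_um, frame_interval_s)
}

#' Write a stack to a multi-page grayscale TIFF
#'
#' Integer-valued stacks with range below 2^16 are written as 16-bit
#' (8-bit if the range allows) so that [read_stack()] inverts the write
#' bit-exactly; other stacks are written as 32-bit float, rescaled by
#' their maximum (recorded as `value_scale`). Calibration keys
#' `pixel_size_um` and `frame_interval_s` are written to a plain-text
#' JSON sidecar `<path>.json` that [read_stack()] picks up.
#'
#' @param stack a [cilium_stack()].
#' @param path output file path; the directory must exist.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  if (!dir.exists(dirname(path)))
    stop("directory does not exist: ", dirname(path))
  fr <- stack$frames
  T <- dim(fr)[3]
  value_scale <- 1
  integral <- max(abs(fr - round(fr))) == 0 && max(fr) < 2^16
  if (integral) {
    bits <- if (max(fr) < 2^8) 8L else 16L
    scale <- 2^bits - 1
    pages <- lapply(seq_len(T), function(t) fr[, , t] / scale)
  } else {
    bits <- 32L
    value_scale <- max(fr, 1e-12)
    pages <- lapply(seq_len(T), function(t) fr[, , t] / value_scale)
  }
  tiff::writeTIFF(pages, path, bits.per.sample = bits,
                  compression = "none", reduce = FALSE)
  jsonlite::write_json(
    list(pixel_size_um = stack$pixel_size_um,
         frame_interval_s = stack$frame_interval_s,
         value_scale = value_scale),
    .sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Select a contiguous range of frames
#'
#' Frame ranges are half-open and 0-based: `frames = c(start, end)`
#' keeps frames `start, ..., end - 1`. This makes composition and
#' empty-range detection unambiguous, and lets one movie be split into
#' treatment windows (e.g. before/after a glucose step) without two
#' separate acquisitions.
#'
#' @param stack a [cilium_stack()].
#' @param frames integer vector `c(start, end)`, `0 <= start < end <= T`.
#' @return a [cilium_stack()] with `end - start` frames and unchanged
#'   calibration.
#' @export
select_frames <- function(stack, frames) {
  T <- n_frames(stack)
  if (length(frames) != 2L || anyNA(frames))
    stop("`frames` must be c(start, end)")
  start <- frames[1]; end <- frames[2]
  if (start != round(start) || end != round(end))
    stop("frame indices must be integers")
  if (start < 0 || end > T || start >= end)
    stop(sprintf("invalid frame range [%d, %d) for a %d-frame stack",
                 start, end, T))
  cilium_stack(stack$frames[, , (start + 1):end, drop = FALSE],
               stack$pixel_size_um, stack$frame_interval_s)
}
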