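# Diagnostic visualizations: temporal waveform heatmap and cost series.

#' Temporal waveform heatmap
#'
#' Overlays every frame's traced centreline in one panel, colored by
#' frame index along a continuous colormap with a time colorbar — the
#' standard at-a-glance picture of a cilium's sweep envelope.
#'
#' @param trace a `cilium_trace`.
#' @param out optional PNG output path; when NULL, draws on the current
#'   device.
#' @param palette colormap name passed to [grDevices::hcl.colors()].
#' @return `out` (invisibly) when writing a file.
#' @export
plot_waveform_heatmap <- function(trace, out = NULL, palette = "viridis") {
  stopifnot(inherits(trace, "cilium_trace"))
  T <- nrow(trace$theta)
  if (T < 1) stop("empty trace")
  cols <- grDevices::hcl.colors(max(T, 2), palette)
  if (!is.null(out))
    grDevices::png(out, width = 900, height = 750, res = 120)
  op <- graphics::par(no.readonly = TRUE)
  on.exit({
    graphics::par(op)
    if (!is.null(out)) grDevices::dev.off()
  })
  graphics::layout(matrix(1:2, 1, 2), widths = c(5, 1))
  xs <- trace$nodes[, 1, , drop = FALSE]
  ys <- trace$nodes[, 2, , drop = FALSE]
  graphics::par(mar = c(4, 4, 2, 1))
  graphics::plot(NA, xlim = range(xs), ylim = rev(range(ys)), asp = 1,
                 xlab = "x (px)", ylab = "y (px)",
                 main = "Waveform heatmap")
  for (t in seq_len(T))
    graphics::lines(trace$nodes[, 1, t], trace$nodes[, 2, t],
                    col = cols[min(t, length(cols))], lwd = 2)
  graphics::points(trace$nodes[1, 1, 1], trace$nodes[1, 2, 1], pch = 16)
  # time colorbar
  graphics::par(mar = c(4, 1, 2, 3))
  times <- (trace$frames - trace$frames[1]) * trace$frame_interval_s
  graphics::image(z = matrix(seq_len(max(T, 2)), 1), col = cols,
                  axes = FALSE, xlab = "", ylab = "")
  graphics::axis(4, at = c(0, 1),
                 labels = sprintf("%.0f s", range(times)))
  graphics::mtext("time", side = 4, line = 1.8, cex = 0.8)
  invisible(out)
}

#' @export
plot.cilium_trace <- function(x, type = c("waveform", "costs"), ...) {
  type <- match.arg(type)
  if (type == "waveform") plot_waveform_heatmap(x, ...)
  else plot_cost_series(x, ...)
}

#' Cost-series diagnostic plot
#'
#' One panel per penalty term plus the total cost versus frame; the
#' total-cost panel shows a dashed mean line and solid bounds at two
#' population standard deviations above (red) and below (green) the
#' mean. Frames above the upper bound are candidate tracking failures.
#'
#' @param costs a `cilium_trace` or its `costs` data.frame (columns
#'   frame, intensity, curvature, tvel, rvel, dcurv, total).
#' @param out optional PNG output path.
#' @return `out` (invisibly) when writing a file.
#' @export
plot_cost_series <- function(costs, out = NULL) {
  if (inherits(costs, "cilium_trace")) costs <- costs$costs
  if (is.null(costs) || nrow(costs) < 2)
    stop("cost plot needs at least 2 frames of costs")
  diag <- cost_diagnostics(costs)
  if (!is.null(out))
    grDevices::png(out, width = 1100, height = 700, res = 120)
  op <- graphics::par(no.readonly = TRUE)
  on.exit({
    graphics::par(op)
    if (!is.null(out)) grDevices::dev.off()
  })
  graphics::par(mfrow = c(2, 3), mar = c(4, 4, 2, 1))
  terms <- c("intensity", "curvature", "tvel", "rvel", "dcurv")
  for (tm in terms)
    graphics::plot(costs$frame, costs[[tm]], type = "l", xlab = "frame",
                   ylab = "cost", main = tm)
  ylim <- range(costs$total, diag$upper, diag$lower)
  graphics::plot(costs$frame, costs$total, type = "l", xlab = "frame",
                 ylab = "cost", main = "total", ylim = ylim)
  graphics::abline(h = diag$mean, lty = 2)
  graphics::abline(h = diag$upper, col = "red")
  graphics::abline(h = diag$lower, col = "darkgreen")
  if (length(diag$outlier_frames))
    graphics::points(diag$outlier_frames,
                     costs$total[costs$frame %in% diag$outlier_frames],
                     col = "red", pch = 4)
  invisible(out)
}
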