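# Config-driven orchestration: simulate (optional) -> stabilize ->
# trace -> metrics -> plots, with every artifact written to disk.

#' Read a tracing seed from JSON
#'
#' Expected layout: `{"base": [x, y], "polyline": [[x, y], ...]}`.
#'
#' @param path JSON file path.
#' @return a [cilium_seed()].
#' @export
read_seed <- function(path) {
  if (!file.exists(path)) stop("seed file not found: ", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(j$base) || is.null(j$polyline))
    stop("seed JSON must have `base` and `polyline`")
  cilium_seed(as.numeric(j$base), matrix(as.numeric(t(j$polyline)),
                                         ncol = 2, byrow = TRUE))
}

#' Write a tracing seed to JSON
#' @param seed a [cilium_seed()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_seed <- function(seed, path) {
  stopifnot(inherits(seed, "cilium_seed"))
  jsonlite::write_json(list(base = seed$base_xy,
                            polyline = unname(apply(seed$polyline, 1,
                                                    c, simplify = FALSE))),
                       path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Write a trace and its costs to CSV
#'
#' The trace CSV has one row per (frame, segment) with columns frame,
#' segment, s_um (arc length at the segment midpoint), x_px, y_px (the
#' segment end node) and theta_rad; the costs CSV has one row per frame.
#'
#' @param trace a `cilium_trace`.
#' @param trace_csv,costs_csv output paths (either may be NULL to skip).
#' @return invisibly, a list of the written paths.
#' @export
write_trace_csv <- function(trace, trace_csv, costs_csv = NULL) {
  stopifnot(inherits(trace, "cilium_trace"))
  out <- list()
  if (!is.null(trace_csv)) {
    T <- nrow(trace$theta); N <- trace$n_segments
    ds_um <- trace$config$segment_length_px * trace$pixel_size_um
    df <- data.frame(
      frame = rep(trace$frames, each = N),
      segment = rep(seq_len(N), times = T),
      s_um = rep((seq_len(N) - 0.5) * ds_um, times = T),
      x_px = as.vector(vapply(seq_len(T), function(t)
        trace$nodes[-1, 1, t], numeric(N))),
      y_px = as.vector(vapply(seq_len(T), function(t)
        trace$nodes[-1, 2, t], numeric(N))),
      theta_rad = as.vector(t(trace$theta)))
    utils::write.csv(df, trace_csv, row.names = FALSE)
    out$trace <- trace_csv
  }
  if (!is.null(costs_csv)) {
    utils::write.csv(trace$costs, costs_csv, row.names = FALSE)
    out$costs <- costs_csv
  }
  invisible(out)
}

#' Write waveform metrics to JSON
#' @param metrics a `waveform_metrics` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(metrics, path) {
  stopifnot(inherits(metrics, "waveform_metrics"))
  jsonlite::write_json(unclass(metrics), path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

# Collect all config violations at once so the user fixes them in one
# pass.
.validate_run_config <- function(cfg) {
  errs <- character()
  need <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  if (is.null(cfg[["simulate"]])) {
    need(!is.null(cfg[["input"]]$stack), "input$stack (TIFF path) is required")
    if (!is.null(cfg[["input"]]$stack))
      need(file.exists(cfg[["input"]]$stack),
           paste0("input stack not found: ", cfg[["input"]]$stack))
    need(!is.null(cfg[["seed_file"]]) || !is.null(cfg[["seed"]]),
         "a seed (seed_file or inline seed block) is required")
    if (!is.null(cfg[["seed_file"]]))
      need(file.exists(cfg[["seed_file"]]),
           paste0("seed file not found: ", cfg[["seed_file"]]))
  }
  if (!is.null(cfg[["input"]]$pixel_size_um))
    need(cfg[["input"]]$pixel_size_um > 0, "pixel_size_um must be > 0")
  if (!is.null(cfg[["input"]]$frame_interval_s))
    need(cfg[["input"]]$frame_interval_s > 0, "frame_interval_s must be > 0")
  if (!is.null(cfg[["frames"]]))
    need(length(cfg[["frames"]]) == 2 && cfg[["frames"]][1] >= 0 &&
           cfg[["frames"]][1] < cfg[["frames"]][2],
         "frames must be c(start, end) with 0 <= start < end")
  need(!is.null(cfg[["output_dir"]]), "output_dir is required")
  errs
}

#' Run the full waveform-analysis pipeline from a config
#'
#' Stages: optional simulation of a synthetic scene, drift
#' stabilization, tracing, waveform metrics, and the two diagnostic
#' plots. All artifacts (stabilized TIFF, drift CSV, trace CSV, costs
#' CSV, metrics JSON, PNG plots, the effective config YAML) are written
#' under `output_dir`; re-running from the written config reproduces
#' them.
#'
#' @param config a list, or path to a YAML file, with blocks:
#'   \describe{
#'     \item{simulate}{optional scene: `model` (fields of
#'       [waveform_model()]), `render` (fields of [render_params()]),
#'       `n_frames`, `geometry`;}
#'     \item{input}{`stack` (TIFF path), `pixel_size_um`,
#'       `frame_interval_s` (overrides);}
#'     \item{seed_file / seed}{seed JSON path, or inline `base` +
#'       `polyline`;}
#'     \item{frames}{`c(start, end)` half-open frame range;}
#'     \item{stabilize}{`enabled` (default TRUE), `upsample`, `window`;}
#'     \item{trace}{overrides for [trace_config()] fields;}
#'     \item{output_dir}{artifact directory (created).}
#'   }
#' @return invisibly, a list with `trace`, `metrics`, `drift` and the
#'   artifact `paths`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  errs <- .validate_run_config(config)
  if (length(errs))
    stop("invalid config:\n", paste("  -", errs, collapse = "\n"))
  dir.create(config[["output_dir"]], showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  msg <- function(...) message("[ciliawave] ", sprintf(...))

  if (!is.null(config[["simulate"]])) {
    sc <- config[["simulate"]]
    model <- do.call(waveform_model, sc$model)
    render <- do.call(render_params, sc$render %||% list())
    geometry <- sc$geometry %||% list(H = 512, W = 512,
                                      pixel_size_um = 0.35,
                                      frame_interval_s = 2)
    sim <- simulate_cilium_movie(model, render, sc$n_frames, geometry)
    stack <- sim$stack
    paths$movie <- file.path(config[["output_dir"]], "movie.tif")
    write_stack(stack, paths$movie)
    msg("simulated movie -> %s", paths$movie)
    paths$truth <- file.path(config[["output_dir"]], "truth.json")
    jsonlite::write_json(
      list(s_um = sim$truth$s_um, theta = sim$truth$theta,
           drift = sim$truth$drift, phase = sim$truth$phase,
           model = unclass(model)),
      paths$truth, digits = NA, auto_unbox = TRUE)
    seed <- seed_from_truth(sim$truth)
  } else {
    stack <- read_stack(config[["input"]]$stack,
                        pixel_size_um = config[["input"]]$pixel_size_um,
                        frame_interval_s = config[["input"]]$frame_interval_s)
    seed <- if (!is.null(config[["seed_file"]])) read_seed(config[["seed_file"]])
            else cilium_seed(as.numeric(config[["seed"]]$base),
                             matrix(as.numeric(t(config[["seed"]]$polyline)),
                                    ncol = 2, byrow = TRUE))
  }
  if (!is.null(config[["frames"]]))
    stack <- select_frames(stack, as.integer(config[["frames"]]))

  stab <- config[["stabilize"]] %||% list()
  if (!identical(stab$enabled, FALSE) && n_frames(stack) >= 2) {
    drift <- estimate_drift(stack, upsample = stab$upsample %||% 10L,
                            window = stab$window %||% TRUE)
    stack <- apply_correction(stack, drift)
    paths$drift <- file.path(config[["output_dir"]], "drift.csv")
    utils::write.csv(as.data.frame(drift), paths$drift, row.names = FALSE)
    paths$stabilized <- file.path(config[["output_dir"]], "stabilized.tif")
    write_stack(stack, paths$stabilized)
    msg("stabilized stack -> %s", paths$stabilized)
  } else {
    drift <- NULL
  }

  tc <- do.call(trace_config, config[["trace"]] %||% list())
  fit <- trace_movie(stack, seed, tc)
  paths$trace <- file.path(config[["output_dir"]], "trace.csv")
  paths$costs <- file.path(config[["output_dir"]], "costs.csv")
  write_trace_csv(fit, paths$trace, paths$costs)
  msg("trace -> %s", paths$trace)

  metrics <- summary(fit)
  paths$metrics <- file.path(config[["output_dir"]], "metrics.json")
  write_metrics_json(metrics, paths$metrics)
  msg("metrics -> %s", paths$metrics)

  paths$waveform_png <- file.path(config[["output_dir"]], "waveform.png")
  plot_waveform_heatmap(fit, paths$waveform_png)
  if (nrow(fit$costs) >= 2) {
    paths$costs_png <- file.path(config[["output_dir"]], "costs.png")
    plot_cost_series(fit, paths$costs_png)
  }
  # the re-runnable config is the user's own (defaults are code, so a
  # re-run resolves them identically); the resolved trace parameters
  # are recorded under an informational key that a re-run ignores
  paths$config <- file.path(config[["output_dir"]], "config.yaml")
  effective <- config
  effective$trace_resolved <- lapply(unclass(tc), function(x)
    if (is.numeric(x)) signif(x, 10) else x)
  yaml::write_yaml(effective, paths$config)
  msg("done; artifacts in %s", config[["output_dir"]])
  invisible(list(trace = fit, metrics = metrics, drift = drift,
                 paths = paths))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
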