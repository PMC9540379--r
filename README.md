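# ciliawave

Quantitative waveform analysis of beating primary cilia in time-lapse
fluorescence microscopy.

Primary cilia on islet cells are solitary, sub-micron-wide,
microtubule-based projections, typically 5–10 µm long. Live-cell
imaging shows they are not static: they sweep slowly and irregularly,
with periods on the order of 20–30 s. `ciliawave` is for microscopists
who have such a movie — one channel, one field of view, ≥ 1 frame per
2 s — and want per-cilium numbers out of it: beat amplitude, period,
frequency, periodicity, length, maximal curvature.

## Method

The cilium in each frame is modeled as a chain of N equal-length
segments anchored at a stationary base (the basal body), described by
the tangent angle θ(s, t) — the angle between the local tangent and
the image x-axis at arc length s from the base. A user seed on the
first frame (base point + clicked polyline toward the tip) fixes N and
the initial angles; each subsequent frame is traced base-to-tip by
exhaustive grid search, scoring each candidate angle θ with

    C(θ) = − w_I · Ī(θ)                            (probe intensity)
           + w_c (θ − θ_prev_segment)²              (curvature)
           + w_v ‖Δ end node‖² / Δt²                (translational velocity)
           + w_r (θ − θ_prev_frame)² / Δt²          (rotational velocity)
           + w_d (Δ curvature)² / Δt²               (curvature rate)

where Ī is the transverse-weighted mean intensity under a rotating
rectangular probe array spanning the segment. The penalties keep the
trace on track through noise, poor contrast and focus drift. Before
tracing, whole-field specimen drift is removed by FFT registration
(low-passed matched-filter correlation between consecutive frames,
refined against a temporal-median template with a stationarity mask;
subpixel via upsampled DFT). Metrics are computed from θ(s, t)
restricted to the middle 80 % of the cilium: amplitude is the pooled
population SD of θ (A/√2 for a sinusoidal sweep of amplitude A),
period/periodicity come from the first autocorrelation peak of the
mean angle, and curvature from wrapped angle differences between
adjacent segments.

A ground-truthed simulator renders beating-cilium movies (traveling
wave θ(s,t) = θ₀ + A sin(2πt/T − ks + φ₀), Gaussian tube profile,
tissue background, random-walk drift, additive noise), so the whole
chain is validated by parameter recovery without any real data.

## Worked example

Simulate a 10-minute recording at the default acquisition envelope
(512×512 px, 0.35 µm/px, 2 s/frame) of an 8 µm cilium pivoting with
amplitude 0.3 rad and period 24 s, under drift and noise — then
recover those numbers blind:

```r
library(ciliawave)

mdl <- waveform_model(base_xy = c(250, 280), base_angle_rad = -0.6,
                      length_um = 8, amplitude_rad = 0.3, period_s = 24)
rp  <- render_params(noise_sigma = 10, drift_sigma_px = 0.5, rng_seed = 42)
sim <- simulate_cilium_movie(mdl, rp, n_frames = 300)

stab <- apply_correction(sim$stack, estimate_drift(sim$stack))
fit  <- trace_movie(stab, seed_from_truth(sim$truth))
summary(fit)
#> Waveform metrics (one cilium)
#>   amplitude     : 0.2159 rad
#>   period        : 24.00 s  (frequency 0.0417 Hz)
#>   periodicity   : 0.958
#>   length        : 7.70 um
#>   max curvature : 0.3366 1/um
#>   frames used   : 300
```

The recovered amplitude matches the sinusoid's angle SD
0.3/√2 ≈ 0.2121 rad within 2 %; the period is exact to the frame
interval; the length (11 segments × 2 px × 0.35 µm/px = 7.70 µm)
reflects the seeded cilium up to the floor-rule quantization of the
segment chain. `plot(fit)` overlays all 300 traced centerlines colored
by time (the waveform heatmap); `plot(fit, type = "costs")` shows the
per-term cost series with mean ± 2 SD bands that flag frames needing
manual review.

For real movies, read the stack with `read_stack("movie.tif",
pixel_size_um =, frame_interval_s =)`, supply your own
`cilium_seed(base, polyline)` clicked on the first analyzed frame, and
optionally restrict to a condition window with `select_frames()` /
the `frames =` argument. `run_pipeline()` drives
simulate → stabilize → trace → metrics → plots from a YAML config, and
`inst/scripts/ciliawave.R` exposes the same stages as shell
subcommands (`simulate`, `stabilize`, `trace`, `metrics`, `plot`,
`run`).

See the vignette (`vignettes/waveform-methods.Rmd`) for the model,
parameter guidance and numerical design choices.

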