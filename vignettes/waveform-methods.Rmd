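---
title: "Tracing and quantifying primary-cilium waveforms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing and quantifying primary-cilium waveforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciliawave)
```

## The problem

Primary cilia on islet cells are solitary, sub-micron-wide projections,
typically 5–10 µm long, that move slowly and irregularly in live-cell
recordings — sweep periods on the order of 20–30 s, far slower than
classic motile cilia. Quantifying that motion from a time-lapse
fluorescence movie means recovering, frame by frame, the centerline of
one chosen cilium and reducing it to a tangent-angle field
$\theta(s,t)$: the angle between the local tangent and the image
x-axis, as a function of arc length $s$ from the base and time $t$.
Everything downstream — beat amplitude, period, periodicity, maximal
curvature — is a statistic of $\theta(s,t)$.

The package implements this as four stages: drift stabilization,
seeded tracing, waveform metrics, and a ground-truthed simulator used
to validate the other three by parameter recovery.

## The tracing model

The cilium in frame $t$ is a chain of $N$ straight segments of equal
length $\Delta s$ (pixels), anchored at a user-identified stationary
base (the basal body). The user supplies a seed on the first analyzed
frame: the base point plus a clicked polyline toward the tip. The
polyline fixes the traced length — $N = \lfloor L/\Delta s\rfloor$,
the tip remainder dropped — and the initial angles. Length is not
re-estimated afterwards; elongation/shrinkage is out of scope.

For each subsequent frame, segment angles are chosen in order from
base to tip by exhaustive search over a candidate grid, and each
candidate angle $\theta$ is scored by a penalized cost:

$$
C_i(\theta) =
  -w_I\,\bar I(\theta)
  + w_c\,(\theta-\theta_{i-1,t})^2
  + \frac{w_v}{\Delta t^2}\,\lVert e_i(\theta)-e_{i,t-1}\rVert^2
  + \frac{w_r}{\Delta t^2}\,(\theta-\theta_{i,t-1})^2
  + \frac{w_d}{\Delta t^2}\,
    \bigl[(\theta-\theta_{i-1,t})-(\theta_{i,t-1}-\theta_{i-1,t-1})\bigr]^2
$$

where $\bar I$ is the transverse-weighted mean of bilinearly
interpolated intensities over a rotating rectangular probe array
spanning $\Delta s$ along the candidate direction and $w$ pixels
across it, $e_i(\theta)$ is the segment end node, and all angle
differences are wrapped to $(-\pi,\pi]$. The four penalties —
curvature, translational velocity, rotational velocity, rate of change
of curvature — keep the trace on track where focus, contrast, noise or
neighboring objects make the local angle ambiguous; with clean images
they contribute almost nothing.

The first segment omits the two within-frame curvature terms: it has
no preceding segment, and anchoring it to the fixed seed angle instead
would penalize genuine sweep, systematically shrinking the amplitude
of a pivoting cilium (we measured a beat-locked ~7° RMS bias that
propagates several segments up the chain).

### Candidate grid and determinism

Candidates lie on a fixed lattice of multiples of $\delta\theta$
(default 0.5°) within $\pm\Theta$ (default 30°) of the previous
frame's angle. Centering the lattice on the previous angle instead
would let quantization drift accumulate: on a static scene the trace
then wanders in a ±2-step limit cycle. On the fixed lattice a static
scene reproduces the identical trace every frame, and the whole
algorithm is deterministic: exact ties break to the candidate nearest
the previous angle, then to the numerically smaller one. $\Theta$
doubles as a hard bound on rotational velocity
($\Theta/\Delta t \approx 15°/s$ at 2 s sampling — several times the
fastest sweep we simulate).

### Parameters that matter

* `segment_length_px` ($\Delta s$, default 2 px ≈ 0.7 µm at
  0.35 µm/px). Larger segments average more pixels and give the probe
  a longer lever arm (better angular SNR), but quantize the seeded
  length more coarsely ($N = \lfloor L/\Delta s\rfloor$) and smooth
  real curvature. At 2 px an 8 µm cilium resolves ~11 segments and the
  length quantization error stays below 5%.
* `probe_width_px` ($w$, default 2 px) with Gaussian transverse
  weighting ($\sigma = w/4$). A diffraction-limited cilium appears
  ~0.7 px wide (σ) at 0.35 µm/px; a probe much wider than the object
  flattens the intensity-versus-angle landscape, so the default hugs
  the filament.
* penalty weights (`w_curv` 0.4 rad⁻², `w_tvel` 0.002 s²px⁻²,
  `w_rvel` 0.3 s²rad⁻², `w_dcurv` 0.01 s²rad⁻²). Frames are min–max
  normalized before costing, so the intensity term lies in
  $[-w_I, 0]$ and the weights transfer across movies of different
  brightness. The defaults were chosen on synthetic movies to leave
  low-noise tracing essentially unbiased (the penalties cost ≪ the
  intensity gain of following a clean filament) while still rescuing
  tracing at SNR 2, where unpenalized tracing falls apart.

Probe samples that fall outside the image take the frame median (a
background estimate); a segment whose probe lies entirely outside
truncates the trace with a flag, and the remaining segments carry the
previous frame's geometry.

## Drift stabilization

Whole-islet translation (treatments, osmotic pressure changes) is not
part of the tracing model and must be removed first. Registration is
FFT-based and purely translational, in two passes:

1. **Consecutive pass.** The shift between consecutive frames is the
   peak of the inverse transform of their cross-power spectrum, with
   mean subtraction, a Hann window, and a Gaussian low-pass
   (`blur_sigma_px`, default 4 px) so that tissue-scale structure, not
   the thin bright cilium or pixel noise, drives the fit. Subpixel
   precision ($1/\mathrm{upsample}$, default 1/10 px) comes from
   evaluating the correlation on a locally upsampled grid by direct
   matrix-multiply DFT — deterministic, no iterative fitting. Shifts
   are accumulated relative to frame 0.
2. **Template refinement** (`refine_iters`, default 3). The coarsely
   corrected stack is collapsed to its pixelwise temporal median — a
   template in which stationary tissue stays sharp while the beating
   cilium smears out — and every frame is re-registered against it,
   with pixels downweighted by their temporal variance about the
   template (a stationarity mask that automatically suppresses the
   moving cilium). This pass removes the random-walk error
   accumulation of pass 1 and the bias a bright moving object exerts.

Two numerical details are deliberate. The magnitude-weighted (matched
filter) spectrum is the default rather than the fully whitened
phase-correlation spectrum: whitening weights all frequencies equally,
which is right for rich rigid texture but disastrous for smooth,
low-contrast tissue where most frequencies carry only noise
(`normalization = "phase"` restores the classic behavior). And the
template pass runs unwindowed: any static taper shared by template and
frame — a Hann window as much as our mask would be if it were sharp —
correlates with itself and biases residual shifts toward zero, which
can lock the iteration into a wrong solution; the variance mask
already suppresses the problematic content.

Rotation and scaling are not corrected: only the translation of the
ciliary base matters to the tracer, whose base is pinned anyway.

## Waveform metrics

All angle-based metrics use segments whose arc-length midpoint lies in
the middle 80% of the cilium ($[0.1L, 0.9L]$), excluding the clamped
base and the noisy tip.

* **Amplitude** — the population SD of $\theta$ pooled over the
  middle segments and all frames, after unwrapping about the circular
  mean (so a cilium oriented near the $\pm\pi$ branch cut, or any
  global rotation of the field of view, gives the same answer). For a
  sinusoidal sweep of angular amplitude $A$ sampled over whole
  periods this equals $A/\sqrt 2$. Pooling over the segments × frames
  set is the default; per-segment-temporal and per-frame-spatial
  variants are exposed via `pooling=` because the field's usage is
  ambiguous.
* **Period / frequency / periodicity** — from $\phi(t)$, the mean
  middle-80% angle: the period is the lag of the first local maximum
  (lag ≥ 2 frames) of the normalized autocorrelation that exceeds
  0.2, and the periodicity is the autocorrelation value at that lag,
  clipped to $[0,1]$. Autocorrelation is preferred to a spectral
  argmax because islet cilia beat irregularly; the first-peak height
  gives "periodicity" — otherwise an undefined word — a concrete,
  bounded meaning: 1 for a metronome, <0.2 (flagged
  `period_unreliable`, period reported absent) for noise. Requiring
  the peak to clear the threshold skips spurious ripples at short
  lags.
* **Length** — $N \Delta s \times$ pixel size: fixed by the seed, in
  µm.
* **Maximal curvature** — $\max_{i,t}
  |\theta_{i+1,t}-\theta_{i,t}|/(\Delta s\cdot\text{µm/px})$ over
  interior joints in the middle band. Being a maximum over all joints
  and frames, it is an extreme-value statistic: on noisy traces it
  reflects the noise tail as much as true bending, and it should be
  compared between conditions traced at the same SNR and $\Delta s$.

## The simulator, and what passing tests mean

`simulate_cilium_movie()` renders a single-harmonic traveling wave

$$\theta(s,t) = \theta_0 + A\,\sin(2\pi t/T - k s + \phi_0)$$

integrated from the base at ≤ 0.5 px arc steps, drawn with a Gaussian
transverse profile (σ 0.25 µm — sub-micron apparent width), on top of
a uniform background, dim Gaussian "tissue blobs" emulating
out-of-focus islet autofluorescence (static in specimen coordinates,
so they carry the drift signal exactly as real tissue does),
cumulative random-walk drift, and additive Gaussian noise clipped at
zero (SNR defined as (peak − background)/noise SD; Poisson noise is
deliberately out of scope to keep SNR interpretable). `k = 0` gives a
rigid pivot; `period_jitter_sd` adds per-cycle multiplicative period
jitter for irregular beats. The exact angle field, centerline, and
drift are returned, and identical seeds give bit-identical movies.

Default study conditions mirror the acquisition regime of live
islet-cilium recordings: 512×512 fields at 0.26–0.44 µm/px (0.35 in
the defaults), ≥ 1 frame / 2 s for 10 min (300 frames), an 8 µm
cilium, A = 0.3 rad, T = 24 s.

What the simulator does *not* emulate — photobleaching, Poisson/read
noise statistics, focal drift, neighboring moving cilia, 3-D motion
through the focal plane — bounds what a passing test shows: parameter
recovery on these movies demonstrates the estimator chain is correct
and well-conditioned at realistic SNR, not that every real movie will
trace cleanly. The per-frame cost diagnostics (mean ± 2 population
SDs, outliers flagged) exist precisely to surface frames needing
manual review in real data.

Problem sizes in the test suite are chosen to exercise each property
at the smallest scale that still shows it: most tracer and metric
tests run on 160×160 scenes of 40–120 frames; drift recovery uses
256×256; the single end-to-end recovery test runs the full 512×512,
300-frame condition.

## A worked example

```{r example, eval = FALSE}
mdl <- waveform_model(base_xy = c(250, 280), base_angle_rad = -0.6,
                      length_um = 8, amplitude_rad = 0.3, period_s = 24)
rp  <- render_params(noise_sigma = 10, drift_sigma_px = 0.5, rng_seed = 42)
sim <- simulate_cilium_movie(mdl, rp, n_frames = 300)

stab <- apply_correction(sim$stack, estimate_drift(sim$stack))
fit  <- trace_movie(stab, seed_from_truth(sim$truth))
summary(fit)
plot(fit)                  # temporal waveform heatmap
plot(fit, type = "costs")  # per-term cost series with ±2 SD bands
```

## Known limitations

* One cilium per run; multi-cilium scenes need one seed each.
* Length is frozen at seeding; a cilium that grows past its seed is
  traced only over the seeded arc.
* The grid search bounds rotational velocity at
  $\Theta/\Delta t$; a cilium sweeping faster than ~15°/s at 2 s
  sampling will be lagged (raise `angle_halfwidth_rad` or image
  faster).
* Stabilization assumes some stationary structure shares the field of
  view; a field containing nothing but the moving cilium gives the
  template pass nothing to hold on to.
* TIFF I/O covers single-channel multi-page grayscale; multi-channel
  or z-stack files and proprietary microscope formats are out of
  scope.
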