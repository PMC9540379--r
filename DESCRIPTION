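Package: ciliawave
Title: Seeded Tracing and Waveform Quantification of Beating Primary Cilia
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantifying the motion of single primary cilia in
    time-lapse fluorescence microscopy. Given a user-supplied seed (a
    stationary ciliary base and an initial trace toward the tip), the
    package follows the cilium frame by frame as a chain of equal-length
    segments, choosing each segment's tangent angle by minimizing a
    penalized intensity cost evaluated on a rotating rectangular probe
    array. Whole-field specimen drift is removed beforehand by FFT phase
    correlation with subpixel refinement. The resulting tangent-angle
    field theta(s, t) is post-processed into waveform metrics: beat
    amplitude, period, frequency, periodicity, cilium length and maximal
    curvature. A synthetic-movie generator renders ground-truthed
    beating-cilium stacks so that tracing and metrics can be validated by
    parameter recovery without real data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
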