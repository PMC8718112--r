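---
title: "slicequant: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{slicequant: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slicequant)
```

This vignette documents the models behind the three pipelines, the
parameters that matter, the numerical conventions, and what the synthetic
generators do and do not emulate. It is the package's own account of its
procedures; every empirical claim here is one that the test suite or
`scripts/acceptance.R` computes.

## Membrane fluorescence quantification

The measurement problem: estimate the mean receptor-label fluorescence on
the plasma membrane of one neuron from a two-channel Z-stack, where a
cytoplasmic fill (GFP) reports the cell's shape and the label channel
(Alexa 594) carries the signal of interest. The pipeline per optical slice:

1. **Gaussian smoothing** of the fill channel, `blur_sigma = 1` px by
   default. Implemented as separable convolution with a truncated kernel
   (half-width `4σ`, renormalized) and *symmetric-reflection* borders.
   Reflection was chosen over circular or replicate padding because the
   cell can sit near the image edge and any darkening there would bias the
   threshold. The implementation is tested against a dense double-loop
   convolution oracle to 1e-10.
2. **Moment-preserving (Tsai) thresholding.** Among all bilevel
   quantizations of the intensity distribution, choose the one preserving
   the first three sample moments. The closed form gives the
   below-threshold mass fraction
   `p0 = (z1 − m1)/(z1 − z0)` where `z0, z1` are the roots of the
   moment-matching quadratic. Because only finitely many mass fractions
   are attainable on a discrete histogram, the implementation selects the
   sample value whose attainable fraction minimizes the third-moment
   mismatch (the first two moments are matched exactly by the
   representative levels for *any* candidate split, so this is the full
   moment-mismatch criterion). A brute-force candidate search that solves
   the two-level system numerically for every threshold serves as the
   oracle; the two routes agree on random 8-bit histograms. Pixels
   *strictly above* the threshold are foreground. Degenerate (constant)
   planes are an error, surfaced as a segmentation failure naming the
   slice. The criterion is equivariant under positive affine intensity
   maps, so gain/offset changes move the threshold but never the
   partition.
3. **Cleanup**: hole filling, then the largest 8-connected component.
   EBImage's labeling is 4-connected, so diagonal-touching labels are
   merged by union--find before size ranking; ties resolve to the smallest
   label. Cleanup exists because neighbouring labeled neurites would
   otherwise attach spurious pieces to the mask.
4. **Contour tracing**: the mask's outer boundary (foreground pixels with
   an edge-adjacent background pixel; image borders count as background)
   ordered clockwise by Moore-neighbour tracing into a closed 8-connected
   ring one pixel (~0.08 µm) wide. A seeded random break turns the ring
   into an open line, mirroring the original macro's selection-to-line
   conversion; the break position provably cannot change a mean along the
   path, and tests assert that irrelevance rather than assume it.
5. **Pooling**: the label channel is averaged along the contour per slice,
   and slice means are averaged with *equal weights* (a mean of means, not
   a pixel-weighted mean) into F-memb, by default over
   `n_slices_analyzed = 10` consecutive slices.

Two genuinely open choices, and how they were settled:

* **Which side of the mask edge carries the line.** Both sides are within
  one pixel of each other. The *foreground* side was chosen because the
  membrane signal surrounds the fill, so the inner boundary maximizes
  rim overlap on phantoms; slice exclusion plus the recorded per-slice
  means let users replicate the manual practice of discarding slices with
  truncated masks (no automated detector is provided — the original
  practice was a judgement by eye, and the package exposes
  `exclude_slices` instead of guessing).
* **Group comparisons** are reported as integer percent of control
  (`percent_of_control()`), matching how such comparisons are usually
  printed.

## Internalization (F/F0)

The cytoplasm region is the cell mask eroded by `erosion_px = 8` px with a
Euclidean disk structuring element, implemented exactly via the distance
transform (`distance to background > r`), with a zero-padding ring so that
image borders behave as background. Eight pixels at 0.08 µm/px is a
~0.6 µm band, wide enough to keep membrane signal blurred over >1 px out
of the cytoplasmic mean. Erosion monotonicity (`region(r) ⊆ region(r−1) ⊆
mask`) is asserted as a property. A cell thinner than twice the erosion
radius empties the region and raises a degenerate-geometry error rather
than returning a misleading mean.

F-cyt pools per-slice region means with equal weights, like F-memb. The
compartment fractions are `F-memb/(F-memb + F-cyt)` and its complement —
computed as `1 − memb` so their sum is exactly 1 in floating point. F/F0
compares fractions across timepoints; both ratios are invariant under a
uniform gain change of the "after" acquisition, which is the reason
fractions rather than raw intensities are compared at all. No image
registration is attempted: measurements are region means and the
before/after pairing is by `cell_id`. Background fluorescence is *not*
subtracted, matching the underlying protocol; the nucleus is included in
the cytoplasm region because the fill channel does not distinguish it —
both conventions are deliberate and documented rather than configurable
magic.

## Spike-train metrics

Recordings are loose cell-attached traces of spontaneously active neurons
(~1.5 Hz). Detection, when starting from a raw trace, thresholds the
absolute deviation from the trace median at `spike_threshold_sd` (default
4) times the MAD-based noise SD — MAD rather than SD because the spikes
themselves would inflate a naive SD estimate — keeps each excursion's
extremum, and enforces a 2-ms refractory. A note on false positives: a
single-sample threshold at 4 SD on Gaussian noise crosses spuriously at
rate `P(|z|>4) ≈ 6.3e-5` per sample, i.e. a handful of events per minute
at 10 kHz. That is a property of every threshold detector, not of this
implementation; the tests therefore assert exact recovery of injected
spikes at a threshold where the Gaussian tail bound makes noise crossings
negligible (5.5 SD for the trace lengths used) and recovery-with-possible-
extras at 4 SD.

The metrics are window statistics on spike counts:

* `percent_inhibition`: `100·(1 − r_w/r_b)` with the baseline rate over
  the pre-agonist epoch (at least 60 s required; a silent baseline is an
  error because such cells are excluded from analysis, not scored) and the
  agonist rate over a window 1–2 min after onset. Clamped to [0, 100];
  rebound firing above baseline reports 0 with a `rebound` flag.
* `percent_desensitization`: early-window inhibition minus the inhibition
  at 5 min (window 4.5–5 min), clamped to [0, 100]. The "at 5 min" anchor
  is operationalized as one 30-s window; both windows are arguments, so
  other conventions are one keystroke away. The difference is *not*
  rescaled by the maximal inhibition by default — the raw difference is
  consistent with how inhibition/desensitization pairs are usually
  tabulated (e.g. ~99% inhibition with ~32% desensitization) — and a
  `normalized = TRUE` variant is available.

Binned time courses use half-open 15-s bins (`[k·b, (k+1)·b)`; an edge
spike belongs to the later bin), and counts are conserved by construction.

## Saturation binding

Wells are background-subtracted (mean of the no-primary wells, per
wavelength) and each well's 784 nm signal is normalized to its own 658 nm
signal; wells whose denominator is nonpositive after subtraction are
flagged and excluded rather than silently producing wild ratios.
Normalization happens per well *before* any averaging; replicates enter
the fit as points. The nonspecific component is modeled as linear through
the origin — the standard assumption for antagonist-blocked labeling — and
estimated from the blocked wells alone, then held fixed while `Bmax` and
`Kd` are fit to the total wells by Levenberg–Marquardt least squares
(unweighted: no weighting scheme is part of the protocol being modeled).
A simultaneous fit of both curves (`method = "shared"`) is provided; the
two agree on noise-free plates. Kd estimates far above the tested
concentration range trigger a warning. Throughout, "Kd" is an apparent
labeling coefficient of a covalent reagent, not an equilibrium constant.

## Synthetic generators

The generators define the conditions under which the pipelines are
validated; their defaults mirror the experimental regime they emulate.

**Cell phantoms** (`make_cell_stack`): a disk, ellipse or sinusoidally
perturbed blob with a 1–3 px membrane rim at 200 AU, uniform cytoplasm at
20 AU over a 10 AU background, GFP fill at 150 AU, 0.08 µm/px, 10 slices
at 0.5 µm (tests typically render 1–2 slices at 120–256 px for speed; the
geometry is identical across slices). Internalization moves a programmed
fraction of the *total* rim signal into non-overlapping cytoplasmic
puncta, conserving summed intensity, so F-memb, F-cyt and the fractions
are analytic. Noise is additive Gaussian rounded to integer counts
(a PMT-regime approximation); an optional Gaussian PSF can blur the
phantom *before* noise so contour-overlap tolerances stay honest when
blur is being studied. What the phantoms do not emulate: dendrites and
neurites, per-slice shape variation, photon (Poisson) statistics, slice
cross-talk, or a distinguishable nucleus — so passing tests demonstrate
correctness of the measurement pipeline, not robustness to every feature
of real tissue.

**Firing phantoms** (`make_spike_experiment`): an inhomogeneous Poisson
process at 1.5 Hz baseline (180 s, comfortably above the 60-s minimum the
metric requires), then inhibition at depth `d` held for a 120-s plateau
covering the early measurement window, then exponential relaxation
(τ = 90 s) toward `d·(1 − p)`. This plateau-then-decay form exists
because a pure exponential recovery from onset cannot hold the 1–2-min
window at 100% mean inhibition while recovering by 5 min; with the
plateau, both window means are analytic and `solve_firing_params()`
inverts any (inhibition, desensitization) target. Recovery fractions
above 1 produce rebound firing; the truth record then reports the
*clamped* expected metrics, exactly as the measurement clamps. Sampling
is by thinning, so spike times are exact draws from the rate profile.
Not emulated: bursting, slow drift of the baseline, seal-quality changes,
or correlated (non-Poisson) spiking.

**Binding phantoms** (`make_binding_plate`): the six-concentration design
(0, 1, 3, 10, 30, 100 nM), triplicate total and duplicate blocked wells,
background wells included, rendered as two-wavelength signals whose
per-well normalization returns the model ratios exactly when noise-free.
Noise is multiplicative Gaussian on the net signals, the dominant
variability of plate fluorescence. Not emulated: edge effects, pipetting
gradients, or wavelength cross-talk.

All generators take an `rng_seed`, are bit-reproducible under it, and
restore the caller's RNG state.

## Numerical conventions and degenerate inputs

* Arrays are `[slice, row, col]`, 0-based physical origin at pixel
  centers; intensities are doubles internally regardless of file depth.
* TIFF output is 16-bit integer; integer-valued stacks round-trip bit for
  bit, and non-integer stacks are rejected at write time rather than
  silently quantized. Channel identity is always declared by the caller —
  wavelength tags are not trusted. Metadata travels in a JSON sidecar.
* Thresholding requires ≥ 2 distinct values; erosion must not empty the
  mask; contours require a single hole-free component; all-excluded slice
  lists, silent baselines, short agonist epochs, and all-zero plate
  designs are errors, not NA propagation.
* Tie-breaks are fixed: equal-size components keep the smallest label;
  the threshold candidate search takes the first minimum; bin edges are
  half-open to the right.

## Problem sizes in the shipped tests

The suite renders phantoms at 64–256 px with 1–6 slices, runs the firing
grid at 9 programmed conditions × 200 seeds, and fits 100 noisy plates;
the full suite completes in well under a minute on one core, and the
acceptance script in a few seconds. These sizes were chosen as the
smallest at which the discretization tolerances (5% contour overlap,
Jaccard ≥ 0.98 on a 60-px-radius cell) are meaningful.

## Known limitations

* One neuron per stack; no instance segmentation or dendrite tracing.
* No registration between before/after acquisitions; large drift would
  bias both compartments, though fractions absorb uniform gain only.
* The moment-preserving threshold assumes a roughly bimodal histogram;
  a field of view dominated by background with a tiny cell can put the
  split inside the background mode. The recorded per-slice thresholds
  make such failures visible.
* Spike metrics assume one unit per recording; no sorting is attempted.
* The binding model fixes nonspecific labeling as linear through the
  origin; saturable nonspecific components would bias `ns_slope` into
  `Bmax`.
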