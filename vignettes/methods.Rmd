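---
title: "Quantifying centrosome fracturing in migrating cells: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying centrosome fracturing in migrating cells: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

A migrating cell's centrosome — two centrioles held together by a cohesive
linkage — experiences mechanical load when the cell squeezes through complex
environments. In live imaging of centrin-2 (CETN2) labelled cells, the pair
appears as two fluorescent puncta that normally stay 0.5–1 µm apart. Under
load the pair can suddenly *fracture*: the centrioles separate at rates of
micrometers per minute, sometimes re-cohering later ("repair"), sometimes
splitting long-term. cenfrac turns calibrated time-lapse movies of such cells
into the quantitative phenotypes of this process: per-frame distance
categories, cell-level fracture calls, breakage frequency, separation
velocity, maximal separation, repair outcome, junction decision timing,
front–rear polarity profiles, bulk chemotactic velocity, FRAP recovery
parameters and cell-to-vessel proximity.

Because raw movies of this kind are rarely shareable, the package ships a
synthetic-movie generator (`make_centriole_movie()` and friends) that encodes
the same statistical structure the analyses assume and returns the exact
ground truth alongside the pixels. Every pipeline stage is validated against
that ground truth rather than against published figure values.

## Distance phenotypes

All distances are in micrometers; pixel `(row, col)` maps to
`x = (col-1)·pixel_size`, `y = (row-1)·pixel_size`.

**Fracture threshold.** A frame is fractured when the inter-centriole
distance is at least 1.5 µm. The threshold is *inclusive*: the category
scheme below places 1.5 µm in "near", and printed bounds such as "1.49" are
display rounding of half-open intervals, so `d = 1.5` must count as
fractured. A cell is fractured when at least `min_fractured_timepoints`
(default 2) frames — any frames, not necessarily consecutive — are
fractured.

**Categories.** Two schemes, both half-open with inclusive lower bounds:
dendritic-cell `[0,1.5) / [1.5,3.5) / [3.5,5) / [5,∞)` (close, near,
short-distance separated, long-distance separated) and fibroblast
`[0,1.5) / [1.5,3) / [3,∞)` (close, near, far). `classify_frame()` therefore
partitions `[0,∞)` and is monotone in distance, and
`is_fractured_frame(d) ⇔ classify_frame(d) ≠ "close"` at the default
threshold.

**Separation velocity.** The estimator is the maximum over sliding windows
of 3 consecutive observations (configurable) of Δdistance/Δtime after
fracture onset, in µm/min; onset is the first frame at or above the
threshold, and the window immediately preceding the crossing is included so
a fast initial jump is not missed. A window-maximum over noisy slopes is
biased upward; with a localization RMS near 0.05 µm the bias is negligible
for windows spanning ≥ 1 min but grows like the extreme-value expectation of
the per-window slope noise as the frame interval shrinks. The validation
cohort therefore images every 30 s (see below).

**Repair.** A fractured cell is `repaired` if, after onset, the distance
returns below the threshold and stays there for at least `rejoin_frames`
(default 3) observations; `non-repaired` if it never returns; `censored` if
the series ends inside a too-short re-cohesion run. The 3-frame persistence
requirement exists because localization noise near the threshold would
otherwise flip single frames below it.

**Junction decision time.** The clock runs from the first entry of the cell
reference point into the junction polygon to the first frame after which it
has permanently exited; re-entrant excursions keep the clock running. The
reference point is the nucleus centroid when available, else the
centriole-pair midpoint. An entry-based clock was chosen over a
first-protrusion clock because protrusion events are not available to an
automated tracker.

## Detection and linking

Centriole puncta are detected per frame by a Laplacian-of-Gaussian filter at
the scale of the expected diameter (default 0.65 µm), local-maximum
selection, and a quality cut expressed as a fraction of the strongest
response in the frame (default 0.5) — the automated counterpart of a
manually adjusted quality threshold.

Sub-pixel refinement is the intensity-weighted centroid of the *positive
band-passed response* in a window of about one object diameter. This choice
is deliberate: a centroid of the raw image over a wider (two-diameter)
window is pulled toward the partner punctum whenever the pair is at cohesive
distance (≈ 0.8 µm ≈ 5–6 px here), collapsing the measured distance by
several hundred nanometers. The LoG response's negative annulus cancels the
partner's shoulder, and the tight window bounds the residual bias; on
noiseless synthetic pairs the distance RMS error is ≈ 0.03 µm, and ≈ 0.05 µm
at SNR 5.

Linking is a greedy two-identity assignment minimizing summed frame-to-frame
displacement, with exact ties broken by spot quality rank. A missed
detection is bridged for up to `gap_size` (default 3) frames by carrying the
last position as assignment memory while recording the frame as missing —
never interpolating; longer gaps end the track. More than four candidate
spots persisting for three consecutive frames abort the cell as ambiguous.
Distances are invariant under global translation/rotation of the field and
under A/B relabeling.

## Intensity measurements

**Line profiles** use bilinear interpolation at a uniform step (default
0.1 µm) along a 5-µm segment. Normalization divides by the mean of the first
and last four samples *pooled* (a single mean of 8 samples); a per-end
variant is available behind `per_end = TRUE`. Pooling was chosen because the
two ends of a centriolar-axis profile sample equivalent cytoplasm, and a
pooled mean is insensitive to which end is "first".

**Two-ROI ratio.** Mean intensity in two circular ROIs (radius 0.35 µm)
centered on the two centrioles of a summed z-projection, ratio with the
higher mean as divisor — symmetric in the inputs and confined to (0, 1].
ROI membership is a pixel-center test without sub-pixel area weighting,
matching common region-measurement behaviour; the discretized area converges
to πr² as the pixel size shrinks, which is how the tests reconstruct the
radius from the mask.

**FRAP.** Normalization is
`(bleached − background) / (reference − background)`, rescaled so the
pre-bleach mean is 1 — single-reference normalization, no double
normalization to whole-cell intensity. The generator produces five 1-s
pre-bleach frames by default. Because the underlying studies report recovery
as curves without a scalar statistic, the exponential fit
(`value = plateau − (plateau − depth)·e^{−kt}`, via Levenberg–Marquardt) is
an explicit extension of the package: it reports `τ½ = ln 2 / k` and the
plateau-derived mobile fraction `(plateau − depth)/(1 − depth)`. A flat
post-bleach curve returns mobile fraction 0; a decreasing one is an error.

## Polarity profiles

Per cell and frame: pixels within 1.5 µm of any centriole are excluded
(a disk — the radius reading of the ambiguous "1.5-µm area" — and the
exclusion applies to the per-cell normalization mean as well, i.e. the mean
is over included pixels only); each channel is normalized by the cell's
all-time-point mean; pixel positions are projected onto the migration
direction and rescaled to [0, 1] by that frame's min/max projection (the
cell's own extent, not its bounding box); pixels fall into 50 (fine) or 2
(front/back) equal segments; the bin value is mean normalized reporter over
mean normalized reference, averaged first within each time point and then
across time points. Cells must contribute at least 6 usable time points
(30 min at 5-min intervals). Empty bins are reported missing, never imputed.

The migration axis, when not supplied, is the mask-centroid displacement
smoothed over 3 frames — sustained chemotactic movement makes this estimator
stable, and reversing the declared axis exactly reverses the bin order.

The synthetic polarity cell is a translating *rectangle* carrying a linear
reporter ramp and a uniform reference. The rectangle is intentional: with a
constant width profile, the expected per-bin ratios have a closed form
(`polarity_bin_oracle()` evaluates the continuous-geometry integrals,
including the exclusion disks, by fine 1-D quadrature), so the profiler can
be scored to sub-percent accuracy. Real cells have irregular shapes, so the
passing tests demonstrate the correctness of the projection/normalization/
binning arithmetic, not robustness to segmentation error.

## Bulk velocimetry

The collagen-migration tool is re-implemented as: (i) background correction
by subtracting the pixelwise temporal mean (negatives clipped — correlation
on signed residuals is unstable for sparse scenes); (ii) 8-connected
component size filtering with inclusive area bounds; (iii) per-frame-pair
displacement as the integer shift maximizing zero-mean normalized
cross-correlation over the overlap region within a 25-px search radius
("optimizes its overlap" operationalized as NCC; phase correlation is
available behind `method = "phase"`), ties broken toward the smaller shift
to avoid drift inflation in featureless frames, optional 3-point parabolic
sub-pixel refinement; (iv) chemotactic velocity as the y-displacement toward
the declared source direction (a movie attribute, default `+y`) times pixel
size over frame interval, in µm/min. Integer scripted drifts are recovered
exactly and the estimator is antisymmetric under frame exchange.

## Vessel proximity

The distance map is the exact Euclidean distance transform of the
vessel-mask complement (validated pixel-for-pixel against brute-force
nearest-vessel search), scaled to µm. Cells are reduced to centroids before
lookup; `per_pixel = TRUE` retains the original per-pixel reading, reporting
the distance distribution over all supra-threshold pixels. Binarization
thresholds and projections are inputs, not computed — they were manual in
the source workflow.

## Noise model and synthetic data

Puncta are isotropic 2-D Gaussians (σ default 0.2 µm — the diffraction scale
at the 0.1426 µm/px calibration; no PSF is stated for the source data).
Noise is Poisson shot noise plus additive Gaussian read noise, with SNR
defined as peak signal over read-noise σ; the default test SNR of 5 is a
free parameter chosen as a conservative lower bound for spinning-disk
centriole imaging, and `snr = Inf` gives strictly noiseless frames. Fracture
kinetics are piecewise linear in time (constant cohesive distance, linear
separation at the scripted µm/min rate from onset, linear re-approach after
the repair frame), matching the locally linear separations that motivate a
single separation-velocity scalar. Every generator is a pure function of
(parameters, seed), restoring the caller's RNG state.

What the generators do *not* emulate: photobleaching outside FRAP, 3-D
optics, cell-shape realism, motion blur, or neighbouring cells. Passing the
synthetic validation therefore certifies the measurement arithmetic and the
detector/linker under the stated noise model, not performance on arbitrary
real recordings.

## Problem sizes and numerical choices

The shipped validation cohort is 100 synthetic cells (50 scripted fractures
at 2 µm/min with repair), 40 frames of 128×128 px every 30 s at SNR 5 —
about a minute of compute. The 30-s interval is a deliberate study-design
choice: the prescribed 3-observation window-maximum velocity estimator then
spans 1 min, where its noise-induced upward bias (≈ +0.05 µm/min at the
measured localization RMS) is well inside the ±0.2 µm/min validation band;
at few-second intervals the same estimator is biased upward by several
tenths of a µm/min on any implementation, because it takes the maximum of
many noisy short-baseline slopes.

Other numerics: movies are written as 16-bit integer TIFFs so intensities
round-trip bit-exact; CSV tables serialize doubles at 17 significant digits
for lossless round-trips; assignment ties in the linker use a 10⁻¹² cost
tolerance before quality-rank tie-breaking; the displacement search orders
candidates by |shift| so exact score ties resolve toward zero; the FRAP fit
starts from the first post-bleach value and the last-quintile mean and
rejects non-positive recovery rates.

## Known limitations

- The linker handles exactly one centriole pair per movie; crowded fields
  must be cropped to single cells upstream, as in the source workflow.
- Fracture onset is defined by threshold crossing, so a cell fracturing
  before the recording starts has its onset censored at frame 1.
- The polarity profiler assumes masks are correct; segmentation error
  propagates directly into bin ratios.
- `comet_stats()` reports nucleation rate both per anchor and per cell
  because the normalization convention varies between studies.
- Decision timing needs the track to leave the junction before the recording
  ends; otherwise the decision time is reported missing.
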