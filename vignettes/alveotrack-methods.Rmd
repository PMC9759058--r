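---
title: "AlveoTrack: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{AlveoTrack: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AlveoTrack)
```

AlveoTrack analyzes two-channel intravital microscopy of the ventilated
lung: an interstitial channel in which fluorescent dextran renders the
tissue bright and the alveolar airspaces dark, and a neutrophil channel in
which labeled immune cells appear as bright blobs. This vignette explains
the processing model, the parameters that matter, what the synthetic
benchmark does and does not emulate, and the design decisions taken where
the problem was genuinely open.

## The processing model

### Denoising and mask formation

Each frame is first denoised with non-local means: pixel $p$ is replaced by
a weighted average of pixels $q$ in a $21 \times 21$ search window, with
weight $w(p,q) = \exp(-d^2(p,q)/h^2)$ where $d^2$ is the mean squared
intensity difference over $7 \times 7$ patches centered on $p$ and $q$.
The filter strength is $h = 35$ for the interstitial channel and $h = 45$
for the noisier, sparser neutrophil channel. The implementation (in C++)
computes patch distances offset-wise with integral images, shares one
distance field between each pair of opposite displacements, and reads
weights from a table over integer-quantized $d^2$ — $d^2$ of 8-bit imagery
lies in $[0, 255^2]$, and a table step of one unit is three orders of
magnitude below $h^2$, so the quantization is far below any visible effect.
Borders are handled by coordinate clamping (replicated edges). $h = 0$ is
an exact identity, and constant frames are preserved exactly.

Feature masks are then formed per channel by Gaussian blur, intensity
threshold, and dilation, in that fixed order. The blur kernel is 11 px with
$\sigma = 0.3\,((k-1)/2 - 1) + 0.8$ derived from the kernel size — the
conventional size-to-sigma rule — giving $\sigma = 2$. Thresholding keeps
pixels *below* the cutoff for the alveolar mask (airspaces are unlabeled
and dark; the default cutoff is 50) and *above* it for the neutrophil mask
(default 60). The cutoffs are exposed hyperparameters: acquisition
protocols differ in labeling intensity, and no single value is universal.
Dilation uses a square structuring element of side 4. Blurring before
thresholding erodes the detected region by roughly $0.8\sigma$ at a sharp
edge; the subsequent dilation expands it by a comparable amount, which is
why the blur–threshold–dilate order reproduces feature areas well (about
1% error on the synthetic benchmark).

### Segmentation

Foreground components of the mask are labeled with 8-connectivity and each
component yields one contour: its external boundary traced clockwise
(Moore neighbor tracing), its pixel count as area, and the mean of its
pixel coordinates as centroid. Coordinates are 0-based, $x$ = column,
$y$ = row. Holes inside components are neither emitted as contours nor
subtracted from areas; on this imagery dark airspaces are solid regions
and holes are vanishingly rare. Per-channel area restrictions (alveoli
200–26000 px², neutrophils 30–800 px² at 512×512 scale, both configurable)
discard implausibly small or large components.

### Temporal-consistency filtering

The distinctive step of the pipeline exploits the video structure: a
detection at frame $t$ is kept only if at least one detection at frame
$t-1$ or $t+1$ matches it. A match requires both centroid proximity
(default radius 20 px for alveoli, 15 px for neutrophils) and area
agreement — relative for alveoli
($|a_1 - a_2| \le 0.5 \max(a_1, a_2)$, since breathing deforms them) and
absolute for neutrophils ($|a_1 - a_2| \le 50$ px²). The centroid criterion
is our addition to the area rule: area alone would match distant,
coincidentally same-sized features. The filter is a **single pass** judged
against the *unfiltered* neighboring frames. Because the match relation is
symmetric, a matched neighbor is itself always kept, so iterating the
filter to a fixed point would change nothing; single-pass semantics make
this explicit and keep the operation order-independent. Matching is
existential, not one-to-one assignment — the requirement is that a
plausible continuation exists, not a full tracking solution. Persistent
track IDs via greedy nearest-centroid linking are available
(`linkTracks()`) but are an extension: the core filter never depends on
track identity.

### Per-frame statistics and respiratory cycles

All areas are reported as percentages of the whole image; with no reference
region available in-frame, image-area normalization is the reproducible
choice. Airspace per alveolus divides the frame's alveolar percentage by
that frame's alveolus count. Interstitial area uses a bright-polarity mask
of the denoised interstitial channel with otherwise identical parameters.

Respiratory cycles are delimited at troughs (end-expiration) of the
alveolar-area signal: the signal is smoothed with a centered 3-frame moving
average; local minima with topographic prominence of at least 0.5
percentage points and pairwise separation of at least 4 frames become cycle
boundaries, deeper troughs winning ties. Troughs were chosen over peaks
because the resulting cycles rise through inspiration and fall through
expiration, matching ventilator volume–time convention. Cycle min/max are
taken from the **unsmoothed** signal within each span so reported extremes
are not biased low by the smoothing. Frames before the first and after the
last trough belong to no cycle. The defaults suit breathing periods of
roughly 6 frames and up; faster breathing relative to the frame rate needs
a smaller `minCycleLen`.

### Two-experiment comparison

Alignment is manual: a signed frame offset applied to series B (dropping
leading or trailing frames, no resampling) before its cycles are
re-detected. The per-cycle scalar compared across experiments is the
**mean** of the feature over the cycle — stable against single-frame
outliers, and symmetric in the two experiments. Slope charts report
first-cycle vs last-cycle means; distribution summaries report the
five-number summary plus mean with linearly interpolated quartiles, and
attach the raw per-frame values so a plotting layer can draw violins.
Hypothesis testing between conditions is deliberately out of scope.

## The synthetic benchmark

`generateScene()` emulates the data's defining structure: a bright
interstitial background (intensity 200) with dark elliptical airspaces
whose semi-axes scale with the breathing signal
$s(t) = 1 + A\sin(2\pi t/P)$; bright Gaussian-profile neutrophils drifting
at constant velocity and reflecting off the margins; one-frame transient
blobs placed at least 30 px (twice the matching radius) from every
persistent neutrophil path, so their removal by the temporal filter is
unambiguous; and additive Gaussian sensor noise clipped to $[0, 255]$.
Ground truth is analytic: $\pi a b\, s(t)^2$ per alveolus and $\pi r^2$
per neutrophil (the blob's disk above the mask threshold in the clean
rendering).

The default configuration — 256×256 px, 64 frames, period 16 frames,
amplitude 0.2, six alveoli of 18–28 px radius, five neutrophils of 4–7 px
radius drifting 1 px/frame, ten transients, noise $\sigma = 5$ — is sized
so that features are well separated, breathing spans three full cycles,
and noise is visible but not dominant: a clean but realistic instance of
the imaging geometry. Radii modulate with breathing while centers stay
fixed, which reproduces the area oscillation the analysis measures while
keeping centroids within the matching radius of the temporal filter.

What the generator does **not** emulate — and hence what passing tests do
not establish about real recordings: respiratory-motion blur and frame
shear, focal drift, illumination inhomogeneity, Poisson shot noise,
overlapping or merging alveoli, neutrophil shape change and extravasation,
and episodes of image-quality collapse. Results on synthetic scenes bound
the method's correctness, not its robustness to degraded acquisitions.

## Numerical choices and degenerate inputs

* All processing is deterministic; the generator seeds a local RNG and
  restores global state, and identical seeds give bit-identical scenes.
* NLM weight quantization (one intensity-unit² steps) and the
  sigma-from-kernel rule are fixed, documented constants.
* Thresholding is strict (`<` / `>`); mask dilation with the even kernel
  size 4 expands two pixels up/left and one down/right (anchor at the
  element center, rounding down), matching common morphology conventions.
* One- and two-pixel components get a pixel-corner rectangle as their
  polygon so every contour has at least three vertices; they are normally
  removed by the area restrictions anyway.
* Empty masks yield empty contour lists, not errors; an all-constant
  alveolar signal yields the explicit error
  `"no complete respiratory cycle detected"`, which `analyzeExperiment()`
  converts to a warning plus `NULL` cycles so batch runs survive.
* Feature placement in the generator uses rejection sampling with full
  restarts; infeasible configurations fail with `"cannot place features"`
  after bounded retries rather than looping.
* 16-bit sources are mapped to 8-bit by full-scale division (65535 → 255)
  so that acquisitions of different brightness remain comparable; mapping
  by the observed maximum would make the scale content-dependent.

## Problem sizes in the test suite

Unit tests run on 32–128 px frames and scenes of 2–32 frames; the
end-to-end benchmark checks use the default 256×256, 64-frame scene
(segmentation, tracking, and cycle recovery) and a 128×128, 32-frame scene
for the bit-level determinism check; the contour extractor is validated
against a brute-force connected-component oracle on one hundred random
32×32 masks. These sizes exercise every code path at full parameter
settings while keeping the suite quick to run.

## Known limitations

* No registration or motion compensation: sudden shifts or artifacts in
  the video will fragment detections (they may, however, be caught by the
  temporal filter as inconsistent features).
* Merged alveoli are detected as one contour; no watershed splitting.
* Cycle detection assumes a quasi-periodic alveolar signal; apnea or
  irregular ventilation produce few or no cycles.
* Comparisons handle exactly two experiments; the offset is manual (an
  automatic cross-correlation alignment is exposed as an extension point
  but the manual offset is authoritative).
* Inspiratory and expiratory sub-phases are not labeled, and no
  lung-compliance estimate is derived.
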