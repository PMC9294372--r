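---
title: "Trial-based calcium imaging: registration, segmentation and cross-session tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trial-based calcium imaging: registration, segmentation and cross-session tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caimtools)
```

`caimtools` processes trial-structured two-photon calcium imaging movies
through five stages: motion correction, per-trial active-neuron
segmentation, session-level mask integration, cross-session alignment, and
dF/F trace extraction. A seeded synthetic generator produces ground-truth
movies so that every stage is testable without real data. This vignette
explains the models behind each stage, the parameters that matter, and the
design choices made where more than one reading was defensible.

## Motion correction

Brain pulsation and body movement translate the field of view between
frames. Each frame `a` (h × w) is aligned to a fixed template `t` (by
default the first frame; a mean image can be supplied instead) by the
integer offset `(x, y)` minimizing the windowed mean squared difference

```
D(x, y) = 1 / ((h - |x|)(w - |y|)) * sum_ij (t[i, j] - a[i + x, j + y])^2
```

over `(x, y) in [-Ms, Ms]^2`. `Ms`, the maximum shift, defaults to one
fifth of the smaller frame dimension; too small a value fails when true
motion exceeds it, too large a value admits spurious matches and shrinks
the usable central window.

Only the central crop of the frame (margins of width `Ms` removed) is
compared against sliding windows of the full template. This makes the
overlap area constant, so the normalization drops out of the argmin, and
expands the objective into three terms: a sliding-window sum of `t^2`
(precomputed once per template), the constant `sum(a'^2)` of the crop, and
a cross-correlation term computed for all offsets at once with a 2-D FFT.
A note on the expansion: the box-filter identity is applied to the
*template* squared (windowed sums of `t^2` over crop-sized windows), with
the crop's own sum entering as a constant — the mathematically consistent
arrangement of the three terms.

Because FFT arithmetic carries round-off, every offset whose FFT score is
within a small relative tolerance of the minimum is re-scored by exact
direct summation before the argmin is taken. The result is therefore
bit-identical to exhaustive evaluation of the objective, including the
deterministic tie-break (smallest `|x| + |y|`, then row-major), which the
test suite verifies against a brute-force oracle on small fixtures.

Design notes:

* **Integer offsets only.** The objective is defined over integer
  translations; no subpixel interpolation is attempted. Registered frames
  are produced by pure index shifts, so intensities are never resampled.
* **Coarse-to-fine mode** estimates the shift on block-averaged images and
  refines by exhaustive exact search in a `±(factor + 1)` full-resolution
  window; it must (and in tests does) reproduce the exhaustive result.
* **Degenerate frames** (zero variance) abort with an error naming the
  frame rather than silently returning (0, 0).

## Per-trial segmentation

A trial is `N` frames at `fps` Hz: a baseline window (by default the first
second) followed by a response window. Two algorithms identify ROIs from a
single trial, both deterministic.

**Algorithm 1 — cumulative dF/F with entropy thresholding.** Each pixel's
dF/F is computed against its baseline-window mean; pixels with near-zero
baseline are zeroed and counted. The dF/F is summed over the response
window, floored at zero, and multiplied by the pixel's temporal dF/F
standard deviation over the response — a per-pixel scale that favours
transient pixels over flat ones of equal sum. We read the published
"standard deviation" scale as this per-pixel *temporal* SD: it is the only
reading that yields a 2-D scale image to multiply into the cumulative
image. The scaled image is auto-thresholded by the three-order Renyi
entropy procedure (orders 1/2, 1, 2 computed on a 256-bin histogram after
linear rescale, combined with the published order-dependent weighting and
5-bin closeness rule). The binary image is Gaussian-smoothed (sigma 1 px
default) to merge neighbouring positive pixels, re-binarized at 0.5,
labelled by 8-connected components, and filtered by area (default 16 px)
and by peak cumulative dF/F (default 10, in original cumulative-dF/F
units — the rescaled histogram units are never exposed).

**Algorithm 2 — amplified sensitivity index.** Each pixel is binarized at
its baseline mean plus 3 population SDs (computed over the baseline window
only; the baseline statistics stage of the pipeline). The binary series
`chi` is amplified by the recurrence `L[t] = alpha (L[t-1] + beta) chi[t]`
(`L[1] = chi[1]`, `beta = 1/alpha` by default): a run of `n` consecutive
ones reaches `(alpha^n - 1)/(alpha - 1)`, while isolated noise crossings
stay near 1 and any zero resets the accumulator. Scattered ones of equal
count always score lower than one contiguous run. The time-summed index is
smoothed with a normalized Gaussian kernel (sigma 1) truncated to a
cell-sized window (13 px default) and thresholded at `T = alpha * F + k`,
where `F` is the number of continuous above-threshold frames that counts
as a real transient for the indicator in use; a geometric variant
`T = alpha^F + k` is selectable, since the amplified index itself grows
geometrically in run length. Components pass the same area filter and are
ranked by peak pixel dF/F.

Two numerical points deserve emphasis. First, `alpha` defaults to 1.5: the
index grows like `alpha^run`, so at `alpha = 2` a 45-frame transient
amplifies to ~7e13 and even the far tail of the smoothing kernel exceeds
any threshold of the form `alpha * F + k`, dilating every ROI to the full
kernel window (and overflowing double precision for runs beyond ~1000
frames). At 1.5 the index spans a usable range for trial-length movies
while preserving the run-length convexity that makes the filter work.
Second, both algorithms can fuse genuinely adjacent cells — any
smoothing-based labeling does — which is why the synthetic generator's
default cell spacing is deliberately sparse (below).

## Session masks and cross-session alignment

Per-trial masks are integrated with a capture-all rule: every ROI detected
in any trial is kept. ROIs from different trials are identified as the
same cell when their pixel overlap is at least a fraction (default 0.3) of
the smaller ROI; matches chain transitively through a union-find, and the
merged shape is the pixel union, so no ROI pixel is ever lost. The overlap
fraction is an interpretive choice — the matching rule is not prescribed —
and is exposed as a parameter, alongside a plain binary-OR mode that is
the simplest capture-all reading but can fuse adjacent cells.

Repeated sessions of one field of view are aligned on their time-averaged
images. The similarity metric is the negative mean squared error after
intensity standardization (no metric is prescribed; standardized MSE is
insensitive to gain and offset drift between sessions). Optimization is a
multi-resolution pyramid (block-mean factors 4, 2, 1): the rigid solve
initializes rotation on a coarse grid (−6° to 6°, 2° steps, translation
per angle from the FFT registration engine) and refines (theta, dr, dc) by
Nelder–Mead at each level; the affine solve refines all six matrix entries
from the rigid optimum and is accepted only if it does not score worse.
Everything is deterministic given the inputs. The reference session's
frame is the common space: all transforms map target coordinates to
reference coordinates, and masks are warped into the reference frame
(nearest-neighbour for labels, which are categorical; bilinear for
intensity images). ROIs warped fully outside the frame are dropped with a
report; partial ROIs are cropped. An explicit 2×3 matrix can be supplied
to override estimation (the programmatic replacement for interactive
inspection), and rotations beyond about 5° lose margin content
irrecoverably — a documented limitation of planar alignment, not of the
optimizer.

## Trace extraction

Per ROI, `F(t)` is the mean over the ROI's pixels; `F0` is the mean of
`F(t)` over the baseline window (equivalently, the mean over all ROI
pixels and baseline frames — the reading we adopt for the baseline
formula); the activity trace is `(F(t) - F0)/F0`. `F0` is computed per
trial by default, matching the trial-based design; a session-constant
baseline is available. An ROI is *active* when its peak dF/F exceeds its
baseline-period mean by `n_sd` standard deviations of the baseline dF/F
(sample SD; default `n_sd = 5`, with 3 a common lenient alternative — both
are exposed because both appear in practice). A fixed dF/F floor and a
minimum-size filter are available as alternative criteria. Active ROIs
sort first, by descending peak, ties broken by centroid. dF/F is exactly
invariant to multiplicative rescaling of the movie, and responds to an
additive offset `b` by the closed form `(F - F0)/(F0 + b)` — both are
asserted in tests.

## The synthetic generator

Two generators provide ground truth. The **shift simulator** emulates
heartbeat-locked motion: in each axis, frame `i` receives
`Mx * sin(2 pi rate i / F)` while the sine is nonnegative and zero
otherwise, plus uniform jitter `U(-Mr, Mr)`, rounded to integers (the
phase is read as `2 pi i / F` — one cycle per second at the default 1 Hz
rate, generalized by a rate multiplier). Movies are built by translating a
single base image (edge-replicated), so registration against that base
must recover the series exactly; accuracy is scored per axis as
`diff(t, e) = sum (t_i - e_i)^2`.

The **cell-movie generator** plants Gaussian-profile cells (sigma 3 px) on
a constant background. The defaults are the study conditions used
throughout the tests: 15 fps, a 1-s baseline and 3-s response per trial,
128×128 px, 8 cells, background 100, cell contrast 1, transient amplitude
3.0 dF/F with instantaneous rise and a 15-frame (~1 s) decay — the
dynamics of a bright genetically encoded indicator responding to a burst —
and additive read noise of SD 2. The transient multiplies each footprint
pixel's own baseline by `1 + a(t)` uniformly inside the 2-sigma
ground-truth disk, so every ROI pixel's true dF/F is exactly `a(t)` and
the extracted peak equals the nominal amplitude — which is what lets
amplitude-recovery tests assert against a closed form. Cell centres are
rejection-sampled at a minimum spacing of 8 sigma: a sparsely labelled
population in which single cells are resolvable by smoothing-based
segmentation. What the generator does *not* emulate — overlapping and
touching somata, neuropil contamination, photobleaching, shot-noise
scaling, z-drift, non-rigid deformation — bounds what the passing tests
show: they validate the algorithms' mechanics under their stated
assumptions, not performance on dense or unstable real tissue.

## Problem sizes and verification

The test suite exercises registration oracles on 8–32 px fixtures
(`Ms` 2 and 4), full shift recovery on a 300-frame 256×256 simulated movie
(`Ms` 51), segmentation recovery on ten seeded 60-frame movies per
algorithm, and cross-session recovery at 1°–5° on 128×128 blob fields;
`scripts/acceptance.R` scans 1°–10° rotations (plus a (7, −4) px
translation) of a 30-blob 256×256 field and reports the largest angle
aligned to sub-pixel mean centroid error. These sizes were chosen to probe
every code path at full fidelity while keeping a complete run in the
minutes range on a single CPU.

## Known limitations

* Registration is translation-only and integer-valued; rotation within a
  session, non-rigid deformation and subpixel motion are out of scope.
* Both segmentation algorithms can merge adjacent active cells and make no
  attempt to demix overlapping somata.
* The sensitivity index overflows double precision for contiguous runs
  beyond roughly `1000 / log2(alpha)` frames; use a smaller `alpha` for
  very long continuous recordings.
* Cross-session alignment assumes a planar field of view; rotations much
  beyond 5° lose marginal content irrecoverably.
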