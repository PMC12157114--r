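---
title: "Adaptive union/intersection fusion of segmentation masks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive union/intersection fusion of segmentation masks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maskfuse)
```

## The problem and the method

Automated brain tissue segmentation (skull stripping) on head CT produces a
binary mask per slice: 1 for brain parenchyma, 0 for everything else.
Convolutional segmenters of the U-Net family are good at this but make
*directional* mistakes: some habitually label skull-base, periorbital or
subcutaneous tissue as brain (over-segmentation — false positive pixels),
others clip true brain tissue (under-segmentation — missed pixels). When
masks from two or more models are available, the right way to combine them
depends on that direction:

* the pixel-wise **intersection** of masks can only *remove* foreground, so
  it never adds a false positive beyond what every model already agrees on;
* the pixel-wise **union** can only *add* foreground, so it never loses a
  pixel that any model found.

maskfuse makes the choice empirically. On a labelled calibration set, each
model `m` is summarized by two totals:

* `num_overseg(m)` — predicted-foreground pixels the ground truth calls
  background, summed over all calibration slices (total false positives);
* `num_miss(m)` — ground-truth foreground pixels the model misses
  (total false negatives).

The fusion rule classifies each model as **OVER** (`num_overseg > num_miss`),
**UNDER** (`num_miss > num_overseg`) or **NEUTRAL** (exactly equal;
comparisons are strict because only the two strict cases are well defined —
see below). Then:

* two or more OVER models → fuse all OVER models by intersection;
* otherwise, two or more UNDER models → fuse all UNDER models by union;
* otherwise no two models agree in direction; the plan defaults to
  intersection over all models and the plan's `rationale` string flags
  `tie-unresolved default`.

The two-model tie (one OVER, one UNDER) is inherently undecidable by this
rule; adding a third model resolves it by supplying an agreeing pair, which
is why `select_strategy()` takes any number of profiles and fuses *all*
models agreeing in the majority direction. The intersection default for the
unresolved case reflects what this model family does in practice —
segmentation networks on head images produce more false alarms than misses —
and is always auditable from the serialized plan.

## Evaluation metrics

Two complementary scores are computed per slice and aggregated:

* **IoU** (Jaccard index): overlap pixels over union pixels, in `[0, 1]`.
  Sensitive to region fill, insensitive to exactly where a boundary error
  sits.
* **Hausdorff distance (HD)**: contours are taken as the sets of foreground
  pixels with at least one 4-neighbour of background (off-image counts as
  background, so foreground bleeding off the image edge is boundary and gets
  penalized). The directed distance `h(A,B)` is the exact
  max-over-A of min-over-B Euclidean distance; `HD = max(h(A,B), h(B,A))`.
  No percentile approximation is used — the implementation is the exact
  all-pairs form, vectorised; boundary sets on the phantom sizes used here
  are a few hundred points, so exactness costs nothing. HD is reported in
  pixel units throughout: the pixel spacing of the source images is
  deliberately treated as abstract.

Whole-series aggregation is deliberately reported two ways, because
reasonable people aggregate differently and published tables rarely say
which: `mean_iou` (unweighted mean of per-slice IoU — small bottom/top
slices count as much as large middle ones) and `pooled_iou` (IoU of
confusion counts summed over slices — pixel-weighted). Comparisons in this
package's reports default to `mean_iou`.

**Empty-slice conventions.** A whole-head series contains slices with no
brain at all, and their ground truth is all background. Conventions chosen:
IoU of two empty masks is 1 (a perfect all-background prediction must score
perfectly); HD of two empty masks is 0; HD between an empty and a non-empty
mask is *undefined* — recorded as `NA`, excluded from `mean_hd`, and counted
in `n_undefined_hd`. Replacing the undefined case with an arbitrary large
constant would let a single blob on an empty slice swing the mean by an
amount chosen by the implementer rather than the data; flagging and counting
is honest.

## Post-processing

The refinement step smooths the 0/1 mask with a normalized 9×9 Gaussian
kernel of unit standard deviation and re-binarizes with a strictly-greater
threshold at 0.5. Since the kernel's centre weight is ≈ 0.159 < 0.5, an
isolated foreground pixel cannot survive, and by complement symmetry an
isolated hole is filled: the step scrubs speckle noise near predicted
boundaries in both directions, which is exactly the false-positive cleanup
it is used for. Numerical choices:

* **Reflect padding** at image borders. Zero padding would erode foreground
  touching the border — and real skull-stripped slices do touch the border.
  Under reflect padding constant masks are exact fixed points.
* **Strictly greater than 0.5.** The equality case is measure-zero (the
  Gaussian weights are irrational), but a deterministic tie rule costs
  nothing and makes the complement-duality property
  `smooth(!m) == !smooth(m)` exact.
* Kernel size, sigma, and threshold are exposed
  (`gaussian_kernel(size, sigma)`, `threshold` argument) but the defaults
  are the method's; nothing in the package tunes them.

Two pipeline orders are supported and labelled, because either reading is
defensible: `filter_then_fuse` (default — each model's output is smoothed,
then fused; profiling and single-model "filtered" columns then refer to the
same masks that get fused) and `fuse_then_filter`. Similarly, profiling uses
raw predictions by default with a flag to profile filtered ones; both
variants of the counts are what the profile report is for.

## The synthetic benchmark

No clinical data ships with the package; every test and the acceptance
script run on synthetic phantoms generated in code.

**What the phantom emulates.** A head series of 31 slices of 128×128 pixels
(a routine head series has "over 30" slices; pixels are abstract). Slice
area follows a unimodal profile — small cross-sections at the bottom of the
head, maximal in the middle, small near the vertex, topmost slice empty.
Each non-empty slice's brain region is a perturbed ellipse: an ellipse
(`base_radius` default `0.3 * min(height, width)` ≈ 38 px, so the brain
fills about a third of the field of view with room for surrounding anatomy)
whose radius is modulated by three low-frequency radial harmonics with fixed
amplitudes and slowly drifting phases. Fixed amplitudes mean the enclosed
area stays proportional to the squared radius scale, so the measured
per-slice areas track the configured unimodal profile; drifting phases make
neighbouring slices similar but not identical, like real anatomy. The
lowest quartile of slices carries *distractor* blobs disjoint from the
brain — stand-ins for eyes, cheeks and skull base, the structures that real
segmenters falsely label as brain.

**What the simulated segmenters emulate.** A `segmenter_profile` applies,
in order: boundary jitter (random single-pixel flips along the contour, both
directions), uniform dilation *or* erosion (mutually exclusive, so the
profile's error direction is unambiguous), spurious foreground blobs placed
outside the true region with 80% preference for distractor structures, and
an occasional disc-shaped "bite" out of the region. The default trio mirrors
the qualitative behaviours reported for U-Net-family models on this task:
`unet_like` (moderate dilation, distractor-linked false alarms, occasional
bites), `unet2p_like` (strong over-segmentation, misses essentially
nothing), `unet3p_like` (most accurate, boundary noise with small false
alarms). All three over-segment far more than they miss, so profiling them
selects intersection — the configuration the method was designed around.
These defaults were chosen once, when the generator was written, and frozen.

**What the phantom does *not* show.** It contains no intensity information,
no anatomy beyond "one smooth dominant component plus distractors", no
inter-patient variability, and its error processes are statistically clean
(dilation is exactly uniform; blob placement is independent across models
except through the shared distractor geometry). Passing the package's tests
therefore demonstrates that the *decision rule, fusion algebra, metrics and
post-processing* behave as specified — not that any particular IoU or HD
level would be attained on clinical images. One consequence visible in the
benchmark numbers: because all models prefer the same distractor regions,
their false-alarm blobs sometimes co-locate and survive intersection, which
inflates mean HD (a single surviving far-away blob dominates a slice's HD)
even while IoU improves substantially. That, too, mirrors practice: fusion
removes most, not all, false alarms.

## Problem sizes

The shipped test-suite and acceptance script use: metric-oracle checks on
500 random mask pairs up to 16×16 against independent brute-force
implementations; fusion algebra on 500 random tuples; direction-recovery
over 20 seeds of a 7-slice 48×48 phantom; and the benefit benchmark over 50
seeds of the full 31-slice 128×128 phantom with the default three-model
trio, on which the adaptively fused series' mean IoU matched or beat every
single model in 100% of runs (the suite asserts ≥ 90%). These sizes keep a
full run in well under a minute per property while leaving the statistics
stable across seeds.

## Known limitations

* Masks are strictly binary and 2-D per slice; fusion is slice-wise with no
  3-D regularization across slices.
* The Hausdorff implementation is exact but quadratic in boundary size; for
  megapixel masks a distance-transform formulation would be the next step.
* Only the Gaussian smooth-and-binarize refinement is implemented; no
  morphological or connected-component post-processing.
* Probabilistic label fusion (e.g. STAPLE-style weighting) is out of scope:
  the point of this method is that two set operations, chosen by a
  calibration-set error profile, already capture most of the benefit.
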