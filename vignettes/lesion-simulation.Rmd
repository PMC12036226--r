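---
title: "Simulating microcalcification clusters and enhancement in CEM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating microcalcification clusters and enhancement in CEM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cemsim)
```

## The problem

Contrast-enhanced mammography (CEM) pairs a *low-energy* image, equivalent
to a digital mammogram, with a *recombined* image that highlights iodine
uptake.  Microcalcification clusters — the earliest imaging sign of many
in-situ carcinomas — are small, enhance only weakly (lesion-to-background
ratios of roughly 1.00–1.06 in the recombined image), and are
under-represented in the datasets used to train lesion detectors.  `cemsim`
implements a hybrid simulation approach: simulated clusters are inserted
into *real-style* background images rather than fully synthetic phantoms,
so the surrounding anatomy is realistic by construction, and matched
enhancement is added to the paired recombined image.

The package has three parts: the simulator (site selection, cluster
synthesis, insertion, masks, enhancement), the ROI-level evaluation
protocol a detector study needs (IoU matching, sensitivity/precision,
AUC, patient-level bootstrap), and deterministic fixtures that make
everything testable without clinical data.

## The simulation pipeline

`simulate_case()` runs the whole chain on one view:

1. **Breast segmentation** (`segment_breast`): Otsu threshold, largest
   component preferring those touching a lateral border, hole filling.
   Any segmentation of comparable quality would do; the rest of the
   pipeline only needs a support mask.
2. **Site selection** (`compute_grid_features`, `select_insertion_site`):
   five texture features (mean, standard deviation, entropy, mean
   gradient magnitude, range) are computed on a grid of non-overlapping
   200 × 200-pixel cells; cells with less than 90 % breast coverage are
   dropped.  Features are combined by direction-aware, weighted *rank*
   aggregation — ranks rather than raw values because the features are
   incommensurable — and the top cell wins, with ties broken by
   (row, col) order so the result does not depend on input order.  The
   exact feature set is a documented, replaceable default
   (`default_feature_specs()`); what matters downstream is only that the
   chosen cell is dense and structurally busy.
3. **Candidate extraction** (`candidate_mask`, `extract_candidates`):
   the binarized Frangi vesselness response (scales 1–4 px, β = 0.5,
   cut at the 95th percentile of the within-cell response) is intersected
   with an intensity threshold mask (cell mean + 1 SD).  Candidates are
   therefore bright *and* lie on or near curvilinear structures, which is
   how real calcifications present.  Connected components use
   8-connectivity.
4. **Morphology filtering** (`filter_candidates`): typically benign
   clusters keep circular candidates (circularity 0.5–1.0) of equivalent
   diameter 0.3–1.2 mm; typically malignant clusters accept any
   circularity at 0.1–0.5 mm.  All intervals are closed.  Circularity is
   4πA/P² with the perimeter taken from the marching-squares contour of a
   lightly smoothed mask (Gaussian σ = 0.7 px): contouring the raw binary
   mask follows the pixel staircase and overestimates the perimeter by
   10–15 % on small discs, which would misclassify genuinely round
   regions.  The value is clamped at 1 to absorb residual discretization
   bias on very small regions.
5. **Cluster growth** (`grow_cluster`): the 10 × 10-pixel sub-cell with
   the highest contrast (max − mean) seeds the cluster; the search window
   grows by one sub-cell ring per iteration, incorporating every filtered
   candidate whose centroid falls inside, until a target count drawn
   uniformly from the class range (10–20 benign, 20–40 malignant) is
   reached.  When the final ring overshoots the target, the target count
   of regions closest to the seed sub-cell is kept, so counts always land
   inside the class range.  If fewer candidates than the class lower
   bound exist, the view is infeasible and is skipped — a deliberate
   property of the protocol, not an error of the caller's making; the
   condition class `cemsim_infeasible_cluster` makes it catchable.
6. **Template insertion** (`build_template`, `degrade_template`,
   `insert_template`): the binary cluster becomes a multiplicative
   template — background exactly 1.0, calcification pixels
   1 + amplitude · w with w a distance-transform profile peaking at each
   region's centre.  The default peak excess 0.15 is a configurable
   stand-in for system-specific contrast.  Degradation blurs the excess
   with a normalized Gaussian PSF (default σ = 1 px) and scales it by
   1 − scatter_fraction (default 0.2).  Because the template is exactly
   1.0 off-support, insertion by multiplication is bit-transparent
   outside the lesion and exactly invertible on it.
7. **Automatic lesion mask** (`generate_lesion_mask`): convex hull of the
   calcification pixels, an outward corner-smoothing pass, rasterization
   and a disc dilation (default 5 px) to emulate the perilesional margin
   radiologists include.  The corner pass is corner-cutting *in reverse*:
   each corner contributes two points displaced outward by `offset_px`
   (default 2, 2 iterations).  We displace along the two *adjacent edge
   normals* rather than the vertex bisector: edge-normal displacement
   translates every edge outward and bevels every corner, which
   guarantees the input polygon is contained in the output for any convex
   input and any positive offset — with a bisector at fixed offset the
   corner cut can exceed the displacement on long-edged hulls.  Area is
   monotone non-decreasing in iterations.
8. **Enhancement** (`fit_enhancement_distribution`, `sample_enhancement`,
   `apply_enhancement`): measured enhancement ratios (lesion mean over
   background-ring mean) are modelled per (class, view) with a Gaussian
   kernel density on a 121-point grid over [1.00, 1.06], normalized so
   the weighted probabilities sum to 1.  The bandwidth defaults to
   Silverman's rule; the restriction of fitted values to lesions missed
   by a baseline detector is a data-preparation step upstream of the fit.
   Sampling is inverse-CDF on the grid with within-bin jitter, so draws
   are exactly bounded by [1.00, 1.06] without post-hoc clipping.  The
   sampled factor fills the lesion mask, the template is smoothed with a
   Gaussian of σ = 5.0 (interpreted as pixels and config-exposed; the
   physical unit is not pinned down by the protocol) and multiplied into
   the recombined image.

### Ring decomposition

`build_rings()` dilates the lesion mask with 1-pixel 8-connected steps:
the first stop when the dilated area minus the lesion reaches the lesion
pixel count yields the perilesional ring, the second equally sized shell
the background ring.  Step size 1 makes the overshoot at most one
dilation shell.  Lesions touching the image border, or covering a third
of the frame, have no well-defined rings and are rejected.

### Smoothing bias of the measurement

Because enhancement is smoothed (σ = 5 px) before multiplication, the
measured ratio of a small lesion underestimates the applied factor: edge
pixels are attenuated, and some excess spills into the rings.  The bias
shrinks roughly like σ/R with lesion radius R; the test suite asserts the
monotone decrease over three lesion sizes and checks recovery within
±0.005 on lesions of 100 px diameter, the size at which the bias falls
below the measurement tolerance at the top of the enhancement range.

## The evaluation protocol

Predictions below a score of 0.1 are discarded; remaining ROIs are
matched one-to-one to ground truths within each (patient, view) over
pairs with IoU > 0.1.  The protocol specifies the thresholds but not the
assignment rule for multi-overlap cases; `match_rois()` computes the
exact maximum-total-IoU assignment (dynamic programme over ground-truth
subsets, deterministic tie-breaks: more matches, then lowest ground-truth
index), which is well-defined, order-independent, and testable against a
brute-force enumeration oracle.  Per-view ROI counts are tiny in
practice, so exactness costs nothing; a greedy fallback guards the
pathological case of more than 16 ground truths in one view.

A matched pair is a *correct detection* iff the predicted probability of
the ground truth's benign/malignant class exceeds 0.5.  Sensitivity is
correct detections over all true ROIs; precision over all surviving
predictions.  For the classification ROC, every surviving prediction
enters with the overlapped ground truth's class as reference — benign for
unmatched ROIs, penalizing hallucinated malignancy more than hallucinated
benignity — and the malignant probability as score; AUC uses midranks.
DL scores are binomialized as p(predicted class) = 0.5 · score + 0.5, and
ensembling averages the DL and radiomics probability pairs, which can
overrule the DL class when the other model is confidently opposite.  An
exact tie at 0.5 malignant probability classifies as malignant,
consistent with the strict `>` in the correct-detection rule.

Confidence intervals resample *patients* (not ROIs) with replacement,
2000 times by default, taking percentile bounds at 2.5/97.5 %.  Matching
is scoped per patient, so `evaluate_rois()` matches once and resamples
per-patient count records; resamples on which a metric is undefined are
redrawn and counted.  Paired differences between two setups use the same
patient resample on both arms.

## What the fixtures emulate — and what they do not

`generate_background_pair()` builds a half-ellipse breast on a near-zero
background: clustered lumpy texture (Gaussian blobs, σ = 0.7 mm, a
standard mammographic texture surrogate), ducts as smoothed random walks
fanning out from the nipple region with AR(1) brightness modulation along
their length, compact slightly elongated "beads" strung along the ducts
(the duct dims briefly around each bead so the bead reads as its own
opacity), and Gaussian noise.  The recombined fixture is a flat plateau
with mild noise — no enhancement anywhere, so measured ratios are ~1.0.

These choices target the *statistical structure the pipeline consumes*:
the vesselness filter must find curvilinear structures, the intensity
threshold must fragment them into candidate regions of both morphology
classes, and textures must vary between grid cells.  Passing tests on
fixtures therefore demonstrate the pipeline's contracts (determinism,
template and mask invariants, count ranges, bounded enhancement), not
radiographic realism: fixtures have no scatter, no detector noise model,
no compressed-breast thickness gradient, no breast-density classes.
Views for which a fixture yields too few eligible candidates are skipped
by the same rule as any other infeasible view; across the 50-seed batches
used in the tests a modest fraction of benign views is skipped, which
mirrors (at higher rate than) the skip behaviour on real data.

`generate_toy_annotations()` plants ground truths and predictions with
known miss, false-positive and label-flip rates and logs the planted
counts, so sensitivity, precision and AUC can be checked against
hand-computed values.

## Numerical choices

* Convolutions are FFT-based (`EBImage::filter2`) on zero-padded frames,
  so kernel mass is conserved and nothing wraps across the image border;
  excess maps are clamped below 1e-12 to keep template backgrounds
  exactly 1.0.
* The enhancement kernel is truncated at 6σ, so pixels beyond that are
  untouched exactly, and the deep-interior plateau equals the sampled
  factor to <1e-4.
* All randomness flows through explicit seeds; one master seed fans out
  to named per-stage streams (`derive_seed`), so a change in one stage's
  draw count cannot shift another stage's stream.  Repeated calls with
  the same seed are bit-identical, including the 2000-resample bootstrap.
* 16-bit grayscale PNG is written by a small internal encoder (the
  installed PNG writer quantizes to 8 bits); reading uses `png::readPNG`,
  and the write/read round-trip is bit-exact.
* Degenerate inputs are handled explicitly: clusters with fewer than
  three or collinear calcification pixels fall back to a disc-dilated
  mask; empty unions give IoU 0; a metric without predictions reports
  `NA` rather than a number.

## Problem sizes used in the checks

The packaged checks run 50-seed simulation batches per class on
800 × 640 fixtures, 500 random matching instances against the exhaustive
oracle, 10,000-draw sampling checks per fitted distribution, and a
200-replication nested coverage study of the 2000-resample bootstrap —
sizes chosen so each property is exercised well past its edge cases
while the whole suite stays convenient to run routinely.

## Known limitations

* Cluster models are 2D and per-view; CC and MLO clusters of one breast
  share a class but not geometry, matching the image-level training goal.
* Absolute calcification contrast and the degradation constants are
  configurable stand-ins; only their contracts (template >1 on support,
  exactly 1 off-support, excess conservation) are pinned.
* Background parenchymal enhancement and low-energy/recombined appearance
  correlation are not modelled.
* The radiomics feature set behind site ranking is a five-feature proxy;
  swapping in a richer set only requires a different `feature_specs`
  table.
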