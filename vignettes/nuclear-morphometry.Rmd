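---
title: "Nuclear morphometry of thyroid FNA ThinPrep fields: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nuclear morphometry of thyroid FNA ThinPrep fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Thyroid fine-needle aspirations that land in the indeterminate "atypia of
undetermined significance" category are diagnosed with substantial
inter-observer variability, because the distinguishing criteria — specimen
cellularity, follicular-cell crowding, chromatin quality — are judged
visually and are not quantified. ThinPrep liquid-based preparations produce
stain-standardised cell monolayers that are well suited to digital image
analysis. `tpdia` implements a complete quantitative pipeline for this
setting: it reduces RGB field images to a binary nucleus mask, measures
every connected particle with a classic particle-analysis measurement set,
engineers an 86-feature per-image vector organised into interpretable
feature models, and classifies follicular adenoma versus benign thyroid
with tree-ensemble learners under a repeated split protocol. A parametric
synthetic image generator with exact ground truth makes every stage
testable end to end.

```{r setup}
library(tpdia)
```

## Segmentation

A field image is processed in the green channel only. Hematoxylin-stained
chromatin is purple: it transmits red and blue and absorbs green, so the
green channel carries the strongest nucleus/background contrast of the
three. (`extract_green()` takes the channel verbatim; no stain
deconvolution is attempted, since deconvolution matrices for this material
are not available and single-channel extraction is sufficient for
binarisation.)

Illumination is flattened by `subtract_background()`. The background is
estimated as the grayscale morphological closing of the image with a disc
of radius 50 px (configurable): for dark objects on a bright field, closing
erases every object smaller than the disc and returns the smooth
illumination surface. The image is replicate-padded by the radius before
closing so image borders introduce no artefacts, and the result is returned
as `255 + img - background`, clipped to [0, 255] — background maps to a
flat bright level, object contrast is preserved, and a flat field maps to a
flat field. The radius must comfortably exceed the nuclear radius
(about 15 px at high power); 50 px leaves a wide margin at both tiers.

Binarisation uses an automatic histogram threshold (`auto_threshold()`):
Otsu's between-class-variance criterion by default, with the IsoData
intermeans iteration as an alternative, the two classic behaviours of
general-purpose image analysis software. The mask is `gray <= threshold`.
A constant image has no separable classes and returns an empty mask with a
`degenerate` flag rather than an error. Interior holes — which chromatin
texture can punch into a nucleus at the threshold — are filled before
particle analysis, since nuclei are solid objects and holes would corrupt
area and intensity statistics.

All downstream intensity statistics are computed on the same
background-subtracted green channel that produced the mask, so thresholding
and intensity measurement share one consistent substrate.

## Particle analysis

Connected mask components ("particles" — one nucleus, or one overlapping
cluster of nuclei) are labelled under 8-connectivity by default and
filtered by a minimum-area speck filter (4 px at mid power, 20 px at high
power — safely below the 100 px floor of the single-nucleus gate).
Border-touching particles are retained by default (configurable), since
dropping them would bias per-image counts downwards.

Each particle is measured with `measure_particle()`:

* **Area**: pixel count.
* **Perim**: traced along the outer 8-connected boundary
  (Moore-neighbour tracing; hole boundaries excluded) and estimated with
  corner-corrected chain-code weights, 0.980 per orthogonal step, 1.406 per
  diagonal step, −0.091 per direction change. The naive 1/√2 chain length
  overestimates a digital circle's perimeter by a uniform ≈5%, which would
  push a disk's circularity to ≈0.91; the corrected estimator is
  near-unbiased on smooth shapes (disks measure 1.01–1.04 before the cap).
* **Circ** = 4π·Area/Perim², capped at 1.0 (small digital shapes can
  exceed 1).
* **AR** and **Round**: from the moment-fitted ellipse. The pixel
  coordinate covariance (population denominator, plus 1/12 on the diagonal
  for the within-pixel variance of a unit square, which keeps 1-pixel-wide
  lines non-degenerate) is eigen-decomposed; AR = √(λ₁/λ₂). With the
  fitted ellipse scaled to the particle's area, Round = 4·Area/(π·Major²)
  reduces exactly to 1/AR.
* **Solidity** = Area / convex-hull area, the hull taken over the four
  corner points of every pixel square, so hull area ≥ pixel area and
  solidity ≤ 1 by construction.
* **MaxFeret** / **MinFeret**: maximum pairwise distance over hull
  vertices, and the rotating-calipers minimum width (minimum over hull
  edges of the farthest-vertex distance).
* **Intensity statistics** over the particle's pixels: Mean, Median, Mode
  (ties resolve to the smallest gray value), Min, Max, StdDev (sample,
  n−1), Skew = m₃/m₂^1.5 and Kurt = m₄/m₂² − 3 (excess kurtosis; the
  excess convention is what produces the negative kurtosis values typical
  of flat-ish nuclear textures), IntDen = Area × Mean and RawIntDen = Σ
  pixel values (equal under unit pixel calibration).

Degenerate conventions are fixed and documented: a single-pixel particle
reports Circ = AR = Round = Solidity = 1, Feret diameters 1, Perim 4; a
constant-intensity particle reports StdDev = Skew = Kurt = 0. The median is
computed per particle, like every other intensity statistic. All geometry
is reported in pixel units; no micron calibration is applied.

The test suite backs every measurement with an independent brute-force
oracle — exhaustive pairwise distances for MaxFeret, a fine caliper
rotation sweep for MinFeret, an independently implemented monotone-chain
hull for solidity, direct summation for the intensity moments, and an
exhaustive 256-threshold between-class-variance search for Otsu — evaluated
on more than a hundred random rasterised rectangles, ellipses and blob
unions.

## Gating and the 86-feature schema

High-power particles are gated by area and circularity into **single**
nuclei (area in [100, 1200) px, circ in [0.5, 1.0]) versus overlapping
**clusters** (area in [1200, ∞) px, circ in [0.0, 1.0]); everything else
(debris, specks, elongated artefacts) is **rejected**. Area intervals are
half-open — so the two rules are provably disjoint and a particle of
exactly 1200 px is a cluster — and circularity bounds are closed.
Mid-power fields are not gated: their particles form one ungated
population, and only per-image means are taken.

Per image, each feature is the mean or sample standard deviation of one
base measurement over the particles carrying its gate label, giving the
86-feature schema (`feature_schema()`):

| tier | model | features |
|---|---|---|
| mid (100x) | cellularity | Count, TotalArea (2) |
| mid (100x) | ungated means | 12 measurement means |
| high (400x) | architecture | 8 geometry measurements × mean/SD over clusters (16) |
| high (400x) | chromatin | 10 intensity measurements × single/cluster × mean/SD (40) |
| high (400x) | shape | 7 geometry measurements × mean/SD over singles (14) |
| high (400x) | size | AreaSingleMean, AreaSingleStdDv (2) |

Cytology is the union of chromatin, shape and size (56 features);
cellularity lives on the mid-power tier, where fields are sampled to
represent overall specimen cellularity. Feature names follow
`{Base}{Gate}{Agg}` (`IntDenSingleStdDv`), so importance reports align with
the feature table layout of the underlying study design. A gate with no
particle yields a missing mean; with fewer than two, a missing SD —
missingness is data. Before classification, missing values are imputed
with the training-split median per feature (tree learners in the backing
implementations reject missing values; the median is split-safe and leaks
no validation information).

## Classification protocol

Rows are per-image feature vectors (an optional `collapse_cases()` averages
a case's fields). The data are split 1:1 into training and validation,
stratified by diagnostic label, and the split is repeated three times. The
default split unit is the **case**: an image-level split would place fields
of the same patient on both sides and leak case identity, inflating
validation performance; `unit = "image"` is available for protocol
variants, with that caveat.

Two learners are trained per repeat: gradient-boosted trees (via xgboost,
binary logistic objective, 100 rounds, single-threaded) and extremely
randomized trees (via ranger with `splitrule = "extratrees"`, one random
split point per candidate feature, no resampling, 500 trees). Follicular
adenoma is the positive class. Accuracy, precision and recall use the 0.5
probability threshold; the ROC is swept over all thresholds and the AUC is
computed by the rank (Mann–Whitney) convention with midrank tie handling,
which equals the trapezoidal area under the full-threshold curve. Metrics
are summarised per learner and pooled as mean with min–max range over
repeats. Feature importance uses the extremely-randomized-trees impurity
importance on all rows (no split), normalised to sum to 1, reported next to
per-class means and two-sided pooled-variance Student's t-tests (Welch
optional; p-values are reported raw, with no multiple-testing correction).

`reconstruct_confusion()` inverts printed recall/precision over known class
sizes into the integer confusion matrix and its implied accuracy — useful
for checking the internal consistency of published reader-study metrics:
with 20 positives and 20 negatives, recall 0.95 and precision 0.57 force
TP = 19, FP = 14 and accuracy 0.625.

## The synthetic-field generator

`render_scene()` draws a bright ThinPrep-like background (green level
≈230) with dark elliptical nuclei and deterministic ground truth. The
class-controllable knobs map one-to-one onto the feature models:

* **cellularity** — per-field nucleus count, Poisson with configurable
  mean;
* **architecture** — a configurable fraction of nuclei is placed in
  overlapping groups; members are placed with centre separation at most
  0.8×(sum of minor semi-axes), which guarantees pairwise overlap (every
  ellipse contains the circle of its minor semi-axis), so each cluster
  renders as one connected dark region that reaches the cluster gate;
* **chromatin** — per-nucleus base gray (normal, configurable mean/SD)
  plus per-pixel additive Gaussian texture noise;
* **size/shape** — full major/minor axis distributions in pixels.

Isolated nuclei are rejection-sampled to be pairwise disjoint (up to 1000
retries, then a placement-failure error), so "single" particles are truly
single; all nuclei lie fully inside the frame. Nuclei are coloured
hematoxylin-like (red ≈ gray+35, blue ≈ gray+75), making green the
strongest-contrast channel by construction. `study_scene_spec()` provides
per-class, per-tier defaults anchored to the printed per-class feature
means of the underlying clinical cohort (mid-power counts ≈269 vs 164 per
1024×768 field, high-power single areas ≈482 vs 462 px with aspect ratio
≈1.3, darker and more textured adenoma chromatin, higher adenoma cluster
fraction); when a smaller frame is requested the count mean is scaled by
frame area so nuclear density is preserved.

What the generator deliberately does **not** emulate: colloid, blood and
inflammatory background, stain variation, out-of-focus fields, nuclear
membrane irregularity, and true chromatin spatial texture (the noise model
is i.i.d. Gaussian, so higher-order texture statistics carry no spatial
correlation). Passing tests on synthetic cohorts therefore demonstrate
that the pipeline measures what it claims to measure and that the learners
recover planted class differences — they do not certify clinical
performance on real ThinPrep material.

```{r example, eval = FALSE}
spec <- study_scene_spec("adenoma", "high", width_px = 320, height_px = 240,
                         seed = 7)
scene <- render_scene(spec)
fv <- extract_image_features(scene$image, "high")
fv[c("AreaSingleMean", "CircSingleMean", "MeanSingleMean")]
```

## Numerical and design choices

* **Thresholds and ties.** Otsu ties resolve to the smallest maximising
  threshold; histogram thresholds operate on rounded 8-bit values.
* **Connectivity.** 8-connectivity default (4 available); labelling merges
  diagonally touching 4-connected components by union-find.
* **Determinism.** Every stochastic step — scene placement, Poisson
  counts, texture noise, splits, both learners — is seeded; child seeds
  derive from one master seed through a 32-bit Lehmer-style mix, and both
  learners run single-threaded, so the whole pipeline reruns
  bit-identically.
* **Problem sizes in the shipped checks.** The test suite renders reduced
  cohorts (96×72 to 320×240 px frames, 20 cases per class, 3–4 fields per
  case, per-field counts ≈10 high / 18–30 mid) — sizes chosen so the suite
  exercises cohort-level statistics in about a minute of rendering. The
  acceptance script runs the full study layout (20+20 cases × 10 fields,
  400 images) at 320×240 px. Frame size is a free parameter throughout;
  the study's capture resolution is not stated, and density, not frame
  size, is what the features measure.
* **Known limitations.** Touching nuclei are deliberately *not* split
  (no watershed): the cluster gate is the mechanism that turns overlap
  into signal, mirroring the feature-engineering design. The perimeter
  correction is calibrated for smooth convex-ish shapes; on very small or
  very ragged particles the circularity cap absorbs the residual bias.
  Micron calibration is stored nowhere and applied nowhere — all geometry
  is in pixels, and the gate thresholds are pixel-denominated.
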