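---
title: "Co-occurrence texture staging of renal sonograms: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-occurrence texture staging of renal sonograms: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(renotex)
```

## The problem and the model

Sonographers stage chronic kidney disease (CKD) from B-mode ultrasound
using three visual cues: the renal cortex brightens as fibrosis progresses,
the normally crisp boundary between cortex and medulla/sinus fades, and the
kidney shrinks. `renotex` formalizes this reading as a feature-extraction
and classification pipeline:

* three square 50×50 regions of interest (ROIs) per kidney — cortex,
  corticomedullary boundary, medulla;
* per ROI, 19 second-order texture descriptors from gray-level
  co-occurrence matrices (GLCMs), averaged over the orientations
  0°, 45°, 90°, 135° at pixel distance 1;
* the 57 texture features fused with kidney size (cm) into a 58-vector;
* a 58–10–3 feed-forward network with a 3-way softmax output over
  *normal*, *mild-and-moderate CKD*, *severe CKD*.

Because the clinical images behind this design are private, the package is
organized around a synthetic cohort generator whose statistical structure
mirrors those three cues. Everything downstream of the generator operates
on plain 8-bit grayscale matrices, so user-supplied real images (PNG/TIFF
plus a manifest CSV with ROI coordinates and kidney size) drop into the
same code path.

## The synthetic cohort generator

**What it emulates.** Ultrasound speckle is multiplicative and spatially
correlated. Each region's texture is generated as
`mean_echo × G`, where `G` is a unit-mean Gamma(k, rate = k) field obtained
by mapping a Gaussian-smoothed white noise field through the Gaussian
copula (smooth, standardize, `pnorm`, `qgamma`). Two knobs are
interpretable: `speckle_shape` k (larger = smoother; the relative speckle
contrast is 1/√k) and `corr_length_px` (the smoothing kernel's σ, i.e. the
speckle grain size). The field is scaled, clipped to [0, 255] and rounded
to 8 bits.

**Frame layout.** A frame (default 160×160) stacks cortex, boundary and
medulla bands vertically with the three ROIs centered in them; the two
band transitions sit at 20% and 80% of the boundary ROI's height, so both
edges fall inside that window. Bands are blended with logistic row weights
of half-width `1 + 12 × (1 − boundary_sharpness)` pixels: sharpness 1
gives an essentially crisp edge, sharpness 0 spreads it over ~tens of
rows. The frame size is a package choice balancing realism against the
cost of generating hundreds of frames in routine runs; all layout logic is
parametric in `image_dims` and `roi_side`.

**Per-class calibration.** Kidney size and eGFR moments are the published
per-class values (sizes 11.7 ± 0.46 / 9.14 ± 2.00 / 7.07 ± 1.70 cm; eGFR
105 ± 16.7 / 40 ± 9.7 / 4 ± 4.2). Sizes are truncated normals (floor
0.5 cm, inverse-CDF sampling, so truncation never desynchronizes the
random stream); eGFR is cohort metadata only and never enters the feature
vector. Echo and texture parameters have no published values and are free
calibration choices, fixed once on physiological grounds:

| class | cortex echo / k / corr | boundary echo / k / corr | medulla echo / k / corr | sharpness |
|---|---|---|---|---|
| normal | 60 / 10 / 1.5 | 115 / 8 / 2.0 | 170 / 6 / 2.0 | 1.0 |
| mild-moderate | 110 / 5 / 2.5 | 137 / 5 / 2.5 | 165 / 5 / 2.5 | 0.5 |
| severe | 160 / 3 / 3.5 | 157 / 4 / 3.0 | 160 / 4 / 3.0 | 0.2 |

The progression encodes: cortical echogenicity rising toward the sinus
level (fibrosis), texture coarsening and growing more heterogeneous
(larger grain, smaller k), and corticomedullary differentiation collapsing
(sharpness 1.0 → 0.2; cortex and medulla echo converging 60/170 → 160/160).
The (echo, k) pairs were checked analytically so that 8-bit clipping biases
every region mean by well under 10%.

**What it does not emulate.** No beamforming physics, no depth-dependent
attenuation or focus, no anatomy (no oval capsule, no pelvis), no operator
variability in ROI placement, no scanner post-processing. Passing tests
therefore demonstrate that the pipeline's machinery is correct and that it
can separate classes whose statistical structure matches the qualitative
clinical picture — not that it attains any particular accuracy on real
kidneys.

## Preprocessing

Two ROI-level operators, fixed order, each individually switchable:

1. **Histogram equalization** — `out(v) = round((cdf(v) − cdf_min) /
   (1 − cdf_min) × (levels − 1))` with the empirical CDF of the ROI;
   constant ROIs map to 0. Applied per ROI (not full-frame), matching how
   the windows are read in practice.
2. **Range filter** — local max − min over a 3×3 neighborhood with
   replicate border padding (zero padding would fabricate edge responses
   at ROI borders). The 3×3 default is the smallest standard neighborhood.

Which stages were active is recorded in every feature CSV's provenance
header rather than being hard-wired, since reasonable pipelines disagree
on whether co-occurrence statistics should see the equalized or the
range-filtered image.

## The co-occurrence machinery

Images are quantized to `N = 8` gray levels by default — a standard
co-occurrence toolbox convention that keeps a 50×50 window's 8×8 GLCM
well populated (~2450 pairs per orientation). Binning is equal-width over
the observed range (`image_minmax`; a constant window maps to level 1) or
over [0, 255] (`full_range`). Levels are 1-based inside all formulas, so
sum indices k = i + j run over [2, 2N] and difference indices over
[0, N − 1].

GLCMs are symmetric by default (each pair counted in both directions),
which is the convention the sum/difference-marginal descriptor family
assumes; asymmetric counting is available. All entropies use the natural
log by default (`log2` switchable) with 0·log 0 = 0.

**Dialects.** Published descriptor tables in this literature differ in
small ways from the classical definitions, so the 19 descriptors are
computed under one of two dialects:

* `as_printed` (default): cluster prominence uses exponent 3 and cluster
  shade exponent 4 (swapped relative to classical), and the second
  information measure of correlation is `1 − exp(−2(HXY2 − HXY))` without
  the classical square root.
* `classical_haralick`: exponent 4 prominence, exponent 3 shade, square
  root in IMC2.

Two printed irregularities are treated as typos in both dialects because
they contradict the descriptors' defining ranges: homogeneity is the
positive sum Σ p(i,j)/(1 + (i−j)²) (a leading minus sign would make it
negative), and inverse difference sums over all j (a lower limit of j = 2
would make a constant image score 0 instead of 1).

**Degenerate conventions.** On zero-variance GLCMs (constant windows)
correlation is defined as 0, as are IMC1 and IMC2 when `max(HX, HY) = 0`;
IMC2's exponential argument is floored at 0 before any square root. These
choices keep constant ROIs finite instead of propagating NaN.

**Verification strategy.** Every descriptor is tested three ways: exact
closed forms (constant window, checkerboard, a small worked example whose
GLCM has six cells of probability 1/6), algebraic invariants (marginal
normalization, `HXY1 ≥ HXY`, symmetric-mode `px = py`, rotation by 90°
permuting the 0°/90° and 45°/135° descriptor vectors while fixing their
average), and equivalence to an independent brute-force double-loop
evaluator on hundreds of random small rasters to 1e−10.

## Fusion and serialization

Feature blocks concatenate by ROI name (cortex, boundary, medulla), never
by arrival order, with `size_cm` as element 58; ROI coordinates are
0-based and half-open to remove off-by-one ambiguity. Tables serialize as
CSV with `# provenance:` header lines carrying the active preprocessing
and feature configuration plus the cohort seed, and values at 15
significant digits so a write–read round trip is exact at working
precision. A record that fails extraction aborts the whole run with every
failure listed: silently dropping rows would quietly distort class
balance.

## The classifier

A single hidden layer of 10 tanh units. The published phrase "10 hidden
layers" is read as one hidden layer of width 10 — the configuration of the
classical pattern-recognition toolboxes this design matches — and width,
depth-style experiments can be emulated by changing `hidden_units`.
Training details, all recorded in the returned object:

* inputs scaled to [−1, 1] by training-partition min/max (GLCM features
  span wildly different scales); the scaler never sees validation or test
  rows, and out-of-range inputs at prediction time are clipped so unseen
  extremes stay finite;
* full-batch Adam (step 0.02, β₁ = 0.9, β₂ = 0.999, L2 penalty 1e−4) on
  the softmax cross-entropy; full-batch makes runs bit-reproducible for a
  given seed with no minibatch schedule to document;
* 70/15/15 train/validation/test split (`round` half-up, remainder to
  test: 741 → 519/111/111), optionally stratified by class;
* early stopping after 6 consecutive epochs without a new best validation
  loss (max 1000 epochs), restoring the best-epoch weights — the classical
  validation-failure rule of this network family.

## Evaluation

Classification rate is 100 × trace/total of the 3×3 confusion matrix in
fixed class order; misclassification is its complement. ROC curves are
one-vs-rest threshold sweeps over the distinct scores with tied scores
grouped into single vertices, and AUC is the trapezoid rule — under tie
grouping this equals the Mann–Whitney concordance probability with ties
counted ½, which is how the test suite validates it by brute-force pair
enumeration.

## Problem sizes used by the shipped checks

Routine verification runs the full default pipeline (741 synthetic
kidneys, 160×160 frames) in about a minute on a single core; the
statistical acceptance checks use 100,000 kidney-size draws per class, 200
matched-seed texture replicates for the severity ordering, and five seeded
end-to-end pipeline runs for the ≥ 90% held-out accuracy claim (median
across seeds). These sizes were chosen so the whole suite stays
comfortably interactive while keeping Monte-Carlo standard errors an order
of magnitude below the tested margins.

## Known limitations

* The generator's realism gap (above) means accuracy numbers on synthetic
  cohorts say nothing quantitative about clinical performance.
* Kidney size enters as an opaque scalar; no pixel-based measurement is
  attempted, and units are whatever the manifest supplies (cm by
  convention).
* No automatic ROI localization: windows are given, as in manual clinical
  workflow.
* Single split, no cross-validation or confidence intervals on rates; the
  evaluation module reports point estimates only.
* The GLCM descriptor set is fixed at the 19 listed; no run-length,
  wavelet or learned-feature families.
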