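---
title: "Methods: SC-35 texture phenotyping and screen statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SC-35 texture phenotyping and screen statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scientific setting

Nuclear speckles — domains marked by the splicing factor SC-35 — reorganize
when a cell's nucleosomal (epigenetic) state changes. High-content imaging
exploits this: the spatial texture of SC-35 immunofluorescence inside a
nucleus acts as a single-cell surrogate readout of epigenetic state, and
cells treated with different nucleosome-modifying drugs can be told apart by
classifying that texture. The companion readout is a plate-based screen of
osteogenic differentiation in human mesenchymal stem cells: alkaline
phosphatase (ALP) activity normalized to DNA content, with cell viability
(MTS) and adipogenesis (AdipoRed) as secondary assays, and Dunnett
many-to-one testing of every drug condition against the untreated osteogenic
control.

`speckletex` implements both arms as a tested pipeline and, because no raw
images or plate tables are publicly deposited for this kind of experiment,
ships generators that simulate both input types with full ground truth. All
conclusions the package draws are therefore about *method behaviour under a
known generative model*, not about real microscopy; the generators are
first-class, tested code.

## The imaging pipeline

1. **Masking.** The DNA (Hoechst) channel is thresholded by Otsu's method —
   exact exhaustive maximization of between-class variance over every
   boundary between consecutive distinct intensities — and foreground is
   strictly above the threshold. Connected components are 8-connected,
   interior holes are filled, components under 200 px or touching the image
   border are discarded, and labels are re-indexed in raster-scan order.
   All of these conventions are configurable (`label_nuclei()`).
2. **Texture descriptors.** Inside each nucleus the SC-35 channel is
   quantized to `G = 32` gray levels and gray-level co-occurrence matrices
   are accumulated at distance `d = 1` for the four canonical directions
   (0°, 45°, 90°, 135°), symmetrically, counting only pixel pairs that lie
   entirely inside the nucleus. From each GLCM the 13 classical Haralick
   descriptors f1–f13 are computed (f14, the maximal correlation
   coefficient, is excluded); per nucleus the pipeline keeps the
   per-descriptor mean over the four directions and the per-descriptor
   range (max − min; SD is available via `aggregation = "sd"`), giving the
   26-vector.
3. **Reduction.** Features are z-scored and reduced by PCA to the *minimal*
   number of components whose cumulative explained variance reaches 95%
   (`fit_pca()` asserts minimality: dropping the last retained component
   falls below the target).
4. **Classification.** A C4.5-style decision tree is grown on the scores:
   binary splits at midpoints between sorted distinct values, chosen by
   gain ratio, with at least 2 instances per branch; pessimistic-error
   subtree-replacement pruning at confidence factor 0.25. Quality is
   reported as a confusion matrix with per-class precision TP/(TP+FP) and
   recall TP/(TP+FN), their class-share-weighted means, and percent
   correctly classified — under stratified 10-fold cross-validation (the
   headline, with PCA and tree re-fit inside every training fold) and under
   resubstitution (for comparability with training-set evaluation).

### Numerical conventions

* Entropies use log base 2 with 0·log 0 := 0; correlation is defined as 0
  when a marginal SD vanishes; the sum-variance centre is the sum average;
  the second information measure of correlation clamps its radicand at 0.
* Gray levels are indexed 0..G−1 (so a constant image has sum average 0).
* Gain-ratio ties break to the lowest feature index, then the lowest
  threshold; a value exactly at a split threshold follows the ≤ (left)
  branch; leaf-majority ties break to the class earliest in training level
  order. The fit is therefore deterministic given the input order.
* The pessimistic error rate is the one-sided Clopper–Pearson upper
  confidence limit `qbeta(1 − CF, E + 1, N − E)` (for E = 0 this is
  1 − CF^(1/N)); a subtree collapses when the replacement leaf's pessimistic
  error count does not exceed the subtree's. Subtree *raising* is not
  implemented — replacement alone reproduces the intended
  overfitting-correction behaviour and keeps the procedure easy to verify.
* Missing feature values are rejected rather than fractionally propagated.

### Quantization: why the pipeline default is detector-referenced

Per-nucleus min–max quantization is the common Haralick convention and is
implemented (`strategy = "minmax"`, the default of the standalone
`haralick_profile()`; it makes the 26-vector invariant to positive affine
intensity rescaling). But under min–max the level scale of every nucleus is
set by its own brightest speckle — a noisy extreme statistic — and we
measured that this inflates within-class descriptor SD by roughly an order
of magnitude on generated panels, drowning the between-class structure the
panels are designed to carry. The *pipeline* therefore defaults to
`strategy = "global"` with the fixed range [0, 2.5] generator units
(`default_glcm_params()`): the synthetic detector's full scale, analogous to
quantizing raw camera units over the sensor's bit depth. With real images
one would supply the acquisition bit-depth range the same way.

## The image generator

Each nucleus is an ellipse (20–60% of a 512 px field, mild eccentricity,
random orientation). The DNA channel is a bright interior with gentle radial
falloff over a dim exterior — enough structure for threshold masking to be
well-posed, nothing more. The SC-35 channel is a diffuse nucleoplasmic
background plus a Poisson number of Gaussian speckle blobs; the expected
count refers to a nucleus at the reference area (35% of the field) and
scales with realized nuclear area, so speckle *density* is the class trait.
With probability `clustering_strength` a speckle is placed near an existing
one (Gaussian displacement, SD twice the blob radius), otherwise uniformly.
Per-blob amplitude and radius carry ~10% lognormal dispersion. The field is
convolved with a Gaussian PSF (σ = 1 px) and degraded with additive read
noise (SD 0.02), clipped at zero. Images are bit-reproducible in
(spec, size, seed); per-image seeds derive from the master seed, the class
*name* and the replicate index, so reordering classes permutes the dataset
without changing any image.

The class panels (`enhancer_panel_specs()`, `inhibitor_panel_specs()` with
1.5× parameter offsets, and the 7-class 72-hour panel with an
osteogenic-context baseline shift) differ pairwise in at least two generator
fields and are spaced so that mean Haralick contrast separates every class
pair by more than one within-class SD — the designed-in guarantee that makes
classification on these panels meaningful rather than accidental.

What the generator does **not** emulate: optical anisotropy and vendor
PSFs, crowded multi-nucleus fields, out-of-focus light, photobleaching,
3-D structure, or the biological heterogeneity of real drug responses.
Passing classification targets on these panels demonstrates that the
pipeline recovers class structure that GLCM statistics can carry; it does
not certify accuracy on real micrographs.

## The screen generator and statistics

Per condition, the generator draws `n = 6` wells per assay with
multiplicative lognormal noise of mean exactly 1 and coefficient of
variation `cv = 0.10` (plate-reader error grows with signal). Raw ALP scales
with per-cell activity × viable cell number; DNA scales with viable cell
number; so the per-well ALP/DNA ratio cancels viability and isolates the
per-cell fold — mirroring why the assay is DNA-normalized in practice. MTS
reflects viability at day 14 only (day 0 is pre-effect); AdipoRed scales
with the adipogenesis fold. At `cv = 0` every estimator returns its
configured truth exactly, which the tests assert.

Default effect tables encode the headline effect sizes of the screen being
emulated — top enhancer 3.5-fold, second-tier 2.5-fold, strongest inhibitor
45% inhibition, aged-donor top drug 5.9-fold — with day-14 viability
fractions in the 0.6–0.85 range for hit compounds.

* **Fold change** is the ratio of mean per-well normalized ALP (per-well
  ratio first, then mean — robust to well-count imbalance), with a
  2000-resample bootstrap percentile 95% CI under a fixed seed.
* **Dunnett test**: t statistics use the variance pooled across all k+1
  groups (classical assumption; no Welch fallback); the two-sided family
  adjustment integrates the k-variate t distribution with the design's
  product correlation structure (correlation ½ when balanced) by
  Genz–Bretz quasi-Monte-Carlo at absolute tolerance 1e-4 under a fixed
  internal seed, so p-values are reproducible; the adjusted p is clamped to
  be at least the unadjusted two-sample p. With k = 1 the procedure reduces
  to the pooled two-sample t test, and its family-wise error under a null
  simulation is checked against 5% in the test suite.
* **Hits**: enhancers are conditions with fold > 1 and adjusted p < α
  sorted by fold descending, inhibitors fold < 1 sorted ascending,
  alphabetical tie-break, truncated to top k.

## Problem sizes and reproducibility

The study-scale experiments use 100 nuclei per class at 512 px (600–700
nuclei per panel; dataset seeds 11/17/19, CV fold seed 13) and 500 replicate
plates for each screen recovery experiment — sizes at which the pipeline's
Monte-Carlo summaries are stable to well under the tolerances being
checked. `scripts/acceptance.R` recomputes every headline number from
scratch; `analysis/01–04` are the narrative drivers that write the same
tables under `results/`. Image datasets are regenerated from seeds rather
than stored; TIFF export exists for inspection and interoperability.

## Known limitations

* The texture generative model is deliberately minimal; descriptors beyond
  GLCM (wavelet, LBP, learned features) and multi-scale pyramids are out of
  scope.
* Touching nuclei are not split (no watershed); the generator places one
  nucleus per field.
* The C4.5 implementation handles numeric features only and rejects missing
  values.
* The percentile bootstrap CI on the fold change undercovers at the
  default n = 6 wells per group (small-sample bootstrap behaviour; the
  coverage experiment in `analysis/04_parameter_recovery.R` quantifies it) —
  the point estimate is unbiased, but the interval should be read as
  approximate at screen-typical replication.
* Dunnett assumes homoscedastic groups; under strong effect-size spread
  with multiplicative noise this is conservative for the control-adjacent
  comparisons (group SDs grow with means), which is acceptable here because
  power at the simulated effect sizes is essentially 1.
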