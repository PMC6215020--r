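# speckletex

Single-cell phenotyping of nuclear speckle (SC-35) organization, and the
statistics of an epigenetic drug screen of osteogenic differentiation — as a
tested R package exercised end to end on synthetic data with known ground
truth.

## The problem

Nuclear speckles, marked by the splicing factor SC-35, reorganize when a
cell's nucleosomal state changes. In high-content imaging this makes SC-35
texture a single-cell surrogate readout of epigenetic state: human
mesenchymal stem cells pretreated with different nucleosome-modifying drugs
can be told apart purely from the spatial organization of SC-35 inside the
nucleus. The companion assay arm quantifies what those drugs do to
osteogenic differentiation: alkaline phosphatase (ALP) activity normalized
to DNA content, fold change versus the untreated osteogenic control,
viability, adipogenesis, and Dunnett many-to-one testing to call hits.

`speckletex` implements both arms:

* **Imaging arm** — Otsu nuclear masking from the DNA channel; gray-level
  co-occurrence matrices of the SC-35 channel (G = 32, d = 1, symmetric,
  four directions); the 26-descriptor Haralick profile per nucleus
  (13 directional means + 13 directional ranges of f1–f13); PCA reduction to
  the minimal components explaining 95% variance; a C4.5-style gain-ratio
  decision tree with pessimistic-error pruning (CF 0.25, min 2 per leaf);
  confusion matrix with per-class precision `TP/(TP+FP)`, recall
  `TP/(TP+FN)`, weighted averages and percent correct, under stratified
  10-fold cross-validation and resubstitution.
* **Screen arm** — per-well ALP/DNA normalization; fold change with
  bootstrap 95% CI; viability percentages from MTS; AdipoRed fold;
  two-sided Dunnett adjusted p-values from the multivariate-t family
  distribution; ranked enhancer/inhibitor hit lists.
* **Generators** — seeded simulators for class-structured two-channel
  nucleus images (Poisson speckle counts, clustered Gaussian blobs, PSF
  blur, read noise) and for multi-well screen plates (multiplicative
  lognormal measurement noise, viability-coupled DNA), with full ground
  truth for parameter-recovery experiments.

The methods vignette (`vignettes/methods.Rmd`) documents the model,
conventions and design choices in detail.

## Worked example

Classify the default 6-class enhancer panel (untreated + five drug analogs,
100 nuclei per class, 512 px fields):

```r
library(speckletex)
res <- run_imaging_pipeline(enhancer_panel_specs(), n_per_class = 100,
                            size_px = 512, seed = 11, cv_k = 10, cv_seed = 13)
res$report_cv
#> <classification_report (stratified 10-fold CV): 95.5% correct, weighted precision 0.955, recall 0.955>
res$pca
#> <pca_model: 5/26 components retained, 96.51% variance (target 95%)>
```

Five principal components carry 95% of the variance of the 600 × 26 feature
matrix, and the pruned tree separates the six classes at 95.5% weighted
precision and recall under 10-fold CV — comfortably above the >80%
precision/sensitivity regime this kind of SC-35 phenotyping operates in.

Analyze a simulated enhancer screen:

```r
cfg <- enhancer_screen_effects()      # truth: gemcitabine 3.5x, decitabine 2.5x, ...
scr <- run_screen_pipeline(cfg$effects, cfg$controls, seed = 101)
scr$hits$enhancers$condition[1]
#> [1] "gemcitabine"
```

The estimated fold changes recover the configured truths (the generator's
DNA channel tracks viable cell number, so ALP/DNA normalization cancels
viability), and gemcitabine tops the hit list with Dunnett adjusted
p < 0.01.

The numbered drivers under `analysis/` run the full study: `01` simulates
and archives sample images, `02` runs the three classification panels,
`03` analyzes the three screens, `04` checks estimator bias and CI coverage.
Outputs land under `results/`.

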