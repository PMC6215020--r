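Package: speckletex
Title: SC-35 Nuclear Speckle Texture Phenotyping and Epigenetic Drug Screen Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Single-cell phenotyping of nuclear speckle (SC-35) organization from
    two-channel fluorescence images: intensity-based nuclear masking, gray-level
    co-occurrence (Haralick) texture descriptors (13 directional means and 13
    directional ranges), PCA reduction to the minimal components explaining a
    target variance fraction, and a C4.5-style gain-ratio decision tree with
    pessimistic-error pruning, evaluated by confusion matrices, per-class
    precision and recall. Also quantifies epigenetic small-molecule screens of
    osteogenic differentiation: DNA-normalized alkaline phosphatase activity,
    fold change versus control with bootstrap confidence intervals, viability
    percentages, adipogenesis readouts, Dunnett many-to-one testing and ranked
    hit lists. Ships seeded synthetic generators for class-structured nuclear
    images and multi-well screen plates with full ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    EBImage,
    mvtnorm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    foreign,
    multcomp,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
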