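Package: shscontext
Title: Contextual Joint Detection and Damage Classification for Hand Radiographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for automatic radiographic scoring of rheumatoid arthritis
    hand images. Detects the modified Sharp/van der Heijde target joints (16
    erosion, 15 joint-space-narrowing sites per hand) by heatmap keypoint
    regression, crops scale-normalized joint windows, and classifies each
    joint as intact or non-intact with four architectures: an independent
    single-joint classifier and three contextual multi-input multi-output
    variants that jointly read the contralateral joint, the same-hand joint
    group, or the full bilateral joint group. Includes a synthetic
    hand-phantom generator with tunable bilateral and within-group label
    correlation so every stage is trainable and testable without clinical
    data, plus patient-disjoint cross-validation and precision-recall
    evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
SystemRequirements: C++17
RoxygenNote: 7.3.3
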