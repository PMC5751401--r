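Package: targetfisher
Title: Ligand-Based Target Fishing with a Random-Forest QSAR Panel
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds one random-forest structure-activity model per protein
    target from a bioactivity table, screens query ligands against the whole
    panel with a unified forest-vote score, and ranks candidate targets.
    Includes ECFP-style circular fingerprints and Tanimoto similarity on top
    of OpenBabel, class-imbalance handling by negative undersampling or
    weight-based positive oversampling, Tanimoto exclusion of ambiguous
    putative inactives, a five-fold cross-validation harness with per-target
    ROC/AUC, mean-score ratios and recall at top-k target ranks, sigmoid
    calibration of scores to interaction probabilities, and a synthetic
    chemogenomics data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ChemmineOB,
    ranger,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
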