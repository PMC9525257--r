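Package: molstack
Title: Stacked Ensemble Classification of Bioactive Molecules from SMILES
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains a stacked ensemble for binary bioactivity classification
    (e.g. progesterone-receptor antagonist vs inactive) from SMILES alone.
    Compound tables are curated by IC50 thresholding, featurized with twelve
    molecular fingerprint families, and fed to a 6 x 12 grid of baseline
    classifiers whose out-of-fold predicted confidences become probabilistic
    features. A genetic algorithm with a self-assessment report selects a
    small subset of those features and a random-forest meta-predictor makes
    the final call. Includes an evaluation suite (MCC, F-value, sensitivity,
    specificity, accuracy, ROC AUC), synthetic planted-signal benchmarks, and
    a command-line workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    class,
    e1071,
    glmnet,
    igraph,
    jsonlite,
    mixOmics,
    ranger,
    stats,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
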