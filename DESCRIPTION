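Package: crowsae
Title: Crow Search Feature Selection and Sparse Autoencoder Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for wrapper feature selection and classification of
    imbalanced clinical tabular data, built around three components: an
    oppositional binary crow search algorithm for feature-subset search, a
    sparse stacked autoencoder classifier trained by greedy layer-wise
    pretraining and backpropagation fine-tuning, and an equilibrium
    optimizer for cross-validated hyperparameter tuning. Includes a
    synthetic generator for postpartum-hemorrhage-like cohorts with planted
    informative features, stratified splitting and cross-validation folds,
    confusion-matrix metrics (precision, recall, accuracy, F-score,
    Matthews correlation, error rate) with ROC/AUC, and an end-to-end
    pipeline with multi-run aggregation and JSON reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
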