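Package: cpmr
Title: Connectome-Based Predictive Modeling of Behavior from Functional
    Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements connectome-based predictive modeling (CPM) for
    continuous behavioral outcomes from resting-state functional
    connectivity: Fisher-z edge construction from node time series,
    correlation-based edge selection with optional partial-correlation
    confound control, positive/negative network strength models,
    leave-one-out and repeated k-fold cross-validation, permutation
    inference, contributing-network characterization (node strength,
    macroscale-region edge counts, cross-outcome network comparison),
    external-sample generalization with averaged fold models, behavioral
    preprocessing (motion exclusion, pluggable imputation, a
    principal-component negative-emotion composite), and a synthetic-data
    generator with known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
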