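Package: fleaselect
Title: Flea Optimization Algorithm with LASSO for Deep-Feature Selection
Version: 0.1.0
Authors@R: person("fleaselect", "maintainers", email = "maintainers@fleaselect.dev",
    role = c("aut", "cre"))
Description: Population-based feature selection for deep-image-feature vectors.
    Implements the Flea Optimization Algorithm (FOA), a metaheuristic that
    searches over feature-selection vectors scored by an L1-penalized
    least-squares (LASSO) objective solved by cyclic coordinate descent,
    together with a seeded synthetic deep-feature generator, image
    augmentation operators, intra-/inter-class dissimilarity statistics,
    a full confusion-matrix performance-metric suite (MCC, Cohen's kappa,
    one-sample t-test, confidence intervals), a constructive layer-graph
    model of standard and slimmed ResNet-50 inventories with parameter
    counting, and an end-to-end before/after-selection evaluation pipeline
    with a classifier bank and command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    png,
    yaml
Config/testthat/edition: 3
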