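Package: multsens
Title: Multi-Learning Treatment-Sensitivity Prediction and Counterfactual
    Treatment Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A multi-stage machine-learning pipeline that predicts
    per-patient, per-treatment sensitivity in multiple myeloma from
    clinical markers, bulk gene expression and first-line treatment, and
    simulates which treatment maximizes each patient's predicted
    sensitivity.  Stages: Kolmogorov-Smirnov marker selection with
    correlation-redundancy pruning; silhouette-guided selection of the
    number of k-means clusters for genetic profiling and gene clustering;
    a denoising autoencoder for gene-expression feature extraction;
    Gaussian-process Bayesian hyperparameter optimization of a
    gradient-boosted-tree ensemble; survival-guided derivation of the
    binary sensitivity outcome from ordered response classes; a
    class-and-treatment-equalized cross-validation harness; and
    counterfactual treatment simulation.  Includes a simplified baseline
    pipeline and a synthetic cohort generator with planted ground truth
    so every stage is testable without access to restricted patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    dplyr,
    e1071,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    nnet,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
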