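Package: navlearn
Title: Bayesian State-Space Modelling of Spatial Learning Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates hidden block-wise learning states from noisy angular
    pointing errors in spatial-navigation experiments using a hierarchical
    Bayesian state-space model (log-normal observations around a latent
    random-walk state, with trial-level effects shrunk toward the block
    state), fitted per subject by MCMC. Includes posterior predictive
    checks, Pareto-smoothed importance-sampling leave-one-out (PSIS-LOO)
    comparison against a trial-wise alternative model, derived learning
    metrics (learning curves, per-block amount of learning, fMRI contrast
    weights, last-minus-first difference-distribution features), K-means
    learner subtyping with silhouette-based selection of the number of
    clusters, logistic-regression classification of age group from two
    behavioral features, circular statistics (Watson-Williams tests) for
    signed pointing-error biases, and a synthetic cohort generator that
    emulates the trial schedules of a behavioral and an fMRI experiment
    with five learner archetypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    rjags,
    coda,
    cluster,
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
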