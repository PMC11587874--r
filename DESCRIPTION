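Package: enmdyn
Title: Presence-Only Niche Modeling, Area Dynamics and Niche Differentiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for presence-only climatic niche modeling of
    widespread species and for comparing climatic niches between species.
    Implements spatial thinning of occurrence records, kernel-density
    sampling-bias surfaces, a penalized maximum-entropy (MaxEnt-style)
    presence-background model with L/Q/H/P/T feature classes and AICc-based
    tuning over feature classes and regularization multipliers, replicate-based
    evaluation (AUC, omission rates, partial ROC), threshold-based suitable-area
    dynamics across climate periods and regions with exact spherical cell areas,
    and niche differentiation via PCA with broken-stick retention, ANOVA/Tukey
    tests, exhaustive condition-number/VIF variable selection, and
    cross-validated L2 logistic discrimination with linear Shapley attributions.
    A synthetic-data module generates correlated climate raster stacks and
    virtual species with known niches so the full pipeline is testable without
    external climate layers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    Rcpp,
    geosphere,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
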