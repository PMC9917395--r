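Package: ddtraj
Title: Group-Based Trajectory Modeling of Longitudinal D-Dimer in Trauma Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fits group-based trajectory models (GBTM) with a censored-normal
    (Tobit) observation model to longitudinal D-dimer measurements from trauma
    cohorts, using an EM algorithm with multi-start initialization. Implements
    the two-stage model-selection protocol of Nagin (BIC, relative entropy,
    group size, and average posterior probability of assignment), trajectory
    group assignment by highest posterior probability, and downstream
    association analysis of trajectory groups with in-hospital mortality
    (univariate screening, collinearity diagnostics, multivariable logistic
    regression, and ROC comparison against TRISS survival probabilities).
    Includes a synthetic trauma-cohort generator with latent-class trajectory
    structure, censoring, irregular sampling with informative stopping, and
    class-linked mortality, plus daily-maximum preprocessing, KNN imputation of
    Abbreviated Injury Scale scores, and deterministic trauma scores.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    survival,
    pROC,
    car
Config/testthat/edition: 3
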