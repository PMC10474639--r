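Package: ccwmsm
Title: Target Trial Emulation with Clone-Censor-Weight and Multi-State Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Emulates a target trial from observational hospital cohorts using
    the clone-censor-weight technique with a treatment-initiation grace period,
    estimates inverse-probability-of-artificial-censoring weights from
    arm-specific Cox models with a Breslow baseline, and summarises treatment
    effects with weighted multi-state estimators (Nelson-Aalen cumulative
    transition hazards and Aalen-Johansen transition probabilities over a
    five-state forward-only hospital model) and a weighted proportional-odds
    odds ratio on an ordinal severity scale with nonparametric bootstrap
    confidence intervals. Includes a discrete-time cohort simulator with
    covariate-dependent (confounded) treatment initiation and a Monte-Carlo
    state-occupation oracle for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    survival,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    cmprsk,
    withr,
    optparse,
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
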