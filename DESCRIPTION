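Package: spiroref
Title: Spirometric Reference Equations, GOLD Staging and Between-Equation Agreement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts forced expiratory volume in one second (FEV1), forced
    vital capacity (FVC) and the FEV1/FVC ratio for adults from three sets of
    reference equations: locally derived Greek piecewise-linear study
    equations, the 1993 European Coal and Steel Community (ECSC) linear
    equations, and a Global Lung function Initiative (GLI-2012) style
    lambda-mu-sigma (LMS) model with an age-indexed lookup. Stages chronic
    obstructive pulmonary disease (COPD) severity by GOLD percent-predicted
    criteria under any equation set and quantifies between-set agreement with
    percent agreement, unweighted and weighted Cohen's kappa, and Lin's
    concordance correlation coefficient. Includes piecewise-linear regression
    tooling to re-derive the study equations from cohort data, seeded
    synthetic healthy and COPD cohort generators, and a full
    simulate-fit-predict-stage-agree pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
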