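Package: trajnet
Title: Disease Trajectory Networks from Longitudinal Multimorbidity Cohorts
Version: 0.1.0
Authors@R:
    person("trajnet", "developers", email = "trajnet@example.org",
           role = c("aut", "cre"))
Description: Tools for temporal comorbidity analysis in longitudinal ageing
    cohorts such as CHARLS: cleaning of self-reported chronic-disease onset
    data, survey-weighted descriptives and age-scale Kaplan-Meier cumulative
    incidence, exact binomial tests of pairwise disease ordering,
    incidence-density matched nested case-control sampling with a
    conditional-logistic likelihood fitter and set-resampling bootstrap
    confidence intervals, assembly of directed disease trajectory networks,
    and ranking of linear three-disease trajectories.  Includes a
    discrete-time multistate cohort simulator with planted directional
    hazard dependencies so every stage of the pipeline can be validated
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    survival,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
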