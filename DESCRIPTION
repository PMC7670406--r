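Package: agenet
Title: Weighted Network Model of Health-Deficit Accumulation and Mortality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Stochastic simulation and likelihood-based inference for a
    weighted network model of human aging. Individuals carry N binary,
    irreversible health deficits whose damage rates depend on a weighted
    directed network of interactions plus an age-dependent background term;
    mortality is a separate hazard driven by a weighted deficit load. The
    package provides an exact event-driven simulator with time-dependent
    hazards, simulation-based maximum likelihood for right-censored
    cross-sectional cohorts (with missing-deficit marginalization), particle
    swarm optimization for parameter fitting, a validation battery (deficit
    prevalence forecasts, left-out-deficit imputation AUC, Kaplan-Meier
    comparisons, time-dependent concordance, censoring-weighted Brier
    scores), and synthetic-cohort generators emulating the structure of
    cross-sectional aging studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    survival,
    utils
LinkingTo: Rcpp
Suggests:
    Matrix,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
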