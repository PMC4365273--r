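Package: qsstmdd
Title: Population Pharmacokinetics of Antibody-Ligand Binding with a
    Quasi-Steady-State TMDD Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population pharmacokinetic analysis of a monoclonal
    antibody binding a soluble ligand, built around the quasi-steady-state
    (QSS) approximation of target-mediated drug disposition (TMDD).
    Provides a two-compartment linear disposition model and the QSS TMDD
    system with a compiled adaptive integrator, a nonlinear mixed-effects
    estimation engine based on a Laplace approximation of the marginal
    likelihood with interaction, stepwise covariate model building with a
    permutation-based significance calibration, prediction-corrected
    visual predictive checks and goodness-of-fit residuals, and a
    synthetic-cohort generator emulating a sparse oncology sampling
    design. All user-facing functions consume and return tidy data
    frames.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    jsonlite,
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
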