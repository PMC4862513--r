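Package: isavupk
Title: Population Pharmacokinetics of Isavuconazole in Hepatic Impairment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and estimation tools for the population
    pharmacokinetics of the triazole antifungal isavuconazole in subjects
    with mild or moderate hepatic impairment. Implements a two-compartment
    disposition model with zero-order intravenous infusion input and a
    Weibull-type oral absorption function; a hepatic-function covariate
    model mapping published fixed effects to individual parameters;
    Monte-Carlo simulation of steady-state trough concentrations under the
    clinical loading/maintenance regimen; non-compartmental analysis with
    terminal-slope selection and AUC extrapolation; and a two-stage
    estimation pipeline with stepwise covariate selection, nonparametric
    bootstrap confidence intervals and normalized prediction distribution
    errors. A synthetic-study generator emulates the two phase-1
    hepatic-impairment studies so every component is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    jsonlite,
    optparse,
    patchwork,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
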