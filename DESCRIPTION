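Package: cipropk
Title: Population and Individual Pharmacokinetics of Ciprofloxacin in
    Critically Ill Adults
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: One-compartment intravenous-infusion pharmacokinetics of
    ciprofloxacin with tools for the full analysis chain used in critical
    care dosing studies: synthetic cohort and concentration-time dataset
    simulation, MAP-Bayesian individual parameter estimation with
    two-stage covariate statistics, nonlinear mixed-effects population
    estimation (Laplace/FOCE-I type approximation) with creatinine
    clearance as a covariate on clearance, simulation-based model
    diagnostics (bootstrap, visual predictive checks, normalized
    prediction distribution errors), Monte Carlo probability of target
    attainment for the AUC24/MIC >= 125 target, and a creatinine
    clearance versus MIC dosing nomogram.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
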