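Package: dphpbpk
Title: Whole-Body Physiologically Based Pharmacokinetic Modeling of
    Diphenhydramine Across the Lifespan
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A whole-body physiologically based pharmacokinetic (PBPK)
    simulator for diphenhydramine, a weakly basic H1 antihistamine cleared
    by four hepatic cytochrome P450 enzymes (CYP2D6, CYP1A2, CYP2C9,
    CYP2C19) and, to a small extent, renally.  Builds age- and
    sex-parameterized virtual individuals from packaged literature-informed
    physiology tables, predicts tissue-to-plasma partition coefficients with
    the Rodgers-Rowland tissue-composition method, integrates a
    perfusion-limited multi-organ ODE system for intravenous bolus and oral
    dosing (linear 80%-dissolution formulation, first-order gastric
    transit, portal first pass), scales clearance to pediatrics via CYP
    ontogeny curves and microsomal-protein maturation, simulates seeded
    virtual populations with percentile summaries, performs
    non-compartmental analysis (Cmax, Tmax, AUC, lambda_z, clearance), and
    verifies predictions against observed summaries with predicted/observed
    ratios, average fold error, and a 2-fold acceptance screen.  Scenario
    tools compare exposure across WHO pediatric age bands, single-enzyme
    knockouts, chronic kidney disease stages, and Child-Pugh liver
    cirrhosis grades.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    ggplot2
Config/testthat/edition: 3
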