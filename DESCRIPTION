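Package: tilcea
Title: Cost-Effectiveness Modelling of TILs-Guided Chemotherapy
    De-Escalation in Early Triple-Negative Breast Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A hybrid decision-tree plus three-state Markov cohort model for
    evaluating whether tumor-infiltrating lymphocyte (TILs) testing to spare
    low-risk early triple-negative breast cancer patients from adjuvant
    chemotherapy is cost-effective.  Provides pseudo individual-patient-data
    reconstruction from digitized Kaplan-Meier curves with numbers at risk,
    parametric survival fitting and extrapolation with AIC/BIC model
    selection, time-dependent cycle transition probabilities, body-surface-
    area based regimen costing with vial rounding, incremental
    cost-effectiveness statistics (ICER, CER, net monetary benefit,
    dominance), one-way (tornado) sensitivity analysis, and probabilistic
    sensitivity analysis with cost-effectiveness acceptability curves.  A
    synthetic-data generator supplies survival data, digitized-curve
    fixtures and parametric life tables so the whole pipeline is testable
    without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    flexsurv,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
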