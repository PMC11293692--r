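Package: smarttriage
Title: Compare Sign-Based and Risk-Model Paediatric Emergency Triage Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing paediatric emergency-department triage
    systems: a rule engine for the WHO Emergency Triage Assessment and
    Treatment (ETAT) sign-based algorithm, a dual-threshold logistic
    risk classifier (Smart Triage) with independent emergency and
    priority triggers and intercept-only recalibration
    (recalibration-in-the-large), and an evaluation layer producing
    reclassification (Sankey flow) tables and dichotomized diagnostic
    statistics with Wilson score confidence intervals. Includes a
    synthetic paediatric cohort generator driven by a latent severity
    so every pipeline stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
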