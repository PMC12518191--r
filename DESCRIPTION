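Package: stpdosim
Title: Single-Time-Point Radioiodine Thyroid Dosimetry with Nonlinear
    Mixed-Effects Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Population biokinetic modelling of thyroidal iodine-131
    retention and single-time-point (STP) estimation of the
    time-integrated activity (TIA). Provides sum-of-exponentials
    retention models with closed-form TIAs, nonlinear mixed-effects
    population fitting with multi-start initialisation and
    empirical-Bayes individual estimates, STP and no-time-point TIA
    estimators, the closed-form EANM standard-operating-procedure
    estimators, accuracy metrics (relative deviation, RMSE, MAPE,
    exceedance counts, paired Wilcoxon tests), and a synthetic-cohort
    generator emulating a 73-patient clinical sampling design so the
    whole pipeline can be exercised and validated by simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    nlme,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
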