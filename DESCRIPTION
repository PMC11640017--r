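Package: hazardnet
Title: Discrete-Time Deep Survival Models with Time-Varying Covariates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Discrete-time survival analysis with neural-network hazard
    models for longitudinal claims-style cohorts. Provides a calibrated
    synthetic cohort generator for elderly stage IV breast cancer
    populations (monthly visit grid, treatment and adverse-event flags,
    drifting comorbidity index, administrative right-censoring), a
    covariate-extension step that summarizes each patient's treatment and
    adverse-event history up to a landmark time, four survival objectives
    (Cox partial likelihood with a feed-forward risk score, the DeepHit
    likelihood/ranking mixture, the discrete logistic-hazard model, and a
    time-dependent Cox score with sampled risk sets), time-dependent
    evaluation metrics (Antolini's concordance index and the IPCW
    integrated Brier score), and a cross-validated experiment runner that
    contrasts time-fixed against extended covariate sets.
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
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
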