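Package: pcnlblood
Title: Perioperative Blood-Loss Estimation and Transfusion Audit for
    Percutaneous Nephrolithotomy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hematocrit-based accounting of perioperative blood loss for
    percutaneous nephrolithotomy (PCNL) cohorts.  Implements the red-cell-mass
    chain from anthropometrics (body surface area, sex-specific estimated
    blood volume) and the pre-operative to 72-hour post-operative hematocrit
    shift to a hemodilution-corrected total blood loss; audits transfusion
    practice (cross-match-to-transfusion ratio, transfusion pattern,
    under/over-transfusion classification); screens candidate predictors of
    blood loss with Pearson/Spearman correlations and fits a p-value-driven
    stepwise linear model alongside a fixed published predictor; and
    generates synthetic cohorts with matched marginal statistics so the
    whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
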