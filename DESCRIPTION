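Package: iitriage
Title: Risk Triaging for Interruption in HIV Treatment from Longitudinal Clinic Visit Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to label interruption-in-treatment (IIT) outcomes from
    longitudinal HIV clinic visit records, engineer visit-history predictor
    features, train an imbalance-corrected boosting classifier that scores
    each visit for the risk that the next scheduled visit is missed, triage
    scored visits into low/moderate/high risk bins by score percentile,
    segment clients into rule-based demographic, behavioral and
    socio-behavioral archetypes, and estimate crude relative risks with
    log-method confidence intervals. Includes a synthetic electronic medical
    record generator that emulates visit schedules, lateness behavior,
    covariate-linked disengagement risk and re-engagement dynamics, so the
    whole pipeline is testable without access to restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lubridate,
    pROC,
    purrr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    xgboost
Config/testthat/edition: 3
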