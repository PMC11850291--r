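Package: rtlsfall
Title: In-Hospital Fall-Risk Modelling from Real-Time Location System
    Movement Features and Clinical Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Engineers patient-movement features from event-triggered
    real-time location system (RTLS) streams (haversine segment physics,
    daily movement metrics, velocity-threshold activity ratios, temporal
    aggregation), combines them with clinical covariates, trains
    gradient-boosted in-hospital fall-risk classifiers (clinical-only,
    RTLS-only, combined), and evaluates them with paired bootstrap metric
    comparison, decision-curve analysis, DeLong tests and subgroup
    statistics. Includes a synthetic inpatient cohort generator with
    configurable group contrasts so the full pipeline is testable without
    access to protected hospital data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    geosphere,
    jsonlite,
    stats,
    utils,
    xgboost,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
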