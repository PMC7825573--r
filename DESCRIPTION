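Package: dvhtox
Title: Dose-Volume Histogram Reduction and Logistic NTCP Modelling of
    Late Bladder Toxicity
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling late genitourinary toxicity after prostate
    radiotherapy from bladder dose-volume histograms (DVHs). Implements
    cumulative/differential DVH handling with per-patient interpolation,
    generalized equivalent uniform dose (gEUD) reduction, a logistic
    NTCP dose-response parameterized by TD50 and gamma50 with
    maximum-likelihood fitting, an AIC-driven Vdose threshold scan,
    inversion of the fitted logistic risk model into dose-volume
    constraint tables, bootstrap internal validation with ROC AUC, and
    Hosmer-Lemeshow calibration. A seeded synthetic-cohort generator
    emulates the statistical structure of a 175-patient bladder DVH
    cohort so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
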