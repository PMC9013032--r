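Package: jscore
Title: Grouper-Independent Severity-of-Illness Scoring from ICD-10-CM Diagnoses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a severity-of-illness scoring system for inpatient
    encounters that does not depend on a proprietary DRG grouper. ICD-10-CM
    diagnosis codes are mapped to 18 body systems with 3-level CC/MCC ordinal
    indicators and to 30 Elixhauser comorbidity flags; admission features use
    only present-on-admission and POA-exempt codes. Logistic models with
    orthogonal polynomial contrasts predict high (SOI 3-4) versus low (SOI 1-2)
    severity, classification cutoffs are selected from ROC geometry, and the
    fitted probabilities (J_Score at discharge, J_Score_POA at admission)
    support benchmarking and clinical-documentation-improvement analytics.
    Includes a synthetic encounter generator with known ground truth and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
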