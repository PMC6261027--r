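Package: emrisk
Title: Early Disease Risk Assessment from Longitudinal Diagnosis Records
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Transforms longitudinal outpatient diagnosis records
    (ICD-9-CM coded claims) into a binary patient-disease matrix,
    discovers latent risk factors by non-negative matrix factorization
    with Frobenius-cost multiplicative updates, and assesses individual
    disease risk with a radial-basis-function support vector machine,
    evaluated by stratified k-fold cross-validation. Includes cohort
    construction with censoring at the first target-disease diagnosis,
    noise filtering for claims records, and a synthetic EMR generator
    with planted latent-factor structure for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    e1071,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
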