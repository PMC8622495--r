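Package: stliscreen
Title: Validation of a Screening Questionnaire for Sub-Threshold Lumbar Instability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for validating a 14-item lumbar-instability screening
    questionnaire against flexion-extension radiography in patients with
    chronic low back pain. Implements sagittal segment-kinematics measurement
    from vertebral landmark geometry, per-level threshold classification into
    normal, sub-threshold lumbar instability (STLI) and lumbar instability
    (LI) bands, questionnaire scoring, diagnostic-accuracy evaluation
    (sensitivity, specificity, likelihood ratios, ROC/AUC with
    Hanley-McNeil confidence intervals, cut-off selection), intra-rater
    reliability (ICC and standard error of measurement), reconstruction of
    per-group score distributions from published accuracy columns, and a
    seeded synthetic-cohort generator that emulates the study population so
    the full pipeline can be exercised without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
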