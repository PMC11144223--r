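Package: driven
Title: Sleep Apnea Event Detection and Apnea-Hypopnea Index Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects apnea and hypopnea events and sleep/awake state from
    home-measurable physiological channels (abdominal and thoracic
    respiratory effort, pulse oximetry, optionally airflow and
    ECG-derived R-R intervals), and estimates a patient's Apnea-Hypopnea
    Index (AHI) with the four AASM severity classes. The pipeline
    segments whole-night recordings into 30 s windows, extracts deep
    convolutional features per channel, stacks them with a
    gradient-boosted tree classifier, and maps the fraction of
    event-positive sleep windows to AHI through a calibrated weighted
    linear regression. Includes a synthetic polysomnography generator
    with planted ground truth, EDF and profusion-style XML readers and
    writers, Pan-Tompkins QRS detection, and the full evaluation-metric
    set (ROC/PR curves, macro F1 over severity classes).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    xml2,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
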