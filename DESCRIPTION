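Package: breathprint
Title: Electronic-Nose Exhaled-Breath Analysis for Recent Asthma Exacerbations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for electronic-nose (eNose) exhaled-breath
    analysis of recent asthma exacerbations: conditioning of raw
    sensor-maneuver traces (resonance removal, zero-phase Butterworth
    low-pass, linear detrending, cross-correlation ambient-air correction),
    extraction of the 13-variable breathprint (sensor peaks normalized to
    sensor 2 plus peak/breath-hold-trough ratios), a principal-component
    (Kaiser criterion) to linear-discriminant classifier with Mann-Whitney
    ROC/AUC, leave-one-out cross-validation, stratified bootstrap confidence
    intervals and projection of a held-out validation set through the
    training transform, together with cohort eligibility filtering, baseline
    characteristic tables with between-group tests, and sensitivity-subset
    reruns. A synthetic-data module generates breath maneuvers and cohort
    tables with the multicollinear, class-shifted structure the analysis
    assumes, calibrated to a target AUC, so the whole pipeline is testable
    without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    MASS,
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
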