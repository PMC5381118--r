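Package: oxydyn
Title: Oxygen Uptake Prediction and Aerobic Dynamics from Wearable Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts breath-by-breath oxygen uptake (VO2) from wearable-sensor
    channels (heart rate, minute ventilation, breathing frequency, hip
    acceleration, walking cadence) with a from-scratch bagged regression-tree
    forest validated by leave-one-participant-out cross-validation, and
    characterises aerobic system temporal dynamics with a pseudorandom ternary
    sequence (PRTS) walking protocol and the mean normalized gain (MNG)
    frequency-domain statistic. Includes a seeded synthetic-cohort simulator
    with first-order cardiorespiratory kinetics so the full pipeline can be
    exercised and verified against closed-form oracles, plus agreement
    statistics (Pearson correlation, Bland-Altman, paired bias t-test) and
    metabolic-equivalent intensity clustering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
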