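Package: polycss
Title: Computerized Scoring of Comparison-Question-Test Polygraph Charts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A computerized scoring system (CSS) for comparison-question-test
    (CQT) polygraph examinations. Annotated five-channel physiological
    recordings (photoplethysmogram, blood pressure, thoracic and abdominal
    respiration, skin conductance; 40 Hz) are segmented around paired
    comparison/relevant questions, joined with an offset that removes the
    boundary discontinuity, and classified by a five-branch one-dimensional
    convolutional network feeding a single LSTM layer and a fully connected
    head, trained end to end with Adam on a softmax cross-entropy cost. Nine
    question-set deception probabilities per examination series are summed
    into a 0-9 score and mapped to a deception / non-deception / inconclusive
    decision through thresholds derived from the Utah numerical scoring
    scale. Includes a synthetic session generator emulating event-locked
    sympathetic-arousal responses, a grouped/stratified 10-fold
    cross-validation harness, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
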