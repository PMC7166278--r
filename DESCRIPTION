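Package: eegcnn
Title: One-Dimensional Convolutional Neural Networks for Epileptic Seizure
    Detection from EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection of epileptic seizure activity in single-channel EEG
    recordings with a one-dimensional convolutional neural network built from
    three Conv-BatchNorm-ReLU-Dropout-MaxPool blocks and three fully connected
    layers. Provides readers and writers for the Bonn University EEG text
    format and its chunked 178-sample tabular redistribution, a seeded
    synthetic five-class EEG generator, the M1-M8 model configuration
    registry with exact layer-shape arithmetic, an Adam/cross-entropy
    training harness, stratified 10-fold cross-validation over the 20
    standard set-combination tasks, and macro-averaged one-vs-rest
    confusion-matrix metrics (accuracy, precision, sensitivity, specificity,
    F1).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp
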