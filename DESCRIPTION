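Package: locomode
Title: Locomotion-Mode Recognition from Wearable EMG and Exoskeleton Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for recognising five locomotion modes (level walking, stair
    ascent/descent, ramp ascent/descent) from multichannel surface-EMG and
    hip-exoskeleton encoder/IMU time series. Provides min-max signal
    normalisation with train-split statistics, overlapping sliding-window
    segmentation with subject-grouped train/validation/test partitioning, a
    seeded synthetic gait-signal simulator for end-to-end testing, a
    constrained single- and multi-head 1-D convolutional network family with
    exact parameter accounting, reimplementations of three benchmark
    architectures, tree-structured Parzen estimator structural search, a
    plateau learning-rate training protocol with best-validation-loss
    checkpointing, and macro precision/recall/F-measure reporting from
    confusion matrices. The neural-network engine (convolution, batch
    normalisation, pooling, LSTM, dense layers, Adam) is implemented in base R
    on matrix operations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    nnet
Config/testthat/edition: 3
RoxygenNote: 7.3.3
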