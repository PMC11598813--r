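Package: bitbeat
Title: Binarized Depthwise-Separable Convolutional Networks for ECG Beat
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reference implementation of a binarized depthwise-separable
    convolutional neural network (bDSCNN) for five-class (AAMI N/S/V/F/Q)
    electrocardiogram beat classification, together with the hardware-oriented
    inference algebra that makes such models deployable on tiny devices:
    merged convolution-pooling (MCP) kernels built by OR-combining shifted
    copies of a binary kernel, blockwise incremental inference with analytic
    latency and storage models, and batch-normalization folding into
    integer comparator thresholds plus a lookup table for the output layer,
    giving a bit-exact integer-only inference twin of the floating-point
    reference network. Includes a seeded synthetic ECG beat generator with
    class-dependent P-QRS-T morphology, beat segmentation and binarized
    imaging, z-score class balancing, dataset splitting, straight-through
    estimator training, and confusion-matrix metrics (sensitivity, positive
    predictive value, specificity, per-class accuracy, F1 and macro-F1).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
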