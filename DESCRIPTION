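Package: protclass
Title: Imbalance-Aware Multi-Label Classification Tools for Fluorescence
    Microscopy Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-class, multi-label protein localization
    classification on four-channel (RGBY) fluorescence microscopy images
    with severe long-tail label imbalance. Implements effective-number
    class weighting (E-loss), batch-level hard example mining,
    adaptive concatenate pooling (ACP) with buffering-layer classifier
    heads and four-channel input adaptation, learning-rate finding with
    discriminative and cyclic cosine-annealed schedules, greedy per-class
    decision-threshold optimization for macro-F1, prediction ensembling,
    and a data pipeline with perceptual-hash deduplication, minority
    oversampling and multi-label stratified splitting. Ships a synthetic
    long-tail RGBY image generator and a compact trainable four-channel
    convolutional network so the full workflow runs end-to-end without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    png,
    tiff,
    withr,
    EBImage,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
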