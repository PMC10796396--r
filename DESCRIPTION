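Package: intakefuse
Title: Integrated Image- and Sensor-Based Detection of Eating Episodes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Detects eating episodes from wearable-device data by fusing two
    modalities: chewing signatures in 128 Hz tri-axial accelerometry, rendered
    as Morse-wavelet scalogram images and classified by a compact convolutional
    neural network, and per-image food/beverage detector confidence scores.
    Per-segment scores are fused with a cost-sensitive random forest over
    temporally lagged predictor vectors, segment decisions are aggregated into
    eating events and episodes (merging events separated by less than 15
    minutes), and the full evaluation suite is provided: segment and episode
    sensitivity/precision/F1, McNemar's paired test, IoU-based average
    precision and mAP over IoU thresholds 0.50-0.95, and leave-one-subject-out
    and holdout split utilities. A seeded synthetic-data generator emulates
    chewing-band accelerometer bursts, detector score streams and bounding-box
    fixtures so the whole pipeline is exercisable end to end without study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    randomForest,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
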