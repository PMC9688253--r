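Package: jellyfuse
Title: Optimized Weighted Deep-Feature Fusion with Jellyfish Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Wrapper-style feature selection for multi-extractor ("multi-view")
    deep feature matrices, as used in skin-lesion image classification. Block-level
    (MOWFS) or per-feature (FOWFS) fusion weights are tuned by an artificial
    jellyfish search optimizer (with genetic-algorithm and particle-swarm
    baselines) against a classifier mean-squared-error cost; features whose
    optimized weight exceeds 0.5 form the highest-ranked feature set. Includes
    plain concatenation (CFS) and adaptive weighting (AWFS) baselines, a
    classifier evaluation harness with macro-averaged multiclass metrics and
    one-vs-rest AUC, a Friedman rank-sum comparison, a synthetic multi-view
    data generator with known ground truth, and fused-versus-ranked accuracy
    delta reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    rpart,
    nnet,
    pROC,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    png,
    yaml
Config/testthat/edition: 3
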