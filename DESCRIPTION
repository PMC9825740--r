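Package: nanoal
Title: Active Learning for Nanopore Ionic-Current Event Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pool-based active learning for classifying nanopore ionic-current
    events. Provides uncertainty-based query strategies (least confident,
    margin, entropy), query-by-committee with vote entropy, density-weighted
    sampling, and a nanopore-specific bias-constraint reweighting of the
    unlabeled pool that downweights hard-to-label noise sequences. Includes a
    geometric stopping evaluator based on the distance of newly queried points
    from the embedded training set, SavedRate accounting of labeling cost, an
    11-statistic per-event feature extractor, trace segmentation and
    fixed-length Gaussian-noise padding, and a synthetic nanopore signal
    simulator (multi-class blockade events, heterogeneous noise events and
    3-bit barcode peak trains) so the whole pipeline is testable end to end
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    randomForest,
    pROC,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
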