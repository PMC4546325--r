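Package: myxotrack
Title: Single-Cell Reversal Analysis for Bacterial Gliding Motility Movies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Segmentation, tracking and reversal-event analysis for time-lapse
    movies of rod-shaped bacteria such as Myxococcus xanthus moving by
    run-and-reverse motility. Detects cells by thresholding the transmitted
    channel after drift stabilization, links detections frame-to-frame by a
    nearest-object rule, calls directional changes from the turn angle at each
    trajectory vertex, and discriminates genuine reversals from stick-slip
    motions by coincident pole-to-pole switches of a polarity reporter
    (e.g. FrzS-YFP) measured at the cell poles. Includes a ground-truthed
    synthetic movie generator for benchmarking, event-level precision/recall
    validation, and the group statistics used in single-cell motility studies
    (percentile summaries, sample-size-conditional Wilcoxon/t tests,
    dose-response tabulation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
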