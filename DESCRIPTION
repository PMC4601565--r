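Package: mfss
Title: Multidimensional Feature Subset Selection
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Filter feature selection for multidimensional (multi-label /
    multi-target) datasets. Ranks features by per-class Pearson feature-class
    correlation, aggregates the per-class rank weights into a single overall
    weight per feature, and selects the top s = round(log2(l)) features as one
    shared subset for all class variables. Includes readers for multi-label
    ARFF dialects and delimited tables, a synthetic-data generator with
    planted feature-class structure, multi-label evaluation metrics (Hamming
    score/loss, exact match, zero-one loss, example-based precision/recall/F1),
    a problem-transformation benchmarking harness, and statistical validation
    of before/after-selection metric vectors (Pearson correlation with Evans
    strength categories and the paired t-test).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    xml2,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
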