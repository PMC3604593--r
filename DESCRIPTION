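Package: cdclassify
Title: Classification of Differentially Expressed Genes in Principal
    Component Space
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Identifies genes that are differentially expressed between two
    biological conditions by classifying them in a principal-component space.
    Each condition is represented by a direction (the mean of its replicates'
    correlation-circle coordinates) and every gene receives a signed closeness
    value, the cosine of the angle between its factorial-map position and that
    direction, after a norm-quartile filter removes genes near the origin.
    Includes a minimal discriminant analysis on principal components (DAPC:
    k-means grouping followed by linear discriminant reassignment), four
    combined classification strategies, two-regime scenario simulators for
    benchmarking (progressive confusion of gene groups or of condition
    replicates), and an empirical false-discovery-rate threshold-sweep
    evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    cluster
Config/testthat/edition: 3
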