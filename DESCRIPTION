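Package: megnet
Title: Band-Wise MEG Source-Space Correlation Networks and Graph Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A resting-state magnetoencephalography (MEG) functional-connectivity
    pipeline for source-level ("virtual sensor") recordings. Implements
    amplitude-based artifact exclusion, notch filtering, decomposition into the
    seven canonical frequency bands (delta through fast ripple), selection of a
    60 s spike-free analysis segment, Pearson correlation networks thresholded
    by a t-type statistic at p < .01, weighted graph-theory metrics (strength,
    degree, characteristic path length with inverse-weight edge lengths,
    geometric-mean clustering coefficient), group statistics with Bonferroni
    correction, logistic-regression/ROC discrimination of a cognitively
    impaired subgroup, and a synthetic multi-band recording generator with
    planted coupling structure for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
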