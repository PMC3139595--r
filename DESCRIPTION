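Package: trtnet
Title: Test-Retest Reliability of Graph Metrics of Functional Brain Networks
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A pipeline for assessing the test-retest (TRT) reliability of
    graph-theoretical metrics of resting-state functional brain networks.
    Builds Pearson connectivity matrices from ROI time series (nuisance
    regression, band-pass filtering, Fisher-z utilities), thresholds them
    into binarized or weighted networks at exact sparsity levels under
    positive-only or absolute-value edge membership, computes 12 global and
    6 nodal network metrics (including small-world normalization against
    degree-preserving surrogates and modularity-based participation),
    quantifies reliability with one-way random-effects intraclass
    correlation (ICC) summarized by the area under the metric-sparsity
    curve, and runs a connectivity-noise robustness simulation. Includes a
    synthetic multi-subject, multi-scan cohort generator with an
    analytically known between-/within-subject variance decomposition, so
    ICC recovery is testable end-to-end without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    signal,
    MASS,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
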