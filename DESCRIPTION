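Package: caensembles
Title: Neuronal Ensemble Extraction and Cross-Session Reactivation from
    Calcium Imaging Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies reactivation of hippocampal neuronal ensembles across
    recording sessions from calcium-imaging fluorescence traces. Provides
    trace preprocessing (delta-F-over-F, transient event detection, zero-phase
    high-pass filtering, z-scoring with rectification, temporal binning),
    neuronal ensemble extraction by multi-restart non-negative matrix
    factorization with AICc model-order selection, cosine-similarity pattern
    matching across sessions with a matching-score statistic, a three-session
    reactivation analysis, and a synthetic-data generator that plants
    ground-truth ensembles with controllable cross-session sharing for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    grDevices,
    graphics,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    arrow,
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
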