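Package: ehrmatch
Title: Similar-Patient Retrieval and Future Concept Prediction for Longitudinal Health Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Represents longitudinal electronic health records as ordered census
    events of medical-ontology concepts, retrieves records whose time-based
    prefixes are similar under ontology-aware set dissimilarity measures
    (bag-of-concepts, weighted common ancestors, and average minimum path
    length over an ISA hierarchy accelerated by Dewey encodings), and predicts
    future concepts from the retrieved suffixes by confidence thresholding.
    Includes confusion accounting in all/fresh modes, grid tuning of the
    dissimilarity and confidence thresholds, semantic-group-stratified
    evaluation, and a calibrated synthetic-cohort simulator with planted
    prefix-to-suffix associations for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
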