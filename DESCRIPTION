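Package: drugspace
Title: Metric-Space Protein Representations for Druggability Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Embeds protein chains into four biologically informed metric
    spaces (sliding-window Kyte-Doolittle hydropathy, post-translational
    modification density, dynamic-time-warping alignment of PTM site
    positions, and secondary-structure composition) and classifies chain
    druggability with a k-nearest-neighbour majority-voting ensemble over
    the resulting distance matrices. Includes disassembly of multi-chain
    complexes with L1 k-means labelling and rule-based label correction,
    PseAAC-variant and gapped-dipeptide baseline featurizers, a
    leave-one-out cross-validation and permutation-testing evaluation
    stack with neighbour-quality diagnostics, and a synthetic dataset
    generator emulating the statistical structure of curated
    drug-binding chain collections.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
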