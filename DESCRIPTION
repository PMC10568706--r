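Package: moltree
Title: Fragment-Based Molecular Optimization by Monte Carlo Tree Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Lead optimization of small molecules by a two-level Monte Carlo
    tree search over molecular graphs. An outer search edits a starting
    molecule fragment by fragment (removing substituents at acyclic single
    bonds, grafting new ones), while an inner search grows each new fragment
    atom by atom, guided by a graph-convolutional generator trained on a
    fragment corpus obtained by cutting all ring/non-ring bonds of a
    molecule collection. Ships built-in evaluation functions (QED,
    penalized logP, similarity-constrained variants), generation-quality
    metrics (validity, novelty, uniqueness, similarity), and a procedural
    drug-like fixture corpus so the full pipeline runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    igraph,
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    withr,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
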