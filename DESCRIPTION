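Package: delphisim
Title: Consensus Indices and Clustered-Convergence Simulation for Delphi Panels
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes nine multi-rater consensus indices (De Moivre unanimity,
    pairwise agreement and its clustered and extremities variants, Fleiss' and
    Conger's kappa, mode, clustered mode, and the interquartile range) on
    expert-by-question ordinal rating matrices, and simulates classic
    three-round Delphi surveys in which experts converge between rounds toward
    the mean of the nearest consensus cluster under a Group Conformity Index.
    Monte-Carlo sweeps quantify how each index depends on the number of survey
    questions, the panel size, and the conformity of the panel, summarised as
    rank-ordered dependency tables. A compiled core makes thousand-replicate
    sweeps fast; a pure-R reference path implements the identical model.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
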