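Package: boolmet
Title: Logical Modelling of Tumour Cell Invasion and Metastasis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and analysing Boolean (logical) models of
    signalling networks, centred on a 32-node model of the early steps of
    metastasis (epithelial-mesenchymal transition, invasion and migration).
    Provides a rule-file parser, exact stable-state enumeration by
    branch-and-propagate constraint solving, continuous-time Markov
    (Gillespie) simulation of the asynchronous dynamics to estimate
    phenotype probabilities under gain- and loss-of-function clamps, a
    systematic single/double-mutant epistasis screen with genetic
    interaction network export, an operator-swap robustness census,
    matching of binarized expression time courses to logical stable states
    (EBP scoring), PCA-based pathway module activity scoring with
    differential-activity testing, and synthetic-data generators that
    emulate EMT-induction time courses and two-group tumour cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    igraph,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
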