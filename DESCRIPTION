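Package: moranfix
Title: Exact Fixation Probabilities for Moran Dynamics on Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes exact fixation probabilities of a single mutant under
    Birth-death (Bd) and death-Birth (dB) Moran dynamics on small graphs by
    solving the full 2^N-state absorbing Markov chain in canonical form, with
    sparse linear algebra. Provides closed-form references for well-mixed
    populations and cycles, structural short-circuits for disconnected and
    rooted directed graphs, a compiled Monte-Carlo simulator as an independent
    check, and an ensemble pipeline that samples Erdos-Renyi random graphs and
    classifies each as an amplifier or suppressor of selection relative to the
    update-rule-matched well-mixed reference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
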