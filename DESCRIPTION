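Package: hopclass
Title: Single-Sample Class Prediction from Gene Signatures with an
    Asymmetric Diluted Hopfield Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies individual transcriptomic samples into predefined
    classes using gene signatures stored as attractor templates of a
    Hopfield-like network. Class templates are written into a binary weight
    matrix by a modified Hebb rule, each sample's binarized expression state
    is evolved under asymmetric diluted dynamics (spins may switch from -1 to
    +1 but are eliminated instead of switching from +1 to -1) until it
    reaches a stored template, oversized signatures are capped at a cutoff
    and resampled with majority voting, and per-sample confidence is
    estimated from the network energy of the initial state via a permutation
    null with Benjamini-Hochberg false discovery rates. Also provides a
    storage-capacity simulator for the classical Hopfield model, the
    analytic error-free recall bound used to size the network, a seeded
    synthetic-cohort generator, and GMT/TSV readers and writers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
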