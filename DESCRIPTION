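Package: stemward
Title: Simulated Fossilization and Stemward Slippage in Morphological Phylogenetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how the taphonomic loss of soft-part (non-biomineralized)
    morphological characters distorts parsimony phylogenies. Provides partitioned
    character-matrix containers with NEXUS/TNT readers and writers, a curation
    protocol for compiled matrices, a compiled maximum-parsimony engine (Fitch
    optimization, random-addition stepwise searches with SPR/TBR branch swapping,
    exhaustive enumeration for small problems, strict consensus), pseudoextinction
    and random-deletion perturbation operators, the node-recovery and taxon-shift
    permutation tests with rank-based p-values, cross-dataset meta-statistics
    (binomial and log-likelihood-ratio G tests, dataset jackknife), and a
    synthetic-data generator that emulates compiled morphological matrices with
    tunable decay-biased signal.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
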