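Package: dlrs
Title: Bayesian Gene Tree Reconciliation Under the DLRS Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Probabilistic reconciliation of gene trees with a dated species
    tree under the DLRS model, which integrates gene duplication and loss
    (a linear birth-death process along the species tree), iid
    gamma-distributed substitution rates across gene tree edges (a relaxed
    molecular clock), and amino-acid sequence evolution. Provides dynamic
    programming over a discretized species tree for the gene tree generation
    probability, posterior sampling and maximum a posteriori computation of
    discretized realizations and reconciliations, the posterior probability
    of a fixed reconciliation, comparison of sampled reconciliations with the
    most parsimonious reconciliation via max and average atomary distances,
    Markov chain Monte Carlo inference of gene trees and model parameters
    from alignments, a generative simulator of gene families, and duplication
    heatmaps over the species tree.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
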