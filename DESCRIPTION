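Package: lingstab
Title: Phylogenetic Signal, Evolutionary Rate and Ancestral State
    Reconstruction for Binary Structural Traits
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Stability analysis of binary structural traits (for example
    grammatical features of languages) on phylogenies. Implements the
    Fritz-Purvis D statistic for phylogenetic signal with permutation and
    Brownian-threshold nulls, a two-rate-class hidden Markov (hidden rates)
    model of trait gain and loss with maximum-likelihood fitting via the
    pruning algorithm, marginal ancestral state reconstruction with the
    conditional-likelihood root treatment, a data-free constrained sampler
    of resolved ultrametric trees encoding classification constraints with
    uniform uncertainty over unresolved groupings, and the summary layer
    connecting signal, rate and reconstructability across feature
    categories. A synthetic-data generator produces taxonomies, trees and
    trait matrices with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    tools,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    phytools
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
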