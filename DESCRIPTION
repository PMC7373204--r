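Package: ndch
Title: Compositional Heterogeneity Diagnostics and Non-Stationary Bayesian Phylogenetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting and modelling among-lineage compositional
    heterogeneity in molecular phylogenetics. Implements matched-pairs tests of
    model-process homogeneity between aligned sequences (Bowker's test of
    symmetry, Stuart's test of marginal homogeneity, and Ababneh's internal
    test), codon-degenerate recoding of in-frame protein-coding nucleotide data
    to eliminate synonymous substitutions, a likelihood engine for
    tree-heterogeneous composition models (NDCH and NDCH2) with discrete-gamma
    rate variation, Bayesian MCMC inference over topologies, branch lengths,
    compositions and exchangeabilities with optional Metropolis coupling,
    posterior-predictive checking of compositional homogeneity via the
    chi-squared statistic, split-support summaries and convergence diagnostics,
    and a synthetic-data generator producing alignments with lineage-specific
    base composition and saturating synonymous variation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    Matrix,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
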