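Package: divclock
Title: Tree Prior and Molecular Clock Effects on Diversification Rate Estimates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A seeded simulation pipeline for studying how the choice of
    branching-process tree prior (Yule versus birth-death) and molecular
    clock (strict versus uncorrelated lognormal) affects likelihood-based
    estimates of diversification rates. Simulates ultrametric chronograms
    conditioned on tip count and crown age, assigns per-branch substitution
    rates under strict or relaxed clocks, simulates nucleotide alignments
    under GTR+Gamma, re-estimates clock-constrained dated trees by maximum
    and penalized likelihood, and fits constant-rate birth-death models to
    branching times, with lineage-through-time and comparison reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    phytools,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
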