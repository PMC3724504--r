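Package: combsim
Title: Simulation and Phylogenetic Analysis of Repeated Bacterial Symbiont Replacement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the phylogenetic signature of repeated
    replacement of insect endosymbionts by descendants of a slowly evolving
    environmental progenitor. Provides a discrete-time Monte Carlo simulator of
    a progenitor sequence spawning independently evolving descendant lineages
    (with optional co-speciation), stochastic calibration of simulation
    parameters against observed divergence summaries, neighbor-joining trees
    with nonparametric bootstrap and comb-topology statistics (mean bootstrap
    value, terminal/internal branch-length ratios), structure-aware
    classification of 16S rRNA substitutions into pairing-conservative and
    pairing-disruptive changes with Fisher's exact tests, Tajima relative-rate
    tests, Nei-Gojobori synonymous divergence, and calibration-based
    divergence-time extrapolation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
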