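Package: crossim
Title: Forward-in-Time Simulation of Genomic Selection for Crossbred Performance
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic forward-in-time simulation of a two-way crossbreeding
    program under genomic selection with dominance. Simulates a historical
    population, founds two pure breeds, samples a quantitative trait
    architecture with additive and (over-)dominant QTL scaled to target
    variance components, and runs multi-generation truncation selection on a
    weighted blend of genomic breeding values for purebred and crossbred
    performance. Marker effects are estimated by a Gibbs-sampled Bayesian
    ridge regression with separate additive and dominance effect classes.
    Includes true and genomic breeding values based on mate allele
    frequencies, heterosis decomposition of crossbred performance, QTL
    fixation summaries, selection accuracy, and the correlation of linkage
    disequilibrium phase between populations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
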