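Package: gcpop
Title: Population Genetics and Coalescent ABC Demographic Inference for
    Microsatellite and Mitochondrial Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Diversity and differentiation statistics for diploid
    microsatellite genotypes and aligned mitochondrial sequences
    (observed/expected heterozygosity, rarefied allelic and private
    allelic richness, Weir-Cockerham F-statistics, Jost's D, AMOVA
    Phi-ST, permutation tests with FDR correction), neutrality tests
    (Tajima's D, Fu's Fs) with coalescent-simulated null distributions,
    statistical-parsimony haplotype networks, and an approximate
    Bayesian computation (ABC) engine that simulates single-population
    piecewise-constant demographic scenarios under a generalized
    stepwise microsatellite mutation model and HKY85 sequence model,
    performs scenario choice by rejection and LDA-transformed logistic
    regression, and estimates bottleneck parameters with local-linear
    regression adjustment. Includes a synthetic-data generator with
    known demographic truth and an end-to-end analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    ape,
    MASS,
    nnet,
    igraph,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
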