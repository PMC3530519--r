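Package: msatdemog
Title: Microsatellite Bottleneck Detection and Coalescent Inference of
    Demographic History
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for inferring the demographic history of small, isolated
    vertebrate populations from diploid microsatellite genotypes. Reads and
    writes Genepop files with deme and sample-age metadata; computes standard
    diversity and differentiation statistics (unbiased expected
    heterozygosity, Weir-Cockerham F-statistics, allele-size based R_ST,
    rarefied allelic richness, exact tests of Hardy-Weinberg proportions,
    gametic disequilibrium and genic differentiation); implements three
    bottleneck detectors (heterozygosity excess against a simulated
    mutation-drift equilibrium, the allele-frequency mode-shift test, and the
    Garza-Williamson M-ratio with simulated critical values); and fits a
    coalescent-based Bayesian model of a single effective-population-size
    change (current size, ancestral size and time of change) by Markov chain
    Monte Carlo over latent genealogies under stepwise mutation. A built-in
    coalescent simulator of microsatellite data under two-phase mutation,
    population size change, island-model subdivision and serial (temporal)
    sampling provides equilibrium null distributions and synthetic study
    designs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    coda,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
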