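Package: srsfpr
Title: False-Positive Rates of Genetic Bottleneck Tests Under Sweepstakes
    Reproduction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward-in-time, individual-based simulation of demographically
    stable diploid populations with tunable variance in reproductive success
    (Vk), from Poisson family sizes (Vk = 2) to sweepstakes-like floored-gamma
    family sizes (Vk up to 2000).  Populations carry stepwise-mutation
    microsatellites (optionally with a constrained allelic range) or 500-bp
    infinite-sites sequences, are burned in to mutation-drift equilibrium, and
    are sampled to produce multilocus datasets.  The package re-implements
    four bottleneck-detection procedures (M-ratio with the 0.68 rule of thumb,
    M-ratio with a simulated critical value from 1000 Kingman-coalescent
    simulations, the heterozygosity-excess test with a simulation-based
    equilibrium heterozygosity, and Tajima's D with simulated significance)
    and an orchestrator that estimates each test's false positive rate across
    an Ne-by-Vk grid of stable populations.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
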