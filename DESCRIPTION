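Package: neutralnets
Title: Wright-Fisher Simulation of Recombining Populations on Neutral Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-time Wright-Fisher simulation of finite, haploid,
    facultatively recombining populations evolving neutrally on percolation
    ("holey") fitness landscapes, in which every genotype is independently
    viable with probability p and unfit otherwise.  Implements three
    selection-recombination schemes (concurrent, simple successive, and
    successive with mating pairs), uniform, one-point and obligate
    Poisson-crossover recombination, and both a finite-sites binary
    hypercube and an infinite-sites mutation-set genotype representation
    with lazily generated fitness.  Provides the standard observables of
    neutral-network population genetics (discovery and fixation rates,
    distinct viable genotypes, segregating mutations, pairwise Hamming
    distance, mutational robustness, mean fitness, viable recombination
    fraction), closed-form coalescent expectations used as test oracles,
    experiment drivers for stationary sweeps, full-discovery and
    escape-variant runs, and GraphML export of the genotype cloud.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
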