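Package: mosaicsim
Title: Forward-in-Time Simulation of Recombining Haplotype Mosaics,
    Quantitative Traits and Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-in-time Wright-Fisher simulation of diploid populations
    in which every chromosome is stored as a mosaic of founder-haplotype
    chunks (start position, founder id) rather than as a sequence.  Supports
    arbitrary recombination maps with Poisson crossover sampling, island and
    stepping-stone migration driven by time-varying trajectories, mutation at
    tracked loci, quantitative traits built from QTLs with calibrated
    environmental variance, and selection through identity, single-locus,
    truncation and Gaussian-optimum fitness functions.  Because ancestry is
    explicit, identical-by-descent tracts between any two chromosomes are
    extracted by interval arithmetic, and neutral variation simulated on the
    founders (ms-style coalescent output) can be propagated onto any later
    generation.  Simulations are configured programmatically or through a
    plain-text module configuration file, and results are returned as tidy
    tibbles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
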