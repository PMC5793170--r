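Package: cryptdrift
Title: Multiscale Simulation of Epigenetic Aging in Intestinal Crypts
Version: 0.1.0
Authors@R:
    person("cryptdrift", "developers", email = "cryptdrift@example.org",
           role = c("aut", "cre"))
Description: An individual cell-based, three-dimensional model of the small
    intestinal crypt in which every cell carries a random genome whose gene
    promoters evolve stochastic histone methylation states (H3K4me3,
    H3K27me3) coupled to a deterministic, bistable DNA-methylation difference
    equation with methylation-dependent maintenance-DNMT binding. The package
    simulates damage-free tissue aging and aging under repeated DNA damage
    repair (DDR), in which transiently elevated de novo DNMT activity during
    repair can switch promoters from low to high DNA methylation. Tools are
    included for fixed-point and bistability analysis of the methylation
    equation, neutral-drift clonal statistics, switch and fixation detection,
    phylogeny export in Newick format, and multi-crypt aggregation of
    methylation drifts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
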