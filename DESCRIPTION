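Package: actseg
Title: Activity-Based Segregation Model of Interphase Chromosome Positioning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Coarse-grained polymer simulation of interphase chromosomes in
    which each 1 Mb monomer experiences stochastic forces set by a
    gene-density-dependent effective temperature. Implements overdamped
    (Brownian) Langevin dynamics of a diploid human genome confined to a
    spherical or ellipsoidal nucleus, the random loop model for chromosome
    compaction, an optional selective attraction of active chromatin to the
    nuclear envelope, and the analysis statistics used to characterise
    nuclear organisation: radial chromosome distributions S(R), radial
    activity and density profiles, and a territory index quantifying
    chromosome territory formation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
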