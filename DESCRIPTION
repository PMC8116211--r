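Package: chromarch
Title: Chromosome Architecture Analysis and Polymer Modelling for Early Embryo Hi-C
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing 3D genome organization from binned Hi-C
    contact maps, motivated by the establishment of nuclear architecture in
    early Drosophila embryos. Implements matrix balancing (iterative
    correction), contact-probability scaling curves P(s) with scaling-exponent
    fits, A/B compartment scores (first eigenvector of the observed/expected
    correlation matrix), saddle-based compartment strength, insulation scores
    and TAD boundaries, differential contact maps, and genomic-interval
    statistics for ChIP peaks versus pericentromeric annotation. Includes a
    Metropolis Monte-Carlo block-copolymer simulator of chromosomes as chains
    of A/B/C beads in a cylindrical nucleus with a Rabl-like initial
    configuration and an apically tethered heterochromatic compartment, a
    heterochromatin-weakening ("mutant") energy transform, inverse inference
    of bead-bead interaction energies from contact maps by damped iterative
    Boltzmann inversion, and seed-deterministic synthetic data generators for
    every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
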