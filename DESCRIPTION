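Package: fasterx
Title: Population Genomics of Faster-X Evolution: Diversity Scans, MK
    Alpha, and Selective Sweep Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Windowed scans of nucleotide diversity, Tajima's D, Kelly's
    Z_nS and divergence from haplotype alignments; sequence-class
    stratified polymorphism and divergence with a short-intron neutral
    class; McDonald-Kreitman tests with pooled and lineage-polarized
    alpha and alpha* estimation and bootstrap confidence intervals; a
    composite-likelihood selective-sweep scan over polarized unfolded
    site frequency spectra with two-state HMM segmentation and an
    arm-matched randomization test; least-squares fitting of the hard
    sweep diversity-reduction model to estimate the population-scaled
    selection intensity; and X-versus-autosome contrast statistics.
    Includes synthetic-data generators (a fast spectrum sampler and a
    forward Wright-Fisher simulator with recombination and selection)
    so that every stage is testable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
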