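Package: meipop
Title: Mobile Element Insertion Polymorphisms: Simulation, Detection, and
    Population Genetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying mobile element insertion (MEI) polymorphisms
    (Alu, L1, SVA) in population-scale sequencing cohorts. Simulates MEI
    cohorts under the standard neutral model with reference-genome
    ascertainment, calls non-reference insertions from read-pair and
    split-read fragment evidence, selects reference MEI from deletion calls,
    genotypes loci with a Bayesian binomial model with phred-scaled genotype
    qualities, estimates detection sensitivity by capture-recapture
    (Lincoln-Petersen), builds ascertainment- and efficiency-corrected allele
    frequency spectra with neutral diversity (theta) fits, derives MEI
    mutation rates from corrected heterozygosity, and quantifies the
    suppression of insertions in functional regions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    S4Vectors,
    IRanges,
    GenomicRanges,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    rtracklayer
Config/testthat/edition: 3
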