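Package: popmetab
Title: Population-Genomic and Metabolomic Divergence Scans for Domestication Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying divergence between evolutionary stages of a
    selfing crop (wild, feralized/intermediate, and cultivated groups), built
    around a Qst-Fst comparison. Provides per-group genetic diversity
    statistics (nucleotide diversity, Watterson's estimator, minor allele
    frequency, polymorphism information content), a per-SNP AMOVA fixation
    index with a permutation outlier test that defines a neutral SNP set,
    sliding-window Fst selective-sweep detection with gene mapping,
    gene-pool sliding-window genomic-similarity analysis, per-metabolite Qst
    estimation with stratified bootstrap confidence intervals and divergence
    calls against the neutral Fst, domestication-locus (Btr1/Btr2)
    deletion-haplotype classification, and a synthetic-cohort generator so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    withr,
    yaml,
    jsonlite,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    lme4,
    optparse
Config/testthat/edition: 3
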