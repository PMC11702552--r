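Package: dielscan
Title: Natural Allelic Variation in Diel Transcription
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for detecting natural allelic variation in
    diel (24-hour) transcription from multi-genotype expression time
    courses. Provides likelihood-ratio tests of sinusoidal rhythmicity
    and of between-group amplitude differences; detection of
    differential diel regulation (DDR) genes whose diel expression range
    co-segregates with promoter haplotype, via Kruskal-Wallis permutation
    tests; permutation enrichment tests of candidate gene sets for GWAS
    signal and adaptation-candidate SNPs; per-site Weir-Cockerham Fst and
    Fisher's combined test; cis-eQTL scans of night-day expression
    responses with stratified-matched null draws; and a
    convolutional-recurrent promoter sequence model with filter-to-motif
    extraction. A synthetic-data module generates pangenomes, promoter
    haplotypes, diel expression, promoters with planted motifs, and SNP
    tables with known ground truth so that every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
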