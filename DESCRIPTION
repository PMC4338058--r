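Package: srnaseeker
Title: Intergenic Small RNA Discovery and Stress-Response Expression
    Analysis for Bacterial Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discovers candidate small regulatory RNAs (sRNAs) in the
    intergenic regions of a bacterial genome and analyses their expression
    under stress conditions. Extracts intergenic regions with flank
    trimming and length filtering, scans them for sigma-70 promoters
    (position weight matrices) and rho-independent terminators
    (hairpin plus U-tract scoring), quantifies expression as RPKM from
    aligned reads with PCR-duplicate removal, promotes intergenic regions
    to high-confidence sRNAs when they carry a complete transcriptional
    unit and are expressed at least 15 percent above both flanking genes,
    performs replicate-free differential expression with an exact
    conditional binomial test, and predicts sRNA target genes by antisense
    seed complementarity to build a co-regulation network. Ships a seeded
    synthetic-data generator (genome, annotation, planted sRNAs and
    negative-binomial read counts per condition) so the whole pipeline
    runs and is validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    igraph,
    jsonlite,
    rtracklayer,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
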