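Package: plastedit
Title: Chloroplast C-to-U RNA Editing Analysis and PPR Target Scoring
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying C-to-U RNA editing in plastid
    transcriptomes from per-site allele counts: editing-site discovery with
    read-count and frequency filters, editing-efficiency estimation,
    genotype-by-stage differential classification of editotypes, region and
    amino-acid-consequence annotation against a plastome reference, and
    two-residue PPR-code match scoring of PLS-class pentatricopeptide repeat
    proteins against sequences upstream of candidate edited cytidines. A
    seeded binomial read-count simulator generates toy plastomes, gene
    models and ground-truth editing panels so the whole pipeline is testable
    without raw sequencing data. Ships a curated efficiency table for a
    soybean pale-green-leaf PPR mutant as a worked data set.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
biocViews: Transcriptomics, RNAEditing, Annotation, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'calling.R'
    'differential.R'
    'io.R'
    'plastedit-package.R'
    'ppr.R'
    'simulate.R'
    'utils.R'
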