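# in-code fixtures shared across test files

# 2 kb reference with a two-exon plus-strand gene and a single-exon
# minus-strand gene, built from a fixed seed
toyAnnotation <- function() {
    set.seed(101)
    bases <- sample(c("A", "C", "G", "T"), 2000, replace = TRUE)
    ref <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
    names(ref) <- "toy"
    genes <- GenomicRanges::GRanges("toy",
        IRanges::IRanges(c(101, 1001), c(400, 1300)),
        strand = c("+", "-"))
    S4Vectors::mcols(genes)$gene_id <- c("geneA", "geneB")
    exons <- GenomicRanges::GRanges("toy",
        IRanges::IRanges(c(101, 301, 1001), c(200, 400, 1300)),
        strand = c("+", "+", "-"))
    S4Vectors::mcols(exons)$gene_id <- c("geneA", "geneA", "geneB")
    list(reference = ref, genes = GeneModelSet(genes, exons))
}

toyCounts <- function(position, strand, ref_base, var_base, n_ref, n_var,
                      sample) {
    data.frame(position = as.integer(position), strand = strand,
               ref_base = ref_base, var_base = var_base,
               n_ref = as.integer(n_ref), n_var = as.integer(n_var),
               sample = sample, stringsAsFactors = FALSE)
}

writeRawCounts <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
}

# universal / toy code tables for match-index tests
universalCode <- function(pairs) {
    pprCodeTable(data.frame(aa5 = pairs$aa5, aaLast = pairs$aaLast,
                            nucleotides = "ACGU"))
}
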