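## internal helpers shared across modules

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

complementBase <- function(x) {
    out <- COMPLEMENT[x]
    if (anyNA(out)) stop("cannot complement base(s): ",
                         paste(unique(x[is.na(out)]), collapse = ", "))
    unname(out)
}

## transcript-sense base at a plastome position
baseAt <- function(reference, position, strand = "+") {
    seqchar <- as.character(subseq(reference[[1L]], position, position))
    if (strand == "-") seqchar <- complementBase(seqchar)
    seqchar
}

refLength <- function(reference) {
    if (is(reference, "DNAStringSet")) width(reference)[1L]
    else length(reference)
}

## plastid genes use the bacterial/plastid genetic code (table 11)
plastidGeneticCode <- function() getGeneticCode("11")

aaThreeLetter <- function(aa) {
    if (aa == "*") return("Ter")
    unname(Biostrings::AMINO_ACID_CODE[aa])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
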