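#!/usr/bin/env Rscript
# Optional external validation: computes PPR-code match indices for
# user-supplied inputs that do not ship with the package — the editing
# factor's motif annotation (from a PPR motif predictor), the soybean
# plastome FASTA, and the plastome coordinates/strands of the validated
# editing sites. Not part of the test suite.
#
#   Rscript scripts/external_validation.R \
#       --motifs gmpgl2_motifs.tsv --fasta plastome.fa \
#       --sites sites.tsv --offset -4 [--code code.tsv]
#
# sites.tsv: TSV with columns gene, position, strand.

suppressPackageStartupMessages({
    library(optparse)
    library(plastedit)
})

opts <- parse_args(OptionParser(option_list = list(
    make_option("--motifs", type = "character"),
    make_option("--fasta", type = "character"),
    make_option("--sites", type = "character"),
    make_option("--code", type = "character", default = NULL),
    make_option("--offset", type = "integer", default = -4L))))

stopifnot(!is.null(opts$motifs), !is.null(opts$fasta), !is.null(opts$sites))

prot <- readPPRMotifs(opts$motifs)
ref <- readReference(opts$fasta)
code <- if (is.null(opts$code)) defaultPPRCode() else readPPRCode(opts$code)
sites <- read.delim(opts$sites, comment.char = "#",
                    stringsAsFactors = FALSE)

pairs <- extractCode(prot)
for (i in seq_len(nrow(sites))) {
    win <- buildWindow(sites$position[i], sites$strand[i], ref,
                       n = nrow(pairs), offset = opts$offset)
    mi <- matchIndex(pairs, win, code)
    cat(sprintf("%s-%d\t%d/%d\n", sites$gene[i], sites$position[i],
                mi$matches, mi$total))
}
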