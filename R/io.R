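## Readers and writers for the pipeline's external formats.
## TSV dialect used throughout: UTF-8, tab-delimited, '#' comment lines,
## '.' for missing values. All plastome coordinates are 1-based and
## intervals are closed.

SITE_COUNT_COLUMNS <- c("position", "strand", "ref_base", "var_base",
                        "n_ref", "n_var")

## colClasses guards single-letter columns (bases, residues) against
## read.delim's logical coercion of "T"/"F"
readDialect <- function(path, colClasses = NA, ...) {
    read.delim(path, comment.char = "#", na.strings = ".",
               stringsAsFactors = FALSE, fileEncoding = "UTF-8",
               colClasses = colClasses, ...)
}

writeDialect <- function(df, path, header = NULL) {
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    if (!is.null(header)) writeLines(paste0("# ", header), con)
    df[] <- lapply(df, function(x) {
        x <- if (is.numeric(x)) format(x, digits = 15, trim = TRUE,
                                       scientific = FALSE)
             else as.character(x)
        x[is.na(x)] <- "."
        x
    })
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a per-site allele count table
#'
#' Parses the tab-separated pileup summary produced upstream of this
#' package (columns `position`, `strand`, `ref_base`, `var_base`, `n_ref`,
#' `n_var`) and normalises records to transcript sense: with
#' `sense = "reference"` (the default), bases of minus-strand rows are
#' complemented on ingest, so a C-to-U site on a minus-strand transcript is
#' expected in the file as G-to-A on the plus strand of the plastome.
#'
#' @param path file to read.
#' @param sample sample label attached to every record.
#' @param sense `"reference"` if the file reports plus-strand bases (the
#'   pileup convention), `"transcript"` if bases are already
#'   transcript-sense.
#' @return A data.frame with columns `position`, `strand`, `ref_base`,
#'   `var_base`, `n_ref`, `n_var`, `sample`; bases transcript-sense, counts
#'   non-negative integers, row order preserved.
#' @seealso [writeSiteCounts()], [callSites()]
#' @export
readSiteCounts <- function(path, sample,
                           sense = c("reference", "transcript")) {
    sense <- match.arg(sense)
    df <- readDialect(path, colClasses = c(strand = "character",
                                           ref_base = "character",
                                           var_base = "character"))
    missing <- setdiff(SITE_COUNT_COLUMNS, colnames(df))
    if (length(missing))
        stop("site count file is missing column(s): ",
             paste(missing, collapse = ", "))
    df <- df[SITE_COUNT_COLUMNS]
    for (col in c("n_ref", "n_var")) {
        bad <- which(is.na(df[[col]]) | df[[col]] < 0 |
                     df[[col]] != round(df[[col]]))
        if (length(bad))
            stop(sprintf("invalid %s at row %d: counts must be %s",
                         col, bad[1L], "non-negative integers"))
        df[[col]] <- as.integer(df[[col]])
    }
    if (!all(df$strand %in% c("+", "-")))
        stop("strand must be '+' or '-'")
    if (!all(c(df$ref_base, df$var_base) %in% names(COMPLEMENT)))
        stop("bases must be one of A, C, G, T, N")
    if (any(is.na(df$position) | df$position < 1))
        stop("positions must be 1-based positive integers")
    df$position <- as.integer(df$position)
    if (sense == "reference") {
        minus <- df$strand == "-"
        df$ref_base[minus] <- complementBase(df$ref_base[minus])
        df$var_base[minus] <- complementBase(df$var_base[minus])
    }
    df$sample <- sample
    df
}

#' Write a per-site allele count table
#'
#' Inverse of [readSiteCounts()]: records held transcript-sense are
#' written back in the requested sense so that a write/read cycle
#' reproduces the records exactly.
#'
#' @param x data.frame of transcript-sense site counts.
#' @param path output file.
#' @param sense see [readSiteCounts()].
#' @return Invisibly, `path`.
#' @export
writeSiteCounts <- function(x, path,
                            sense = c("reference", "transcript")) {
    sense <- match.arg(sense)
    df <- x[SITE_COUNT_COLUMNS]
    if (sense == "reference") {
        minus <- df$strand == "-"
        df$ref_base[minus] <- complementBase(df$ref_base[minus])
        df$var_base[minus] <- complementBase(df$var_base[minus])
    }
    writeDialect(df, path, header = "per-site allele counts")
    invisible(path)
}

#' Read and write a plastome reference
#'
#' Thin wrappers over [Biostrings::readDNAStringSet()] /
#' [Biostrings::writeXStringSet()] that validate the alphabet (A, C, G, T,
#' N only) and that a single sequence is present.
#'
#' @param path FASTA file.
#' @return `readReference` returns a one-sequence `DNAStringSet`.
#' @export
readReference <- function(path) {
    ref <- readDNAStringSet(path)
    if (length(ref) != 1L)
        stop("expected a single plastome sequence, found ", length(ref))
    freq <- Biostrings::alphabetFrequency(ref[[1L]])
    if (sum(freq[c("A", "C", "G", "T", "N")]) != width(ref)[1L])
        stop("reference alphabet restricted to A, C, G, T, N")
    ref
}

#' @rdname readReference
#' @param x a `DNAStringSet`.
#' @export
writeReference <- function(x, path) {
    writeXStringSet(x, path)
    invisible(path)
}

#' Read a gene annotation (GFF3)
#'
#' Imports `gene` and `exon` features from a GFF3-style file (1-based
#' closed coordinates) into a [GeneModelSet-class]. Exons are matched to
#' genes via their `Parent` attribute and validated: strand must be `+` or
#' `-`, exon intervals must be well-formed and contained in the gene span.
#'
#' @param path GFF3 file.
#' @return A `GeneModelSet`.
#' @export
readGeneAnnotation <- function(path) {
    gr <- rtracklayer::import(path)
    if (is.null(gr$type)) stop("not a GFF3 annotation: no type column")
    genes <- gr[gr$type == "gene"]
    exons <- gr[gr$type == "exon"]
    if (any(as.character(strand(c(genes, exons))) == "*"))
        stop("unknown strand symbol in annotation")
    gid <- genes$ID
    if (is.null(gid) || anyNA(gid))
        stop("gene features need an ID attribute")
    g <- GRanges(seqnames(genes), IRanges(start(genes), end(genes)),
                 strand = strand(genes))
    mcols(g)$gene_id <- as.character(gid)
    parent <- vapply(exons$Parent, function(p) p[1L], character(1))
    e <- GRanges(seqnames(exons), IRanges(start(exons), end(exons)),
                 strand = strand(exons))
    mcols(e)$gene_id <- as.character(parent)
    GeneModelSet(g, e)
}

#' Write a gene annotation (GFF3)
#'
#' @param x a `GeneModelSet`.
#' @param path output GFF3 file.
#' @return Invisibly, `path`.
#' @export
writeGeneAnnotation <- function(x, path) {
    g <- geneRanges(x)
    e <- exonRanges(x)
    g$type <- "gene"
    g$ID <- g$gene_id
    e$type <- "exon"
    e$Parent <- e$gene_id
    e$ID <- paste0(e$gene_id, ".exon", ave(seq_along(e), e$gene_id,
                                           FUN = seq_along))
    all <- c(g, e)
    all$source <- "plastedit"
    rtracklayer::export(sort(all), path, format = "gff3")
    invisible(path)
}

#' Read and write an editing-efficiency table
#'
#' The TSV form of an [EditingTable-class]: columns `gene`, `position`,
#' `strand`, `site_label`, `region`, `change`, then one efficiency column
#' per sample (fractions in \[0,1\], `.` for missing).
#'
#' @param path file to read or write.
#' @return `readEfficiencyTable` returns an `EditingTable`.
#' @export
readEfficiencyTable <- function(path) {
    df <- readDialect(path, colClasses = c(gene = "character",
                                           strand = "character",
                                           site_label = "character",
                                           region = "character",
                                           change = "character"))
    fixed <- c("gene", "position", "strand", "site_label", "region", "change")
    missing <- setdiff(fixed, colnames(df))
    if (length(missing))
        stop("efficiency table missing column(s): ",
             paste(missing, collapse = ", "))
    samples <- setdiff(colnames(df), fixed)
    if (length(samples) == 0L) stop("efficiency table has no sample columns")
    eff <- as.matrix(df[samples])
    storage.mode(eff) <- "double"
    EditingTable(eff, gene = df$gene, position = df$position,
                 strand = df$strand, siteLabel = df$site_label,
                 region = df$region, change = df$change)
}

#' @rdname readEfficiencyTable
#' @param x an `EditingTable`.
#' @export
writeEfficiencyTable <- function(x, path) {
    rd <- rowData(x)
    df <- data.frame(gene = rd$gene, position = rd$position,
                     strand = rd$strand, site_label = rd$siteLabel,
                     region = rd$region, change = rd$change,
                     stringsAsFactors = FALSE)
    df <- cbind(df, as.data.frame(efficiencies(x)))
    writeDialect(df, path, header = "editing efficiencies (fractions)")
    invisible(path)
}

#' Curated editing-efficiency table of the soybean pale-green-leaf mutant
#'
#' Loads the bundled 43-site editing panel comparing wild-type (HD12) and
#' mutant (Gmpgl2) seedlings at two leaf developmental stages (S1: 12-day,
#' S2: 18-day first trifoliate leaf), transcribed cell-for-cell from the
#' published table. Efficiencies are stored as fractions; the published
#' percent strings (including a bare `0%`) are normalised on load. Region
#' labels are derived from the published annotation column: 38 coding
#' sites plus one downstream, two intergenic and two intron sites — the
#' loader asserts this breakdown.
#'
#' @return An [EditingTable-class] with samples `HD12_S1`, `HD12_S2`,
#'   `Gmpgl2_S1`, `Gmpgl2_S2`.
#' @examples
#' tab <- loadTable1Fixture()
#' dim(tab)
#' @export
loadTable1Fixture <- function() {
    path <- system.file("extdata", "gmpgl2_editing_table.tsv",
                        package = "plastedit", mustWork = TRUE)
    df <- readDialect(path)
    parsePct <- function(x) as.numeric(sub("%$", "", x)) / 100
    samples <- c("HD12_S1", "HD12_S2", "Gmpgl2_S1", "Gmpgl2_S2")
    eff <- vapply(c("hd12_s1", "hd12_s2", "gmpgl2_s1", "gmpgl2_s2"),
                  function(col) parsePct(df[[col]]), numeric(nrow(df)))
    colnames(eff) <- samples
    lab <- df$annotation
    noncoding <- c(Downstream = "downstream", Intergenic = "intergenic",
                   intron = "intron", Intron = "intron")
    region <- ifelse(lab %in% names(noncoding), noncoding[lab], "CDS")
    change <- ifelse(region == "CDS", lab, NA_character_)
    tab <- EditingTable(eff, gene = df$gene, position = df$position,
                        strand = "*", region = region, change = change)
    regs <- table(factor(regionLabels(tab), REGION_LEVELS))
    stopifnot(nrow(tab) == 43L, regs[["CDS"]] == 38L,
              regs[["downstream"]] == 1L, regs[["intergenic"]] == 2L,
              regs[["intron"]] == 2L)
    tab
}

#' Sites with sequencing-validated differential editing
#'
#' The nine editing sites whose genotype difference was confirmed by
#' direct cDNA sequencing of amplicons in both developmental stages. The
#' list is curated (it is not derivable from the efficiency table by a
#' single threshold rule) and is the natural site set for PPR target
#' scoring of the causal editing factor.
#'
#' @return Character vector of nine `gene-position` keys.
#' @examples
#' validatedSites()
#' @export
validatedSites <- function() {
    c("ndhB-139627", "ndhB-141281", "ndhB-141424", "ndhB-141650",
      "ndhD-120618", "ndhE-119873", "ndhF-124681", "rps16-56313",
      "rps18-66641")
}

#' Read a PPR motif annotation
#'
#' TSV with columns `motif_index`, `class`, `start`, `end`, `aa5`,
#' `aa_last` describing a PLS-class PPR protein's motifs in N- to
#' C-terminal order. Motif identification itself is upstream (an external
#' motif predictor); this package consumes its output.
#'
#' @param path TSV file.
#' @param name protein name; defaults to the file name.
#' @return A [PPRProtein-class].
#' @export
readPPRMotifs <- function(path, name = basename(path)) {
    df <- readDialect(path, colClasses = c(class = "character",
                                           aa5 = "character",
                                           aa_last = "character"))
    need <- c("motif_index", "class", "start", "end", "aa5", "aa_last")
    missing <- setdiff(need, colnames(df))
    if (length(missing))
        stop("motif annotation missing column(s): ",
             paste(missing, collapse = ", "))
    df <- df[order(df$motif_index), ]
    PPRProtein(name, data.frame(class = df$class, start = df$start,
                                end = df$end, aa5 = df$aa5,
                                aaLast = df$aa_last))
}

#' Read a two-residue PPR code table
#'
#' TSV with columns `aa5`, `aa_last`, `nucleotides` (e.g. `"UC"`; empty or
#' `.` for an explicit no-prediction entry).
#'
#' @param path TSV file.
#' @param provenance free-text origin recorded on the object.
#' @return A [PPRCodeTable-class].
#' @export
readPPRCode <- function(path, provenance = basename(path)) {
    df <- readDialect(path, colClasses = c(aa5 = "character",
                                           aa_last = "character",
                                           nucleotides = "character"))
    missing <- setdiff(c("aa5", "aa_last", "nucleotides"), colnames(df))
    if (length(missing))
        stop("code table missing column(s): ",
             paste(missing, collapse = ", "))
    nts <- ifelse(is.na(df$nucleotides), "", df$nucleotides)
    pprCodeTable(data.frame(aa5 = df$aa5, aaLast = df$aa_last,
                            nucleotides = nts),
                 provenance = provenance)
}

#' Bundled two-residue PPR code
#'
#' Loads the replaceable code asset shipped with the package, compiled
#' from published two-residue (position 5 + last position) recognition
#' codes for P/L/S motifs of editing-factor PPR proteins. Residue pairs
#' absent from the table score as non-matching in [matchIndex()].
#'
#' @return A [PPRCodeTable-class].
#' @export
defaultPPRCode <- function() {
    readPPRCode(system.file("extdata", "ppr_code.tsv",
                            package = "plastedit", mustWork = TRUE),
                provenance = "bundled two-residue code")
}

#' Read a simulation configuration from YAML
#'
#' @param path YAML file whose keys are [simulationConfig()] arguments.
#' @return A validated simulation configuration list.
#' @export
readSimulationConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    do.call(simulationConfig, cfg)
}
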