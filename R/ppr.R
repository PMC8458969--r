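## PPR-code target scoring: align the two-residue code of a PLS-class PPR
## protein's P/L/S motifs to the sequence upstream of a candidate edited C
## and count code-permitted matches. One motif binds one nucleotide,
## N-terminal motif to 5'-most base.

#' @describeIn PPRProtein-class The recognition code: one
#'   (position-5, last-position) residue pair per P/L/S motif, N- to
#'   C-terminal. E-class motifs are excluded.
#' @export
setMethod("extractCode", "PPRProtein", function(x) {
    m <- motifTable(x)
    if (nrow(m) && any(m$end - m$start + 1L < 5L))
        stop("motif span shorter than 5 residues")
    b <- m[m$class %in% c("P", "L", "S"), , drop = FALSE]
    data.frame(aa5 = b$aa5, aaLast = b$aaLast, stringsAsFactors = FALSE)
})

#' Extract the upstream target window of an edited C
#'
#' Returns the `n`-nucleotide transcript-sense window whose 3'-most base
#' sits `offset` nucleotides from the edited C (default -4: the window
#' spans transcript positions `offset - n + 1 ... offset` relative to the
#' C, e.g. -20..-4 for a 17-motif protein). For minus-strand sites the
#' plus-strand reference slice is reverse-complemented, so "upstream"
#' always means 5' on the transcript.
#'
#' @param position 1-based plastome coordinate of the edited C
#'   (transcript sense: a plus-strand C, or a minus-strand G on the
#'   reference).
#' @param strand transcript strand.
#' @param reference plastome `DNAStringSet`.
#' @param n window length (number of P/L/S motifs).
#' @param offset 3'-end placement relative to the edited C; negative.
#' @return A [TargetWindow-class].
#' @export
buildWindow <- function(position, strand, reference, n, offset = -4L) {
    offset <- as.integer(offset)
    n <- as.integer(n)
    if (offset >= 0L) stop("offset must be negative (window lies upstream)")
    if (baseAt(reference, position, strand) != "C")
        stop("no transcript-sense C at position ", position)
    len <- refLength(reference)
    if (strand == "+") {
        to <- position + offset
        from <- to - n + 1L
        if (from < 1L || to < 1L)
            stop("window extends past the reference start")
        win <- as.character(subseq(reference[[1L]], from, to))
    } else {
        from <- position - offset
        to <- from + n - 1L
        if (to > len)
            stop("window extends past the reference start")
        win <- as.character(reverseComplement(
            subseq(reference[[1L]], from, to)))
    }
    new("TargetWindow", position = as.integer(position), strand = strand,
        window = win, offset = offset)
}

#' Match index of a PPR code against a target window
#'
#' Pairs motif `i` with window nucleotide `i` (N-terminal motif with the
#' 5'-most base) and counts motifs whose code-permitted nucleotide set
#' contains the paired base (T and U are equivalent). Residue pairs
#' absent from the code table count as non-matches.
#'
#' @param code data.frame from [extractCode()] (columns `aa5`, `aaLast`).
#' @param window a [TargetWindow-class] or plain window string of the
#'   same length as the code.
#' @param table a [PPRCodeTable-class].
#' @return List with `matches`, `total` and `fraction`.
#' @examples
#' code <- data.frame(aa5 = c("T", "T", "N"), aaLast = c("D", "N", "D"))
#' tab <- pprCodeTable(data.frame(aa5 = c("T", "T", "N"),
#'                                aaLast = c("D", "N", "D"),
#'                                nucleotides = c("G", "A", "U")))
#' matchIndex(code, "GAA", tab)  # 2 of 3
#' @export
matchIndex <- function(code, window, table) {
    win <- if (is(window, "TargetWindow")) window@window else window
    nts <- strsplit(toupper(win), "", fixed = TRUE)[[1L]]
    nts[nts == "T"] <- "U"
    if (nrow(code) != length(nts))
        stop("code length (", nrow(code), ") and window length (",
             length(nts), ") differ")
    hit <- vapply(seq_along(nts), function(i)
        nts[i] %in% permittedNucleotides(table, code$aa5[i], code$aaLast[i]),
        logical(1))
    list(matches = sum(hit), total = length(nts),
         fraction = if (length(nts)) sum(hit) / length(nts) else NaN)
}

#' Scan annotated genes for candidate PPR target sites
#'
#' Scores every transcript-sense C inside annotated gene spans with
#' [buildWindow()] + [matchIndex()] and ranks candidates by descending
#' match fraction (ties broken by ascending position). Positions whose
#' window would run past the reference are skipped.
#'
#' @param protein a [PPRProtein-class].
#' @param reference plastome `DNAStringSet`.
#' @param genes a [GeneModelSet-class].
#' @param table a [PPRCodeTable-class].
#' @param offset window register, see [buildWindow()].
#' @return data.frame with columns `position`, `strand`, `gene`,
#'   `matches`, `total`, `fraction`, ranked best first.
#' @export
scanTargets <- function(protein, reference, genes, table, offset = -4L) {
    code <- extractCode(protein)
    n <- nrow(code)
    g <- geneRanges(genes)
    out <- list()
    for (i in seq_along(g)) {
        str <- as.character(strand(g))[i]
        span <- start(g)[i]:end(g)[i]
        bases <- strsplit(as.character(
            subseq(reference[[1L]], start(g)[i], end(g)[i])), "")[[1L]]
        isC <- if (str == "+") bases == "C" else bases == "G"
        for (pos in span[isC]) {
            win <- tryCatch(buildWindow(pos, str, reference, n, offset),
                            error = function(e) NULL)
            if (is.null(win)) next
            mi <- matchIndex(code, win, table)
            out[[length(out) + 1L]] <- data.frame(
                position = pos, strand = str,
                gene = mcols(g)$gene_id[i],
                matches = mi$matches, total = mi$total,
                fraction = mi$fraction, stringsAsFactors = FALSE)
        }
    }
    if (length(out) == 0L)
        return(data.frame(position = integer(0), strand = character(0),
                          gene = character(0), matches = integer(0),
                          total = integer(0), fraction = numeric(0)))
    res <- do.call(rbind, out)
    res <- res[order(-res$fraction, res$position), , drop = FALSE]
    rownames(res) <- NULL
    res
}
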