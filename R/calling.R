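## Editing-site discovery and quantification from per-site allele counts.
## All counts are transcript-sense (readSiteCounts normalises on ingest),
## so a C-to-U candidate is always a C record with a T variant.

#' Editing efficiency at a site
#'
#' The editotype estimator: the fraction of reads carrying the edited base,
#' `n_var / (n_ref + n_var)`. Reads carrying third alleles are ignored
#' upstream and do not enter the denominator. Scale-invariant in the
#' counts; undefined (an error) at zero total coverage — callers decide
#' whether to report such site/samples as missing.
#'
#' @param nRef,nVar non-negative integer read counts supporting the
#'   reference and the edited base (vectorised).
#' @return Numeric vector of fractions in \[0,1\].
#' @examples
#' computeEfficiency(2098, 7902)  # 0.7902
#' @export
computeEfficiency <- function(nRef, nVar) {
    if (any(nRef < 0 | nVar < 0)) stop("counts must be non-negative")
    total <- nRef + nVar
    if (any(total == 0))
        stop("editing efficiency undefined at zero coverage")
    nVar / total
}

#' Candidate-site discovery filter
#'
#' A position passes discovery in a sample when the reference reads, the
#' variant reads, and the variant frequency all meet the configured
#' thresholds (frequency bounds inclusive). Failures report the first
#' violated criterion in the stated order: coverage, minimum reference
#' reads, minimum variant reads, frequency window.
#'
#' @param nRef,nVar read counts (vectorised).
#' @param thresholds a [filterThresholds()] object.
#' @return A data.frame with logical `pass` and character `reason`
#'   (`NA` where passing; otherwise one of `"no_coverage"`, `"min_ref"`,
#'   `"min_var"`, `"frequency"`).
#' @examples
#' applyDiscoveryFilter(4, 3)            # pass (freq 3/7)
#' applyDiscoveryFilter(4, 2)$reason     # "min_var"
#' applyDiscoveryFilter(9, 1)$pass       # TRUE: freq 0.1 inclusive
#' @export
applyDiscoveryFilter <- function(nRef, nVar, thresholds = filterThresholds()) {
    n <- max(length(nRef), length(nVar))
    nRef <- rep_len(nRef, n)
    nVar <- rep_len(nVar, n)
    total <- nRef + nVar
    freq <- ifelse(total > 0, nVar / total, NA_real_)
    reason <- rep(NA_character_, n)
    reason[is.na(reason) & total == 0] <- "no_coverage"
    reason[is.na(reason) & nRef < thresholds@minRef] <- "min_ref"
    reason[is.na(reason) & nVar < thresholds@minVar] <- "min_var"
    reason[is.na(reason) &
           (freq < thresholds@freqLo | freq > thresholds@freqHi)] <- "frequency"
    data.frame(pass = is.na(reason), reason = reason,
               stringsAsFactors = FALSE)
}

#' Call editing sites across samples
#'
#' In `discovery` mode, a position becomes an editing site when it passes
#' [applyDiscoveryFilter()] in at least one sample; its efficiency is then
#' reported in every sample with coverage (the frequency window is not
#' re-applied at reporting, so reported efficiencies may lie outside it).
#' In `targeted` mode, efficiency is reported at every panel position
#' regardless of the filter — the mode for re-quantifying a known
#' editotype panel, whose sites routinely sit above the discovery window.
#'
#' Only transcript-sense C-to-T records are considered C-to-U candidates;
#' other records are ignored.
#'
#' @param counts data.frame of transcript-sense site counts for one or
#'   more samples (rows of [readSiteCounts()] output, concatenated).
#' @param thresholds a [filterThresholds()] (discovery mode).
#' @param mode `"discovery"` or `"targeted"`.
#' @param panel targeted mode: either a data.frame with `position` and
#'   `strand` columns, or a [TruthPanel-class] /
#'   [PlastomeSimulation-class], in which case gene, label, region and
#'   amino-acid-change annotation are carried over from the panel.
#' @return An [EditingTable-class] with one column per sample (ordered as
#'   first encountered in `counts`); efficiency is `NA` where a sample has
#'   no coverage at a site.
#' @export
callSites <- function(counts, thresholds = filterThresholds(),
                      mode = c("discovery", "targeted"), panel = NULL) {
    mode <- match.arg(mode)
    samples <- unique(counts$sample)
    cand <- counts[counts$ref_base == "C" & counts$var_base == "T", ,
                   drop = FALSE]
    meta <- NULL
    if (mode == "discovery") {
        if (nrow(cand) == 0L)
            return(emptyEditingTable(samples))
        dec <- applyDiscoveryFilter(cand$n_ref, cand$n_var, thresholds)
        keykeep <- unique(paste(cand$position, cand$strand)[dec$pass])
        if (length(keykeep) == 0L)
            return(emptyEditingTable(samples))
        keep <- unique(cand[paste(cand$position, cand$strand) %in% keykeep,
                            c("position", "strand")])
        keep <- keep[order(keep$position), , drop = FALSE]
    } else {
        if (is.null(panel)) stop("targeted mode requires a panel")
        if (is(panel, "PlastomeSimulation")) panel <- truthPanel(panel)
        if (is(panel, "TruthPanel")) {
            meta <- as.data.frame(panelSites(panel))
            keep <- meta[c("position", "strand")]
        } else {
            keep <- as.data.frame(panel)[c("position", "strand")]
        }
    }
    eff <- matrix(NA_real_, nrow(keep), length(samples),
                  dimnames = list(NULL, samples))
    key <- paste(keep$position, keep$strand)
    for (s in samples) {
        cs <- cand[cand$sample == s, , drop = FALSE]
        idx <- match(key, paste(cs$position, cs$strand))
        hit <- !is.na(idx)
        tot <- cs$n_ref[idx[hit]] + cs$n_var[idx[hit]]
        val <- ifelse(tot > 0, cs$n_var[idx[hit]] / tot, NA_real_)
        eff[hit, s] <- val
    }
    if (is.null(meta))
        EditingTable(eff, position = keep$position, strand = keep$strand)
    else
        EditingTable(eff, gene = meta$gene, position = meta$position,
                     strand = meta$strand, siteLabel = meta$siteLabel,
                     region = meta$region, change = meta$change)
}

emptyEditingTable <- function(samples) {
    eff <- matrix(numeric(0), 0L, length(samples),
                  dimnames = list(NULL, samples))
    EditingTable(eff, position = integer(0))
}

#' Classify the genomic region of a position
#'
#' Region precedence: exonic CDS of a gene, then intron (inside a gene
#' span but outside its exons), then downstream (within
#' `downstreamWindow` nucleotides 3' of a gene end, strand-aware), then
#' intergenic. The reported gene is the containing gene, the gene whose
#' downstream flank covers the position, or the nearest gene.
#'
#' @param position 1-based plastome coordinates (vectorised).
#' @param genes a [GeneModelSet-class].
#' @param downstreamWindow width of the 3' downstream flank in
#'   nucleotides.
#' @param referenceLength optional plastome length; positions outside
#'   `[1, referenceLength]` raise a range error.
#' @return data.frame with columns `region` and `gene_id`.
#' @export
annotateRegion <- function(position, genes, downstreamWindow = 200L,
                           referenceLength = NULL) {
    if (!is.null(referenceLength) &&
        any(position < 1L | position > referenceLength))
        stop("position outside the reference (1..", referenceLength, ")")
    g <- geneRanges(genes)
    e <- exonRanges(genes)
    gid <- mcols(g)$gene_id
    n <- length(position)
    region <- rep("intergenic", n)
    gene <- rep(NA_character_, n)
    if (length(g)) {
        pos <- GRanges(as.character(seqnames(g))[1L],
                       IRanges(position, position))
        ## downstream flanks, strand-aware (3' of the gene end)
        plus <- as.character(strand(g)) == "+"
        dstart <- ifelse(plus, end(g) + 1L, pmax(1L, start(g) - downstreamWindow))
        dend <- ifelse(plus, end(g) + downstreamWindow, start(g) - 1L)
        down <- GRanges(seqnames(g), IRanges(dstart, pmax(dstart - 1L, dend)))
        ovE <- findOverlaps(pos, GRanges(seqnames(e), IRanges(start(e), end(e))))
        ovG <- findOverlaps(pos, GRanges(seqnames(g), IRanges(start(g), end(g))))
        ovD <- findOverlaps(pos, down)
        for (i in seq_len(n)) {
            he <- S4Vectors::subjectHits(ovE)[S4Vectors::queryHits(ovE) == i]
            hg <- S4Vectors::subjectHits(ovG)[S4Vectors::queryHits(ovG) == i]
            hd <- S4Vectors::subjectHits(ovD)[S4Vectors::queryHits(ovD) == i]
            if (length(he)) {
                region[i] <- "CDS"
                gene[i] <- mcols(e)$gene_id[he[1L]]
            } else if (length(hg)) {
                region[i] <- "intron"
                gene[i] <- gid[hg[1L]]
            } else if (length(hd)) {
                region[i] <- "downstream"
                gene[i] <- gid[hd[1L]]
            } else {
                d <- GenomicRanges::distance(pos[i], g)
                gene[i] <- gid[which.min(d)]
            }
        }
    }
    data.frame(region = region, gene_id = gene, stringsAsFactors = FALSE)
}

#' Amino-acid consequence of a C-to-U edit
#'
#' Substitutes U (written T) at the edited codon position and translates
#' both codons with the plastid (bacterial) genetic code. Returns the
#' substitution as `"Ser-Leu"`-style three-letter pairs, or
#' `"Unchanged"` for a synonymous edit.
#'
#' @param codon transcript-sense codon (3 characters, A/C/G/T).
#' @param editedOffset position of the edited C within the codon (1-3).
#' @return Character scalar.
#' @examples
#' predictAminoAcidChange("TCA", 2)  # "Ser-Leu"
#' predictAminoAcidChange("CTC", 3)  # "Unchanged"
#' @export
predictAminoAcidChange <- function(codon, editedOffset) {
    codon <- toupper(codon)
    if (nchar(codon) != 3L || !all(strsplit(codon, "")[[1]] %in%
                                   c("A", "C", "G", "T")))
        stop("codon must be a 3-mer over A, C, G, T")
    editedOffset <- as.integer(editedOffset)
    if (!editedOffset %in% 1:3) stop("editedOffset must be 1, 2 or 3")
    if (substring(codon, editedOffset, editedOffset) != "C")
        stop("no C at the edited codon position")
    edited <- codon
    substring(edited, editedOffset, editedOffset) <- "T"
    gc <- plastidGeneticCode()
    from <- gc[[codon]]
    to <- gc[[edited]]
    if (from == to) "Unchanged"
    else paste0(aaThreeLetter(from), "-", aaThreeLetter(to))
}

## Transcript-sense codon context of a CDS position. Gene spans are taken
## as coding from their first exon base (toy-annotation convention).
codonContext <- function(position, geneId, genes, reference) {
    ee <- exonRanges(genes, geneId)
    if (length(ee) == 0L) stop("gene has no exons: ", geneId)
    str <- as.character(strand(ee))[1L]
    segs <- lapply(seq_along(ee), function(i)
        as.character(subseq(reference[[1L]], start(ee)[i], end(ee)[i])))
    tx <- paste(segs, collapse = "")
    ## transcript coordinate of the genomic position
    offs <- cumsum(c(0L, width(ee)))[seq_along(ee)]
    hit <- which(position >= start(ee) & position <= end(ee))
    if (length(hit) == 0L) stop("position not exonic in ", geneId)
    tpos <- offs[hit] + (position - start(ee)[hit]) + 1L
    if (str == "-") {
        tx <- as.character(reverseComplement(DNAString(tx)))
        tpos <- nchar(tx) - tpos + 1L
    }
    codonIndex <- (tpos - 1L) %/% 3L
    offset <- (tpos - 1L) %% 3L + 1L
    codon <- substring(tx, codonIndex * 3L + 1L, codonIndex * 3L + 3L)
    list(codon = codon, offset = offset, txPos = tpos)
}

#' Annotate called sites with region and amino-acid consequence
#'
#' Fills the `gene`, `region` and `change` row metadata of an
#' [EditingTable-class] using a gene annotation and (for coding sites) the
#' plastome reference: the codon context of each exonic site is extracted
#' transcript-sense and the substitution predicted with
#' [predictAminoAcidChange()].
#'
#' @param x an `EditingTable` whose positions are plastome coordinates.
#' @param genes a [GeneModelSet-class].
#' @param reference the plastome `DNAStringSet` (needed for `change`
#'   prediction; omit to annotate regions only).
#' @param downstreamWindow see [annotateRegion()].
#' @return The annotated `EditingTable`.
#' @export
annotateSites <- function(x, genes, reference = NULL,
                          downstreamWindow = 200L) {
    ann <- annotateRegion(sitePositions(x), genes, downstreamWindow,
                          referenceLength = if (!is.null(reference))
                              refLength(reference) else NULL)
    rd <- rowData(x)
    rd$gene <- ann$gene_id
    rd$region <- ann$region
    change <- rep(NA_character_, nrow(x))
    if (!is.null(reference)) {
        cds <- which(ann$region == "CDS")
        for (i in cds) {
            ctx <- codonContext(rd$position[i], ann$gene_id[i], genes,
                                reference)
            change[i] <- predictAminoAcidChange(ctx$codon, ctx$offset)
        }
    } else if (any(ann$region == "CDS")) {
        stop("reference required to annotate amino-acid changes of CDS sites")
    }
    rd$change <- change
    rownames(rd) <- ifelse(is.na(rd$gene), paste0("site-", rd$siteLabel),
                           paste0(rd$gene, "-", rd$siteLabel))
    rowData(x) <- rd
    rownames(x) <- rownames(rd)
    validObject(x)
    x
}
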