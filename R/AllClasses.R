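#' @include AllGenerics.R
NULL

## Region vocabulary used throughout: exonic coding sequence, intron within a
## gene span, strand-aware downstream flank, and everything else intergenic.
REGION_LEVELS <- c("CDS", "intron", "intergenic", "downstream")

MOTIF_CLASSES <- c("P", "L", "S", "E1", "E2", "E+")

## ---------------------------------------------------------------------------
## FilterThresholds
## ---------------------------------------------------------------------------

#' Discovery filter thresholds
#'
#' Minimum reference/variant read counts and the editing-frequency window a
#' position must satisfy (in at least one sample) to be called a candidate
#' editing site. Defaults: reference reads >= 2, variant reads >= 3, and
#' variant frequency within \[0.1, 0.9\] (both bounds inclusive).
#'
#' @slot minRef minimum reads supporting the reference base.
#' @slot minVar minimum reads supporting the edited (variant) base.
#' @slot freqLo,freqHi inclusive bounds on variant frequency at discovery.
#' @export
setClass("FilterThresholds",
    slots = c(minRef = "integer", minVar = "integer",
              freqLo = "numeric", freqHi = "numeric"))

setValidity("FilterThresholds", function(object) {
    if (object@minRef < 0L || object@minVar < 0L)
        return("minimum read counts must be non-negative")
    if (!(object@freqLo >= 0 && object@freqLo < object@freqHi &&
          object@freqHi <= 1))
        return("frequency window must satisfy 0 <= freqLo < freqHi <= 1")
    TRUE
})

#' @describeIn FilterThresholds-class Constructor.
#' @param minRef,minVar,freqLo,freqHi see slot descriptions.
#' @return A `FilterThresholds` object.
#' @examples
#' filterThresholds()
#' @export
filterThresholds <- function(minRef = 2L, minVar = 3L,
                             freqLo = 0.1, freqHi = 0.9) {
    new("FilterThresholds", minRef = as.integer(minRef),
        minVar = as.integer(minVar), freqLo = freqLo, freqHi = freqHi)
}

setMethod("show", "FilterThresholds", function(object) {
    cat(sprintf(
        "FilterThresholds: ref >= %d, var >= %d, frequency in [%g, %g]\n",
        object@minRef, object@minVar, object@freqLo, object@freqHi))
})

## ---------------------------------------------------------------------------
## GeneModelSet
## ---------------------------------------------------------------------------

#' Gene and exon models on a plastome reference
#'
#' Holds gene spans and their exons as two parallel [GenomicRanges::GRanges]
#' (1-based, closed intervals), each carrying a `gene_id` metadata column.
#' Exons of a gene must be non-overlapping, sorted in genomic order, on the
#' gene's strand, and contained in the gene span. Gaps between consecutive
#' exons are the introns.
#'
#' @slot genes `GRanges` of gene spans with `gene_id`.
#' @slot exons `GRanges` of exons with `gene_id`.
#' @export
setClass("GeneModelSet",
    slots = c(genes = "GRanges", exons = "GRanges"))

setValidity("GeneModelSet", function(object) {
    g <- object@genes
    e <- object@exons
    if (is.null(mcols(g)$gene_id) || is.null(mcols(e)$gene_id))
        return("genes and exons need a gene_id metadata column")
    if (anyDuplicated(mcols(g)$gene_id))
        return("duplicated gene_id among genes")
    if (!all(as.character(strand(g)) %in% c("+", "-")))
        return("gene strand must be '+' or '-'")
    if (!all(mcols(e)$gene_id %in% mcols(g)$gene_id))
        return("exon refers to unknown gene_id")
    idx <- match(mcols(e)$gene_id, mcols(g)$gene_id)
    if (!all(start(e) >= start(g)[idx] & end(e) <= end(g)[idx]))
        return("exon outside its gene span")
    if (!all(as.character(strand(e)) == as.character(strand(g))[idx]))
        return("exon strand differs from gene strand")
    for (gid in unique(mcols(e)$gene_id)) {
        ee <- e[mcols(e)$gene_id == gid]
        if (is.unsorted(start(ee)))
            return(sprintf("exons of %s not in genomic order", gid))
        if (length(ee) > 1L && any(start(ee)[-1L] <= end(ee)[-length(ee)]))
            return(sprintf("exons of %s overlap", gid))
    }
    TRUE
})

#' @describeIn GeneModelSet-class Constructor from two `GRanges`.
#' @param genes,exons `GRanges` with a `gene_id` metadata column.
#' @return A `GeneModelSet`.
#' @export
GeneModelSet <- function(genes, exons) {
    o <- order(start(exons))
    exons <- exons[o]
    new("GeneModelSet", genes = genes, exons = exons)
}

#' @describeIn GeneModelSet-class Gene spans.
#' @param x a `GeneModelSet`.
#' @export
setMethod("geneRanges", "GeneModelSet", function(x) x@genes)

#' @describeIn GeneModelSet-class Exons, optionally of one gene
#'   (genomic order).
#' @param gene optional single `gene_id`.
#' @export
setMethod("exonRanges", "GeneModelSet", function(x, gene = NULL) {
    e <- x@exons
    if (!is.null(gene)) e <- e[mcols(e)$gene_id == gene]
    e
})

#' @describeIn GeneModelSet-class Introns (inter-exon gaps within gene
#'   spans), optionally of one gene.
#' @export
setMethod("intronRanges", "GeneModelSet", function(x, gene = NULL) {
    gids <- mcols(x@genes)$gene_id
    if (!is.null(gene)) gids <- intersect(gids, gene)
    out <- GRanges()
    for (gid in gids) {
        ee <- exonRanges(x, gid)
        if (length(ee) < 2L) next
        st <- end(ee)[-length(ee)] + 1L
        en <- start(ee)[-1L] - 1L
        keep <- en >= st
        if (!any(keep)) next
        ir <- GRanges(seqnames(ee)[1L], IRanges(st[keep], en[keep]),
                      strand = strand(ee)[1L])
        mcols(ir)$gene_id <- gid
        out <- c(out, ir)
    }
    out
})

setMethod("show", "GeneModelSet", function(object) {
    cat(sprintf("GeneModelSet: %d gene(s), %d exon(s)\n",
                length(object@genes), length(object@exons)))
})

## ---------------------------------------------------------------------------
## EditingTable
## ---------------------------------------------------------------------------

#' Sites-by-samples editing efficiencies
#'
#' A [SummarizedExperiment::SummarizedExperiment] with one assay,
#' `"efficiency"`: the fraction of transcripts edited at each site in each
#' sample (in \[0,1\]; `NA` marks a site/sample with no usable coverage, as
#' distinct from a measured zero). Row metadata carries `gene`, `position`
#' (1-based plastome coordinate of the edited C), `strand` (transcript
#' strand), `siteLabel` (display key, by default the position), `region`
#' (one of CDS, intron, intergenic, downstream) and `change` (amino-acid
#' substitution such as `"Ser-Leu"`, `"Unchanged"` for synonymous edits;
#' `NA` for non-coding or unannotated sites). A site has a `change` if and
#' only if its region is CDS.
#'
#' @export
setClass("EditingTable", contains = "SummarizedExperiment")

setValidity("EditingTable", function(object) {
    if (!"efficiency" %in% SummarizedExperiment::assayNames(object))
        return("missing 'efficiency' assay")
    eff <- assay(object, "efficiency")
    if (!is.numeric(eff))
        return("efficiencies must be numeric")
    bad <- !is.na(eff) & (eff < 0 | eff > 1)
    if (any(bad))
        return("efficiencies must lie in [0, 1]")
    rd <- rowData(object)
    need <- c("gene", "position", "strand", "siteLabel", "region", "change")
    if (!all(need %in% colnames(rd)))
        return(paste("rowData must contain:", paste(need, collapse = ", ")))
    if (anyDuplicated(paste(rd$gene, rd$siteLabel)))
        return("duplicated (gene, site) keys")
    reg <- rd$region
    if (!all(is.na(reg) | reg %in% REGION_LEVELS))
        return("invalid region label")
    cds <- !is.na(reg) & reg == "CDS"
    if (any(cds & is.na(rd$change)) || any(!cds & !is.na(rd$change)))
        return("a site has an amino-acid change iff its region is CDS")
    if (anyDuplicated(colnames(object)))
        return("duplicated sample labels")
    TRUE
})

#' @describeIn EditingTable-class Constructor.
#' @param efficiency numeric matrix, sites x samples, with sample names as
#'   column names; values in \[0,1\] or `NA`.
#' @param gene gene identifiers (or `NA` for unassigned sites).
#' @param position 1-based plastome coordinates of the edited C.
#' @param strand transcript strand, `"+"` or `"-"`.
#' @param siteLabel display label per site; defaults to `position`. Kept
#'   separate from `position` so curated tables can label sites by their
#'   published coordinates while simulations use toy coordinates.
#' @param region,change site annotation (see class description).
#' @return An `EditingTable`.
#' @export
EditingTable <- function(efficiency, gene = NA_character_, position,
                         strand = "+", siteLabel = NULL,
                         region = NA_character_, change = NA_character_) {
    efficiency <- as.matrix(efficiency)
    n <- nrow(efficiency)
    if (is.null(colnames(efficiency)))
        stop("efficiency matrix needs sample names as colnames")
    position <- as.integer(position)
    gene <- rep_len(as.character(gene), n)
    strand <- rep_len(as.character(strand), n)
    region <- rep_len(as.character(region), n)
    change <- rep_len(as.character(change), n)
    if (is.null(siteLabel)) siteLabel <- as.character(position)
    siteLabel <- rep_len(as.character(siteLabel), n)
    rd <- DataFrame(gene = gene, position = position, strand = strand,
                    siteLabel = siteLabel, region = region, change = change)
    rownames(efficiency) <- ifelse(is.na(gene), paste0("site-", siteLabel),
                                   paste0(gene, "-", siteLabel))
    se <- SummarizedExperiment(assays = list(efficiency = efficiency),
                               rowData = rd)
    new("EditingTable", se)
}

#' @describeIn EditingTable-class The efficiency matrix.
#' @param x an `EditingTable`.
#' @export
setMethod("efficiencies", "EditingTable",
          function(x) assay(x, "efficiency"))

#' @describeIn EditingTable-class Site keys (`gene-label`).
#' @export
setMethod("siteKeys", "EditingTable", function(x) rownames(x))

#' @describeIn EditingTable-class Sample labels.
#' @export
setMethod("sampleLabels", "EditingTable", function(x) colnames(x))

#' @describeIn EditingTable-class Gene identifiers.
#' @export
setMethod("geneIds", "EditingTable", function(x) rowData(x)$gene)

#' @describeIn EditingTable-class Plastome positions.
#' @export
setMethod("sitePositions", "EditingTable", function(x) rowData(x)$position)

#' @describeIn EditingTable-class Transcript strands.
#' @export
setMethod("siteStrands", "EditingTable", function(x) rowData(x)$strand)

#' @describeIn EditingTable-class Region labels.
#' @export
setMethod("regionLabels", "EditingTable", function(x) rowData(x)$region)

#' @describeIn EditingTable-class Amino-acid changes.
#' @export
setMethod("aaChanges", "EditingTable", function(x) rowData(x)$change)

setMethod("show", "EditingTable", function(object) {
    cat(sprintf("EditingTable: %d site(s) x %d sample(s)\n",
                nrow(object), ncol(object)))
    reg <- regionLabels(object)
    if (any(!is.na(reg))) {
        tb <- table(factor(reg, REGION_LEVELS))
        cat("  regions:",
            paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
    }
    cat("  samples:", paste(colnames(object), collapse = ", "), "\n")
})

## ---------------------------------------------------------------------------
## PPRProtein
## ---------------------------------------------------------------------------

#' A PLS-class PPR protein as an ordered motif array
#'
#' Motifs are listed N- to C-terminal with their class (P, L or S
#' nucleotide-binding repeats; E1/E2/E+ editing domains), 1-based closed
#' span on the protein, and the two code residues: the amino acid at motif
#' position 5 and at the motif's last position. E-class motifs must follow
#' all P/L/S motifs and do not contribute to the recognition code.
#'
#' @slot name protein identifier.
#' @slot motifs `DataFrame` with columns `class`, `start`, `end`, `aa5`,
#'   `aaLast`.
#' @export
setClass("PPRProtein",
    slots = c(name = "character", motifs = "DFrame"))

setValidity("PPRProtein", function(object) {
    m <- object@motifs
    need <- c("class", "start", "end", "aa5", "aaLast")
    if (!all(need %in% colnames(m)))
        return(paste("motif table must contain:", paste(need, collapse = ", ")))
    if (nrow(m) == 0L) return(TRUE)
    if (!all(m$class %in% MOTIF_CLASSES))
        return("motif class must be one of P, L, S, E1, E2, E+")
    if (any(m$end - m$start + 1L < 5L))
        return("motif span shorter than 5 residues")
    if (nrow(m) > 1L &&
        any(m$start[-1L] <= m$end[-nrow(m)]))
        return("motif spans must be ascending and non-overlapping")
    binding <- m$class %in% c("P", "L", "S")
    if (any(binding) && any(!binding) &&
        min(which(!binding)) < max(which(binding)))
        return("E-class motifs must follow all P/L/S motifs")
    aa <- c(m$aa5[binding], m$aaLast[binding])
    if (!all(aa %in% names(Biostrings::AMINO_ACID_CODE)))
        return("aa5/aaLast must be standard one-letter amino acids")
    TRUE
})

#' @describeIn PPRProtein-class Constructor.
#' @param name protein identifier.
#' @param motifs data.frame with columns `class`, `start`, `end`, `aa5`,
#'   `aaLast`, in N- to C-terminal order.
#' @return A `PPRProtein`.
#' @export
PPRProtein <- function(name, motifs) {
    motifs <- DataFrame(class = as.character(motifs$class),
                        start = as.integer(motifs$start),
                        end = as.integer(motifs$end),
                        aa5 = as.character(motifs$aa5),
                        aaLast = as.character(motifs$aaLast))
    new("PPRProtein", name = name, motifs = motifs)
}

#' @describeIn PPRProtein-class The motif table.
#' @param x a `PPRProtein`.
#' @export
setMethod("motifTable", "PPRProtein", function(x) x@motifs)

#' @describeIn PPRProtein-class Number of nucleotide-binding (P/L/S) motifs.
#' @export
setMethod("nBindingMotifs", "PPRProtein",
          function(x) sum(x@motifs$class %in% c("P", "L", "S")))

setMethod("show", "PPRProtein", function(object) {
    m <- object@motifs
    cat(sprintf("PPRProtein '%s': %d motif(s) [%s], %d nucleotide-binding\n",
                object@name, nrow(m), paste(m$class, collapse = ""),
                nBindingMotifs(object)))
})

## ---------------------------------------------------------------------------
## PPRCodeTable
## ---------------------------------------------------------------------------

#' Two-residue PPR recognition code
#'
#' Maps a (position-5, last-position) amino-acid pair of a P/L/S motif to
#' the set of nucleotides that motif is expected to bind (a subset of
#' A, C, G, U; an empty set records an explicit "no prediction"). Pairs not
#' present in the table are treated as non-matching by [matchIndex()].
#'
#' @slot entries `DataFrame` with columns `aa5`, `aaLast`, `nucleotides`
#'   (e.g. `"UC"`).
#' @slot provenance free-text origin of the table.
#' @export
setClass("PPRCodeTable",
    slots = c(entries = "DFrame", provenance = "character"))

setValidity("PPRCodeTable", function(object) {
    e <- object@entries
    if (!all(c("aa5", "aaLast", "nucleotides") %in% colnames(e)))
        return("entries need columns aa5, aaLast, nucleotides")
    if (anyDuplicated(paste(e$aa5, e$aaLast)))
        return("duplicated residue pair in code table")
    nts <- strsplit(e$nucleotides, "", fixed = TRUE)
    if (!all(vapply(nts, function(x) all(x %in% c("A", "C", "G", "U")),
                    logical(1))))
        return("nucleotides must be a subset of A, C, G, U")
    TRUE
})

#' @describeIn PPRCodeTable-class Constructor.
#' @param entries data.frame with columns `aa5`, `aaLast`, `nucleotides`.
#' @param provenance free-text origin.
#' @return A `PPRCodeTable`.
#' @export
pprCodeTable <- function(entries, provenance = "user") {
    entries <- DataFrame(aa5 = as.character(entries$aa5),
                         aaLast = as.character(entries$aaLast),
                         nucleotides = as.character(entries$nucleotides))
    new("PPRCodeTable", entries = entries, provenance = provenance)
}

#' @describeIn PPRCodeTable-class Permitted nucleotides for one residue
#'   pair; `character(0)` when the pair is absent or has no prediction.
#' @param x a `PPRCodeTable`.
#' @param aa5,aaLast one-letter residues at motif position 5 and the last
#'   position.
#' @export
setMethod("permittedNucleotides", "PPRCodeTable", function(x, aa5, aaLast) {
    e <- x@entries
    hit <- which(e$aa5 == aa5 & e$aaLast == aaLast)
    if (length(hit) == 0L) return(character(0))
    strsplit(e$nucleotides[hit[1L]], "", fixed = TRUE)[[1L]]
})

setMethod("show", "PPRCodeTable", function(object) {
    cat(sprintf("PPRCodeTable: %d residue pair(s) (%s)\n",
                nrow(object@entries), object@provenance))
})

## ---------------------------------------------------------------------------
## TargetWindow
## ---------------------------------------------------------------------------

#' Upstream target window of an edited C
#'
#' The transcript-sense nucleotide window (5'->3') aligned to a PPR
#' protein's P/L/S motifs, whose 3'-most base sits `offset` nucleotides
#' from the edited C (offset is negative: the window lies upstream).
#'
#' @slot position 1-based plastome coordinate of the edited C.
#' @slot strand transcript strand.
#' @slot window transcript-sense sequence, 5'->3'.
#' @slot offset position of the window's 3' end relative to the edited C.
#' @export
setClass("TargetWindow",
    slots = c(position = "integer", strand = "character",
              window = "character", offset = "integer"))

setValidity("TargetWindow", function(object) {
    if (object@offset >= 0L) return("offset must be negative (upstream)")
    if (!object@strand %in% c("+", "-")) return("strand must be '+' or '-'")
    TRUE
})

setMethod("show", "TargetWindow", function(object) {
    cat(sprintf("TargetWindow: %s strand %s, 3' end at C%+d, 5'-%s-3'\n",
                object@position, object@strand, object@offset,
                object@window))
})

## ---------------------------------------------------------------------------
## TruthPanel
## ---------------------------------------------------------------------------

#' Ground-truth editing sites for simulation
#'
#' Each site carries its gene, display label, toy plastome coordinate,
#' transcript strand, region class, codon context (for CDS sites) and the
#' expected amino-acid change, together with a sites-by-samples matrix of
#' true editing efficiencies. The panel also records the simulation's
#' sequencing error rate and coverage model.
#'
#' @slot sites `DataFrame` of site descriptors.
#' @slot truth numeric matrix of true efficiencies (sites x samples).
#' @slot errorRate per-base symmetric miscall probability.
#' @slot coverage mean per-site read depth.
#' @slot dispersion negative-binomial dispersion of coverage; `NA` for
#'   fixed coverage.
#' @export
setClass("TruthPanel",
    slots = c(sites = "DFrame", truth = "matrix",
              errorRate = "numeric", coverage = "numeric",
              dispersion = "numeric"))

setValidity("TruthPanel", function(object) {
    if (nrow(object@sites) != nrow(object@truth))
        return("sites and truth matrix disagree in length")
    tr <- object@truth
    if (length(tr) && (any(is.na(tr)) || any(tr < 0 | tr > 1)))
        return("true efficiencies must lie in [0, 1]")
    if (object@errorRate < 0 || object@errorRate >= 0.5)
        return("errorRate must lie in [0, 0.5)")
    if (object@coverage <= 0) return("coverage must be positive")
    TRUE
})

#' @describeIn TruthPanel-class Site descriptors.
#' @param x a `TruthPanel`.
#' @export
setMethod("panelSites", "TruthPanel", function(x) x@sites)

#' @describeIn TruthPanel-class True efficiency matrix.
#' @export
setMethod("truthMatrix", "TruthPanel", function(x) x@truth)

#' @describeIn TruthPanel-class Sample labels.
#' @export
setMethod("sampleLabels", "TruthPanel", function(x) colnames(x@truth))

setMethod("show", "TruthPanel", function(object) {
    cat(sprintf(
        "TruthPanel: %d site(s) x %d sample(s); coverage %g%s, error %g\n",
        nrow(object@sites), ncol(object@truth), object@coverage,
        if (is.na(object@dispersion)) " (fixed)" else
            sprintf(" (NB dispersion %g)", object@dispersion),
        object@errorRate))
})

## ---------------------------------------------------------------------------
## PlastomeSimulation
## ---------------------------------------------------------------------------

#' A simulated plastome with gene models and editing ground truth
#'
#' Bundle returned by [generateReference()] and [panelFromTable1()]: the
#' toy plastome sequence, its gene/exon models, and the ground-truth
#' editing panel, plus the generating configuration.
#'
#' @slot reference single-sequence `DNAStringSet`.
#' @slot genes a `GeneModelSet`.
#' @slot panel a `TruthPanel`.
#' @slot config the generating [simulationConfig()] list.
#' @export
setClass("PlastomeSimulation",
    slots = c(reference = "DNAStringSet", genes = "GeneModelSet",
              panel = "TruthPanel", config = "list"))

setValidity("PlastomeSimulation", function(object) {
    if (length(object@reference) != 1L)
        return("reference must contain exactly one sequence")
    pos <- object@panel@sites$position
    if (length(pos) && any(pos < 1L | pos > width(object@reference)[1L]))
        return("panel site outside the reference")
    TRUE
})

#' @describeIn PlastomeSimulation-class The reference sequence.
#' @param x a `PlastomeSimulation`.
#' @export
setMethod("refSequence", "PlastomeSimulation", function(x) x@reference)

#' @describeIn PlastomeSimulation-class The gene models.
#' @export
setMethod("geneModels", "PlastomeSimulation", function(x) x@genes)

#' @describeIn PlastomeSimulation-class The ground-truth panel.
#' @export
setMethod("truthPanel", "PlastomeSimulation", function(x) x@panel)

setMethod("show", "PlastomeSimulation", function(object) {
    cat(sprintf("PlastomeSimulation: %d bp reference, %d gene(s)\n",
                width(object@reference)[1L],
                length(geneRanges(object@genes))))
    show(object@panel)
})
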