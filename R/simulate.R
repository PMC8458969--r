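## Seeded generation of toy plastomes, gene models, ground-truth editing
## panels, and binomially sampled per-site read counts. Everything is a
## pure function of (config, seed); a fixed seed reproduces sequences,
## annotations and counts byte for byte.

STOP_CODONS <- c("TAA", "TAG", "TGA")

allCodons <- function() {
    b <- c("A", "C", "G", "T")
    as.vector(outer(outer(b, b, paste0), b, paste0))
}

#' Simulation configuration
#'
#' Validated parameter list for [generateReference()] and
#' [simulateCounts()]. Lengths are nucleotides; probabilities are
#' fractions. Defaults describe a small but structurally complete toy
#' plastome: a handful of genes on both strands, occasional introns, and
#' editing sites of intermediate efficiency at moderate coverage with a
#' low symmetric sequencing error rate.
#'
#' @param seed integer seed; the simulation is a pure function of the
#'   configuration including this seed.
#' @param nGenes number of genes.
#' @param codonRange range of codons per CDS (start/stop included).
#' @param intronProb per-gene probability of carrying one intron.
#' @param intronRange intron length range.
#' @param minusStrandProb per-gene probability of the minus strand.
#' @param spacerRange intergenic spacer length range.
#' @param nSites number of ground-truth editing sites (placed on
#'   transcript-sense Cs in coding sequence).
#' @param siteEfficiency a single true editing efficiency for all sites,
#'   or a range to draw each site's efficiency from uniformly.
#' @param samples sample labels; truth is shared across samples.
#' @param coverage mean per-site read depth.
#' @param dispersion negative-binomial coverage dispersion; `NA` for
#'   fixed coverage.
#' @param errorRate symmetric per-base miscall probability.
#' @return A validated list of class `SimulationConfig`.
#' @export
simulationConfig <- function(seed = 1L, nGenes = 8L,
                             codonRange = c(60L, 150L),
                             intronProb = 0.3, intronRange = c(80L, 200L),
                             minusStrandProb = 0.5,
                             spacerRange = c(300L, 600L),
                             nSites = 20L, siteEfficiency = c(0.2, 0.9),
                             samples = "S1",
                             coverage = 100, dispersion = NA_real_,
                             errorRate = 0.001) {
    cfg <- list(seed = as.integer(seed), nGenes = as.integer(nGenes),
                codonRange = as.integer(codonRange),
                intronProb = intronProb,
                intronRange = as.integer(intronRange),
                minusStrandProb = minusStrandProb,
                spacerRange = as.integer(spacerRange),
                nSites = as.integer(nSites),
                siteEfficiency = siteEfficiency,
                samples = as.character(samples),
                coverage = coverage, dispersion = as.numeric(dispersion),
                errorRate = errorRate)
    stopifnot(cfg$nGenes > 0L, cfg$nSites >= 0L,
              length(cfg$codonRange) == 2L, cfg$codonRange[1L] >= 4L,
              diff(cfg$codonRange) >= 0L,
              cfg$intronProb >= 0, cfg$intronProb <= 1,
              cfg$minusStrandProb >= 0, cfg$minusStrandProb <= 1,
              all(cfg$siteEfficiency >= 0), all(cfg$siteEfficiency <= 1),
              cfg$coverage > 0, cfg$errorRate >= 0, cfg$errorRate < 0.5,
              length(cfg$samples) >= 1L)
    class(cfg) <- "SimulationConfig"
    cfg
}

## A gene assembled from its spliced transcript plus an optional intron.
## Returns the plus-strand sequence, local exon intervals, and a mapper
## from transcript coordinates to genomic coordinates once the gene is
## placed at genomic start `s`.
geneLayout <- function(tx, intronAfter = NULL, intronSeq = "",
                       strand = "+") {
    k <- intronAfter %||% 0L
    ilen <- nchar(intronSeq)
    local <- if (k > 0L)
        paste0(substr(tx, 1L, k), intronSeq,
               substr(tx, k + 1L, nchar(tx)))
    else tx
    glen <- nchar(local)
    plusSeq <- if (strand == "+") local else
        as.character(reverseComplement(DNAString(local)))
    exonsLocal <- if (k > 0L)
        rbind(c(1L, k), c(k + ilen + 1L, glen))
    else rbind(c(1L, glen))
    list(tx = tx, plusSeq = plusSeq, glen = glen, strand = strand,
         k = k, ilen = ilen, exonsLocal = exonsLocal)
}

layoutExonsGenomic <- function(lay, s) {
    ex <- lay$exonsLocal
    if (lay$strand == "+") {
        cbind(s + ex[, 1L] - 1L, s + ex[, 2L] - 1L)
    } else {
        out <- cbind(s + lay$glen - ex[, 2L], s + lay$glen - ex[, 1L])
        out[rev(seq_len(nrow(out))), , drop = FALSE]
    }
}

layoutTxToGenomic <- function(lay, s, tpos) {
    local <- ifelse(lay$k > 0L & tpos > lay$k, tpos + lay$ilen, tpos)
    if (lay$strand == "+") s + local - 1L else s + lay$glen - local
}

layoutIntronToGenomic <- function(lay, s, ipos) {
    local <- lay$k + ipos
    if (lay$strand == "+") s + local - 1L else s + lay$glen - local
}

randomBases <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                        replace = TRUE), collapse = "")

randomCodons <- function(n) sample(setdiff(allCodons(), STOP_CODONS), n,
                                   replace = TRUE)

assemblePlastome <- function(layouts, spacers, seqname = "toyplastome") {
    pieces <- character(0)
    starts <- integer(length(layouts))
    at <- 1L
    for (i in seq_along(layouts)) {
        pieces <- c(pieces, spacers[i])
        at <- at + nchar(spacers[i])
        starts[i] <- at
        pieces <- c(pieces, layouts[[i]]$plusSeq)
        at <- at + layouts[[i]]$glen
    }
    pieces <- c(pieces, spacers[length(spacers)])
    seqchar <- paste(pieces, collapse = "")
    ref <- DNAStringSet(seqchar)
    names(ref) <- seqname
    gr <- GRanges(seqname,
                  IRanges(starts,
                          starts + vapply(layouts, `[[`, 0L, "glen") - 1L),
                  strand = vapply(layouts, `[[`, "", "strand"))
    mcols(gr)$gene_id <- names(layouts)
    exAll <- do.call(rbind, lapply(seq_along(layouts), function(i)
        cbind(layoutExonsGenomic(layouts[[i]], starts[i]), i)))
    ex <- GRanges(seqname, IRanges(exAll[, 1L], exAll[, 2L]),
                  strand = vapply(layouts, `[[`, "", "strand")[exAll[, 3L]])
    mcols(ex)$gene_id <- names(layouts)[exAll[, 3L]]
    list(reference = ref, genes = GeneModelSet(gr, ex), starts = starts)
}

#' Generate a toy plastome with ground-truth editing sites
#'
#' Builds a random plastome of `nGenes` protein-coding genes on both
#' strands (spaced by random intergenic sequence, each gene optionally
#' split by one intron), then places `nSites` ground-truth editing sites
#' on transcript-sense Cs within coding sequence, recording each site's
#' codon context and predicted amino-acid consequence. Reproducible:
#' byte-identical output for a fixed configuration.
#'
#' @param config a [simulationConfig()].
#' @return A [PlastomeSimulation-class].
#' @examples
#' sim <- generateReference(simulationConfig(seed = 7, nSites = 5))
#' truthPanel(sim)
#' @export
generateReference <- function(config = simulationConfig()) {
    set.seed(config$seed)
    nm <- sprintf("gene%02d", seq_len(config$nGenes))
    layouts <- list()
    for (i in seq_len(config$nGenes)) {
        nCod <- sample(config$codonRange[1L]:config$codonRange[2L], 1L)
        tx <- paste0("ATG", paste(randomCodons(nCod - 2L), collapse = ""),
                     "TAA")
        strand <- if (runif(1L) < config$minusStrandProb) "-" else "+"
        if (runif(1L) < config$intronProb) {
            k <- 3L * sample(seq_len(nCod - 1L), 1L)
            ilen <- sample(config$intronRange[1L]:config$intronRange[2L], 1L)
            layouts[[nm[i]]] <- geneLayout(tx, k, randomBases(ilen), strand)
        } else {
            layouts[[nm[i]]] <- geneLayout(tx, strand = strand)
        }
    }
    spacers <- vapply(seq_len(config$nGenes + 1L), function(i)
        randomBases(sample(config$spacerRange[1L]:config$spacerRange[2L],
                           1L)), character(1))
    asm <- assemblePlastome(layouts, spacers)
    ## pool of transcript-sense Cs in CDS, with codon context
    pool <- list()
    for (i in seq_along(layouts)) {
        lay <- layouts[[i]]
        tpos <- which(strsplit(lay$tx, "")[[1L]] == "C")
        if (length(tpos) == 0L) next
        codonIndex <- (tpos - 1L) %/% 3L
        pool[[i]] <- data.frame(
            gene = nm[i],
            position = layoutTxToGenomic(lay, asm$starts[i], tpos),
            strand = lay$strand,
            codon = substring(lay$tx, codonIndex * 3L + 1L,
                              codonIndex * 3L + 3L),
            codonOffset = (tpos - 1L) %% 3L + 1L,
            stringsAsFactors = FALSE)
    }
    pool <- do.call(rbind, pool)
    if (config$nSites > 0L &&
        (is.null(pool) || nrow(pool) < config$nSites))
        stop("infeasible configuration: more sites requested than ",
             "available coding Cs")
    sites <- if (config$nSites > 0L)
        pool[sort(sample(nrow(pool), config$nSites)), , drop = FALSE]
    else pool[integer(0), , drop = FALSE]
    eff <- if (length(config$siteEfficiency) == 1L)
        rep(config$siteEfficiency, nrow(sites))
    else runif(nrow(sites), config$siteEfficiency[1L],
               config$siteEfficiency[2L])
    truth <- matrix(rep(eff, length(config$samples)),
                    ncol = length(config$samples),
                    dimnames = list(NULL, config$samples))
    change <- if (nrow(sites)) mapply(predictAminoAcidChange, sites$codon,
                                      sites$codonOffset)
              else character(0)
    sdf <- DataFrame(gene = sites$gene,
                     siteLabel = as.character(sites$position),
                     position = sites$position, strand = sites$strand,
                     region = rep("CDS", nrow(sites)),
                     codon = sites$codon, codonOffset = sites$codonOffset,
                     change = unname(change))
    panel <- new("TruthPanel", sites = sdf, truth = truth,
                 errorRate = config$errorRate, coverage = config$coverage,
                 dispersion = config$dispersion)
    new("PlastomeSimulation", reference = asm$reference,
        genes = asm$genes, panel = panel, config = unclass(config))
}

#' Simulate per-site allele counts by binomial sampling
#'
#' At a ground-truth site with efficiency `e`, coverage `m` and error
#' rate `eps`, the edited-read count is drawn as
#' `Binomial(m, e * (1 - eps) + (1 - e) * eps)`; at non-site Cs the
#' variant count is pure error, `Binomial(m, eps)`. Coverage is fixed or
#' negative-binomial per site. Counts are reported transcript-sense
#' (always a C reference with a T variant), matching the
#' [readSiteCounts()] in-memory layout.
#'
#' @param sim a [PlastomeSimulation-class].
#' @param coverage,errorRate,dispersion override the panel's values.
#' @param positions `"genes"` simulates every transcript-sense C inside
#'   gene spans (plus any panel sites outside them); `"sites"` restricts
#'   to panel sites, the economical choice for targeted re-quantification
#'   studies.
#' @param seed RNG seed; defaults to the simulation's configured seed.
#' @return data.frame of site counts for all panel samples, stacked.
#' @export
simulateCounts <- function(sim, coverage = NULL, errorRate = NULL,
                           dispersion = NULL,
                           positions = c("genes", "sites"), seed = NULL) {
    positions <- match.arg(positions)
    panel <- truthPanel(sim)
    coverage <- coverage %||% panel@coverage
    errorRate <- errorRate %||% panel@errorRate
    dispersion <- dispersion %||% panel@dispersion
    set.seed(seed %||% sim@config$seed)
    ps <- panelSites(panel)
    if (positions == "sites") {
        pos <- ps$position
        strd <- ps$strand
        truthIdx <- seq_len(nrow(ps))
    } else {
        g <- geneRanges(geneModels(sim))
        gStr <- as.character(strand(g))
        pos <- integer(0)
        strd <- character(0)
        for (i in seq_along(g)) {
            bases <- strsplit(as.character(
                subseq(refSequence(sim)[[1L]], start(g)[i], end(g)[i])),
                "")[[1L]]
            want <- if (gStr[i] == "+") "C" else "G"
            at <- start(g)[i] - 1L + which(bases == want)
            pos <- c(pos, at)
            strd <- c(strd, rep(gStr[i], length(at)))
        }
        extra <- !(paste(ps$position, ps$strand) %in% paste(pos, strd))
        pos <- c(pos, ps$position[extra])
        strd <- c(strd, ps$strand[extra])
        o <- order(pos)
        pos <- pos[o]
        strd <- strd[o]
        truthIdx <- match(paste(pos, strd), paste(ps$position, ps$strand))
    }
    truth <- truthMatrix(panel)
    samples <- colnames(truth)
    n <- length(pos)
    out <- vector("list", length(samples))
    for (j in seq_along(samples)) {
        e <- rep(0, n)
        hit <- !is.na(truthIdx)
        e[hit] <- truth[truthIdx[hit], j]
        m <- if (is.na(dispersion)) rep(round(coverage), n)
             else rnbinom(n, mu = coverage, size = 1 / dispersion)
        p <- e * (1 - errorRate) + (1 - e) * errorRate
        nv <- rbinom(n, m, p)
        out[[j]] <- data.frame(position = pos, strand = strd,
                               ref_base = "C", var_base = "T",
                               n_ref = m - nv, n_var = nv,
                               sample = samples[j],
                               stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
}

## codon (and its in-codon offset of the edited C) realising each
## substitution type under the plastid genetic code
CODON_FOR_CHANGE <- list(
    "Ser-Leu" = c("TCA", 2L), "Pro-Leu" = c("CCA", 2L),
    "Ser-Phe" = c("TCT", 2L), "Thr-Met" = c("ACG", 2L),
    "His-Tyr" = c("CAT", 1L), "Thr-Ile" = c("ACA", 2L),
    "Unchanged" = c("CTC", 3L))

#' Ground-truth panel seeded from the curated editing table
#'
#' Rebuilds the curated 43-site editotype panel (see
#' [loadTable1Fixture()]) as simulation ground truth on a generated toy
#' plastome: one toy gene per published gene, in published order, with
#' codon contexts chosen so every coding site reproduces its published
#' amino-acid substitution, introns carrying the two published intron
#' sites, and planted downstream/intergenic Cs for the three published
#' non-coding sites. Published genomic positions are kept as site
#' *labels*; toy coordinates are seeded and arbitrary. True efficiencies
#' equal the published per-sample values; the panel's read-count model
#' defaults to fixed coverage 2000 with error rate 0, the conditions of
#' the package's parameter-recovery study.
#'
#' The builder self-checks: regions re-derived with [annotateRegion()]
#' and substitutions re-derived with [predictAminoAcidChange()] must
#' reproduce the published labels.
#'
#' @param seed seed for the (arbitrary) toy sequence.
#' @param coverage,errorRate,dispersion read-count model recorded on the
#'   panel.
#' @return A [PlastomeSimulation-class] with a 43-site, 4-sample panel.
#' @export
panelFromTable1 <- function(seed = 1949L, coverage = 2000,
                            errorRate = 0, dispersion = NA_real_) {
    set.seed(seed)
    tab <- loadTable1Fixture()
    rd <- rowData(tab)
    geneOrder <- unique(rd$gene)
    minusGenes <- c("rpoB", "rps16", "petB", "ndhB")
    intronLen <- 120L
    intronSiteAt <- 60L
    layouts <- list()
    cdsPlan <- list()  # per gene: fixture row idx -> codon index
    for (g in geneOrder) {
        rows <- which(rd$gene == g)
        cds <- rows[rd$region[rows] == "CDS"]
        cds <- cds[order(rd$position[cds])]
        nCod <- max(12L, 3L * length(cds) + 4L)
        codons <- randomCodons(nCod - 2L)
        codonIdx <- integer(0)
        if (length(cds)) {
            codonIdx <- 2L + 3L * (seq_along(cds) - 1L)
            for (j in seq_along(cds)) {
                spec <- CODON_FOR_CHANGE[[rd$change[cds[j]]]]
                codons[codonIdx[j] - 1L] <- spec[1L]
            }
        }
        tx <- paste0("ATG", paste(codons, collapse = ""), "TAA")
        strand <- if (g %in% minusGenes) "-" else "+"
        hasIntron <- any(rd$region[rows] == "intron")
        if (hasIntron) {
            k <- 3L * (nCod %/% 2L)
            iseq <- randomBases(intronLen)
            substr(iseq, intronSiteAt, intronSiteAt) <- "C"
            layouts[[g]] <- geneLayout(tx, k, iseq, strand)
        } else {
            layouts[[g]] <- geneLayout(tx, strand = strand)
        }
        cdsPlan[[g]] <- list(rows = cds, codonIdx = codonIdx)
    }
    spacers <- vapply(seq_len(length(geneOrder) + 1L),
                      function(i) randomBases(500L), character(1))
    asm <- assemblePlastome(layouts, spacers)
    seqchar <- as.character(asm$reference[[1L]])
    starts <- asm$starts
    names(starts) <- geneOrder
    ## place each fixture row on the toy plastome
    n <- nrow(tab)
    position <- integer(n)
    strand <- character(n)
    codon <- rep(NA_character_, n)
    codonOffset <- rep(NA_integer_, n)
    for (g in geneOrder) {
        lay <- layouts[[g]]
        plan <- cdsPlan[[g]]
        for (j in seq_along(plan$rows)) {
            i <- plan$rows[j]
            spec <- CODON_FOR_CHANGE[[rd$change[i]]]
            tpos <- (plan$codonIdx[j] - 1L) * 3L + as.integer(spec[2L])
            position[i] <- layoutTxToGenomic(lay, starts[[g]], tpos)
            strand[i] <- lay$strand
            codon[i] <- spec[1L]
            codonOffset[i] <- as.integer(spec[2L])
        }
        rows <- which(rd$gene == g)
        for (i in rows[rd$region[rows] == "intron"]) {
            position[i] <- layoutIntronToGenomic(lay, starts[[g]],
                                                 intronSiteAt)
            strand[i] <- lay$strand
        }
    }
    ## non-coding sites planted in the spacers (plus strand)
    plantPlus <- function(pos) {
        substr(seqchar, pos, pos) <<- "C"
        pos
    }
    for (i in which(rd$region == "downstream")) {
        g <- rd$gene[i]
        gr <- geneRanges(asm$genes)
        span <- gr[mcols(gr)$gene_id == g]
        if (as.character(GenomicRanges::strand(span)) == "+") {
            position[i] <- plantPlus(end(span) + 50L)
        } else {
            position[i] <- start(span) - 50L
            substr(seqchar, position[i], position[i]) <- "G"
        }
        strand[i] <- as.character(GenomicRanges::strand(span))
    }
    for (i in which(rd$region == "intergenic")) {
        position[i] <- plantPlus(starts[[rd$gene[i]]] - 250L)
        strand[i] <- "+"
    }
    ref <- DNAStringSet(seqchar)
    names(ref) <- names(asm$reference)
    sdf <- DataFrame(gene = rd$gene, siteLabel = rd$siteLabel,
                     position = position, strand = strand,
                     region = rd$region, codon = codon,
                     codonOffset = codonOffset, change = rd$change)
    panel <- new("TruthPanel", sites = sdf, truth = efficiencies(tab),
                 errorRate = errorRate, coverage = coverage,
                 dispersion = dispersion)
    sim <- new("PlastomeSimulation", reference = ref, genes = asm$genes,
               panel = panel,
               config = unclass(simulationConfig(seed = seed,
                                                 coverage = coverage,
                                                 errorRate = errorRate,
                                                 samples = colnames(
                                                     efficiencies(tab)))))
    ## self-check: the toy placement reproduces the published annotation
    ann <- annotateRegion(position, asm$genes, downstreamWindow = 200L,
                          referenceLength = refLength(ref))
    stopifnot(identical(ann$region, as.character(rd$region)),
              identical(ann$gene_id, as.character(rd$gene)))
    for (i in which(rd$region == "CDS"))
        stopifnot(identical(predictAminoAcidChange(codon[i], codonOffset[i]),
                            rd$change[i]))
    stopifnot(all(vapply(seq_len(n), function(i)
        baseAt(ref, position[i], strand[i]) == "C", logical(1))))
    sim
}
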