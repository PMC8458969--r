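## Differential editing between wild type and mutant across two
## developmental stages. Deltas are in percentage points of editing
## efficiency (wild type minus mutant); "affected" means a strict drop of
## more than `thresholdPoints` points.

#' Canonical sample layout for a two-genotype, two-stage comparison
#'
#' @param wtS1,wtS2,mutS1,mutS2 sample labels of the wild type and mutant
#'   at developmental stages 1 and 2.
#' @return Named character vector used by [deltaPoints()],
#'   [classifyEditing()].
#' @export
editingSamples <- function(wtS1 = "HD12_S1", wtS2 = "HD12_S2",
                           mutS1 = "Gmpgl2_S1", mutS2 = "Gmpgl2_S2") {
    c(wtS1 = wtS1, wtS2 = wtS2, mutS1 = mutS1, mutS2 = mutS2)
}

stageMatrix <- function(x, samples) {
    missing <- setdiff(unname(samples), sampleLabels(x))
    if (length(missing))
        stop("table lacks sample column(s): ", paste(missing, collapse = ", "))
    efficiencies(x)[, unname(samples), drop = FALSE]
}

#' Efficiency drop at one site and stage, in percentage points
#'
#' `100 * (wild type - mutant)` at the requested stage.
#'
#' @param x an [EditingTable-class].
#' @param gene,position site key.
#' @param stage 1 or 2.
#' @param samples sample layout, see [editingSamples()].
#' @return Numeric scalar in \[-100, 100\].
#' @examples
#' deltaPoints(loadTable1Fixture(), "rps16", 56313, stage = 1)  # 79.02
#' @export
deltaPoints <- function(x, gene, position, stage = 1L,
                        samples = editingSamples()) {
    eff <- stageMatrix(x, samples)
    rd <- rowData(x)
    i <- which(rd$gene == gene & rd$siteLabel == as.character(position))
    if (length(i) != 1L)
        stop("site not found (or duplicated): ", gene, "-", position)
    wtName <- samples[[if (stage == 1L) "wtS1" else "wtS2"]]
    mutName <- samples[[if (stage == 1L) "mutS1" else "mutS2"]]
    wt <- eff[i, wtName]
    mut <- eff[i, mutName]
    if (is.na(wt)) stop("missing efficiency for ", gene, "-", position,
                        " in sample ", wtName)
    if (is.na(mut)) stop("missing efficiency for ", gene, "-", position,
                         " in sample ", mutName)
    100 * (wt - mut)
}

#' Classify differential editing across two stages
#'
#' Stage 1 category: `decreased` when the stage-1 drop exceeds
#' `thresholdPoints` percentage points (strictly), else `unaffected`.
#' Stage 2 category, conditional on stage 1: a stage-1-decreased site is
#' `restored` when its stage-2 drop falls strictly below the threshold
#' and `still_decreased` when it strictly exceeds it; a
#' stage-1-unaffected site whose stage-2 drop strictly exceeds the
#' threshold is `newly_affected`; everything else is `unaffected`. Ties
#' at exactly the threshold are never called affected.
#'
#' @param x an [EditingTable-class] with the four canonical samples.
#' @param thresholdPoints strict threshold in percentage points.
#' @param samples sample layout, see [editingSamples()].
#' @return data.frame with one row per site: `key`, `gene`, `siteLabel`,
#'   `deltaS1`, `deltaS2` (points) and factors `categoryS1`
#'   (`decreased`/`unaffected`), `categoryS2` (`restored` /
#'   `newly_affected` / `still_decreased` / `unaffected`).
#' @export
classifyEditing <- function(x, thresholdPoints = 10,
                            samples = editingSamples()) {
    eff <- stageMatrix(x, samples)
    rd <- rowData(x)
    if (anyDuplicated(paste(rd$gene, rd$siteLabel)))
        stop("duplicated (gene, site) keys")
    if (anyNA(eff)) {
        bad <- which(is.na(eff), arr.ind = TRUE)[1L, ]
        stop("missing efficiency for site ", rownames(x)[bad[1L]],
             " in sample ", colnames(eff)[bad[2L]])
    }
    d1 <- 100 * (eff[, samples[["wtS1"]]] - eff[, samples[["mutS1"]]])
    d2 <- 100 * (eff[, samples[["wtS2"]]] - eff[, samples[["mutS2"]]])
    dec1 <- d1 > thresholdPoints
    cat2 <- ifelse(dec1 & d2 < thresholdPoints, "restored",
            ifelse(dec1 & d2 > thresholdPoints, "still_decreased",
            ifelse(!dec1 & d2 > thresholdPoints, "newly_affected",
                   "unaffected")))
    data.frame(
        key = rownames(x), gene = rd$gene, siteLabel = rd$siteLabel,
        deltaS1 = unname(d1), deltaS2 = unname(d2),
        categoryS1 = factor(ifelse(dec1, "decreased", "unaffected"),
                            c("decreased", "unaffected")),
        categoryS2 = factor(cat2, c("restored", "newly_affected",
                                    "still_decreased", "unaffected")),
        row.names = NULL, stringsAsFactors = FALSE)
}

#' Summarise a differential editing classification
#'
#' Aggregates [classifyEditing()] output and site annotation into the
#' counts a study of a plastid editing factor reports: total sites,
#' coding/non-coding breakdown with distinct gene counts, non-synonymous
#' sites and their substitution-type inventory, stage-1 decreased sites,
#' stage-2 restored/newly-affected sites, and the total stage-2 affected
#' set with its distinct gene count.
#'
#' @param records data.frame from [classifyEditing()].
#' @param x the [EditingTable-class] the records derive from.
#' @return A list of class `editingSummary`; see fields in the examples.
#' @examples
#' tab <- loadTable1Fixture()
#' summarizeEditing(classifyEditing(tab), tab)
#' @export
summarizeEditing <- function(records, x) {
    rd <- rowData(x)
    stopifnot(identical(records$key, rownames(x)))
    coding <- !is.na(rd$region) & rd$region == "CDS"
    nonsyn <- coding & rd$change != "Unchanged"
    dec1 <- records$categoryS1 == "decreased"
    restored <- records$categoryS2 == "restored"
    newly <- records$categoryS2 == "newly_affected"
    dec2 <- records$categoryS2 %in% c("still_decreased", "newly_affected")
    out <- list(
        nSites = nrow(x),
        nCoding = sum(coding),
        nCodingGenes = length(unique(rd$gene[coding])),
        regionCounts = table(factor(rd$region, REGION_LEVELS)),
        nNonsynonymous = sum(nonsyn),
        substitutionTypes = sort(unique(rd$change[nonsyn])),
        nDecreasedS1 = sum(dec1),
        decreasedS1 = records$key[dec1],
        nRestored = sum(restored),
        restored = records$key[restored],
        nNewlyAffected = sum(newly),
        newlyAffected = records$key[newly],
        nDecreasedS2 = sum(dec2),
        decreasedS2 = records$key[dec2],
        nDecreasedS2Genes = length(unique(records$gene[dec2])))
    class(out) <- "editingSummary"
    out
}

#' @export
print.editingSummary <- function(x, ...) {
    cat(sprintf("%d editing sites: %d coding (%d genes), %d non-coding\n",
                x$nSites, x$nCoding, x$nCodingGenes, x$nSites - x$nCoding))
    cat(sprintf("  non-synonymous: %d; substitution types (%d): %s\n",
                x$nNonsynonymous, length(x$substitutionTypes),
                paste(x$substitutionTypes, collapse = ", ")))
    cat(sprintf("  stage 1: %d sites decreased by more than threshold\n",
                x$nDecreasedS1))
    cat(sprintf("  stage 2: %d restored, %d newly affected, %d decreased in total (%d genes)\n",
                x$nRestored, x$nNewlyAffected, x$nDecreasedS2,
                x$nDecreasedS2Genes))
    invisible(x)
}

#' Write classification records and summary
#'
#' @param records data.frame from [classifyEditing()].
#' @param path output TSV.
#' @return Invisibly, `path`.
#' @export
writeComparison <- function(records, path) {
    writeDialect(records, path,
                 header = "differential editing classification")
    invisible(path)
}
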