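#' @export
setGeneric("geneRanges", function(x) standardGeneric("geneRanges"))

#' @export
setGeneric("exonRanges", function(x, gene = NULL) standardGeneric("exonRanges"))

#' @export
setGeneric("intronRanges", function(x, gene = NULL) standardGeneric("intronRanges"))

#' @export
setGeneric("efficiencies", function(x) standardGeneric("efficiencies"))

#' @export
setGeneric("siteKeys", function(x) standardGeneric("siteKeys"))

#' @export
setGeneric("sampleLabels", function(x) standardGeneric("sampleLabels"))

#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @export
setGeneric("sitePositions", function(x) standardGeneric("sitePositions"))

#' @export
setGeneric("siteStrands", function(x) standardGeneric("siteStrands"))

#' @export
setGeneric("regionLabels", function(x) standardGeneric("regionLabels"))

#' @export
setGeneric("aaChanges", function(x) standardGeneric("aaChanges"))

#' @export
setGeneric("motifTable", function(x) standardGeneric("motifTable"))

#' @export
setGeneric("nBindingMotifs", function(x) standardGeneric("nBindingMotifs"))

#' @export
setGeneric("extractCode", function(x) standardGeneric("extractCode"))

#' @export
setGeneric("permittedNucleotides", function(x, aa5, aaLast)
    standardGeneric("permittedNucleotides"))

#' @export
setGeneric("truthMatrix", function(x) standardGeneric("truthMatrix"))

#' @export
setGeneric("panelSites", function(x) standardGeneric("panelSites"))

#' @export
setGeneric("refSequence", function(x) standardGeneric("refSequence"))

#' @export
setGeneric("geneModels", function(x) standardGeneric("geneModels"))

#' @export
setGeneric("truthPanel", function(x) standardGeneric("truthPanel"))
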