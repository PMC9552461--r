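#' Sample identifiers
#' @param x an object holding samples in rows
#' @return character vector of sample ids
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))

#' Feature identifiers
#' @param x an object holding molecular features
#' @return character vector of feature ids
#' @export
setGeneric("featureIDs", function(x) standardGeneric("featureIDs"))

#' @export
setGeneric("featureCoords", function(x) standardGeneric("featureCoords"))

#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @export
setGeneric("snpCoords", function(x) standardGeneric("snpCoords"))

#' @export
setGeneric("mafs", function(x) standardGeneric("mafs"))

#' @export
setGeneric("cisMap", function(x) standardGeneric("cisMap"))

#' @export
setGeneric("pcScores", function(x) standardGeneric("pcScores"))

#' @export
setGeneric("pcLoadings", function(x) standardGeneric("pcLoadings"))

#' Proportion of variance explained per component
#' @param x a PCAResult
#' @export
setGeneric("pve", function(x) standardGeneric("pve"))

#' Selected number of components
#' @param x a KSelection
#' @export
setGeneric("selectedK", function(x) standardGeneric("selectedK"))

#' Per-component selection diagnostics
#' @param x a KSelection
#' @export
setGeneric("kDiagnostics", function(x) standardGeneric("kDiagnostics"))

#' Hidden components of an HCP fit
#' @param x an HCPFit
#' @export
setGeneric("hiddenComponents", function(x) standardGeneric("hiddenComponents"))

#' Objective values per coordinate-descent sweep
#' @param x an HCPFit
#' @export
setGeneric("objectiveTrace", function(x) standardGeneric("objectiveTrace"))

#' QTL result rows as a data.frame
#' @param x a QTLResultTable
#' @export
setGeneric("qtlTable", function(x) standardGeneric("qtlTable"))

#' Ground-truth causal pairs of a simulated dataset
#' @param x a SimulatedQTLData
#' @export
setGeneric("truePairs", function(x) standardGeneric("truePairs"))

#' Per-gene realized variance shares
#' @param x a SimulatedQTLData
#' @export
setGeneric("realizedPVE", function(x) standardGeneric("realizedPVE"))
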