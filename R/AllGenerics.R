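#' @include AllClasses.R
NULL

#' Extract the gene symbols of an object
#' @param x a GenePanel, FilteredSet, UniverseSpec or ExpressionSummary.
#' @return character vector of gene symbols.
#' @export
setGeneric("geneSymbols", function(x) standardGeneric("geneSymbols"))

#' Panel name accessor
#' @param x a GenePanel.
#' @return the panel name.
#' @export
setGeneric("panelName", function(x) standardGeneric("panelName"))

#' Provenance accessor
#' @param x a GenePanel.
#' @return the provenance data.frame.
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' Condition labels of an expression summary
#' @param x an ExpressionSummary.
#' @return character vector of condition labels.
#' @export
setGeneric("conditionLabels", function(x) standardGeneric("conditionLabels"))

#' Control condition label
#' @param x an ExpressionSummary.
#' @return the control condition label.
#' @export
setGeneric("controlLabel", function(x) standardGeneric("controlLabel"))

#' Venn region counts of an overlap decomposition
#' @param x an OverlapResult.
#' @return named numeric vector of the seven region counts.
#' @export
setGeneric("regionCounts", function(x) standardGeneric("regionCounts"))

#' Status counts of a screen result
#' @param x a ScreenResult.
#' @return named integer vector partitioning the panel.
#' @export
setGeneric("screenCounts", function(x) standardGeneric("screenCounts"))

#' Responsive gene set of a screen result
#' @param x a ScreenResult.
#' @return character vector of responsive symbols.
#' @export
setGeneric("responsiveGenes", function(x) standardGeneric("responsiveGenes"))

#' Result table of a tabular result object
#' @param x a ScreenResult, EnrichmentResult or OverlapResult.
#' @return a data.frame.
#' @export
setGeneric("resultTable", function(x) standardGeneric("resultTable"))
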