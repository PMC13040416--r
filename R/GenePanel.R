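#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a GenePanel
#'
#' @param name panel name.
#' @param genes character vector of symbols; duplicates are collapsed (their
#'   provenance rows are all kept).
#' @param provenance optional data.frame with a \code{symbol} column plus any
#'   source metadata (study, direction, original spelling). Defaults to one
#'   bare row per symbol.
#' @return a [GenePanel-class].
#' @examples
#' gp <- GenePanel("demo", c("ALAS2", "CA1"))
#' geneSymbols(gp)
#' @export
GenePanel <- function(name, genes, provenance = NULL) {
    genes <- as.character(genes)
    if (is.null(provenance))
        provenance <- data.frame(symbol = genes, stringsAsFactors = FALSE)
    new("GenePanel", name = name, genes = unique(genes),
        provenance = provenance)
}

#' @describeIn GenePanel number of genes in the panel.
#' @param x a GenePanel.
#' @export
setMethod("length", "GenePanel", function(x) length(x@genes))

#' @rdname geneSymbols
#' @export
setMethod("geneSymbols", "GenePanel", function(x) x@genes)

#' @rdname panelName
#' @export
setMethod("panelName", "GenePanel", function(x) x@name)

#' @rdname provenance
#' @export
setMethod("provenance", "GenePanel", function(x) x@provenance)

setMethod("show", "GenePanel", function(object) {
    cat("GenePanel '", object@name, "' with ", length(object@genes),
        " genes\n", sep = "")
    n <- min(6L, length(object@genes))
    if (n > 0L)
        cat("  ", paste(object@genes[seq_len(n)], collapse = ", "),
            if (length(object@genes) > n) ", ..." else "", "\n", sep = "")
})

## coercion helper used throughout: accept a GenePanel or a plain character
.asGeneSet <- function(x) {
    if (is(x, "GenePanel")) x@genes
    else if (is(x, "FilteredSet")) x@genes
    else unique(as.character(x))
}
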