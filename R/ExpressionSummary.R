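#' @include AllClasses.R AllGenerics.R
NULL

#' Construct an ExpressionSummary
#'
#' @param means,sds numeric matrices (genes x conditions) with rownames =
#'   gene symbols and colnames = condition labels.
#' @param p numeric vector of omnibus p-values, one per gene (NaN allowed).
#' @param control control condition label (default "inactivity").
#' @param values optional per-sample matrix (genes x samples).
#' @param sampleConditions condition label of each sample column.
#' @return an [ExpressionSummary-class].
#' @export
ExpressionSummary <- function(means, sds, p, control = "inactivity",
                              values = NULL, sampleConditions = NULL) {
    if (is.null(values)) {
        values <- matrix(numeric(), nrow = nrow(means), ncol = 0)
        sampleConditions <- character()
    }
    new("ExpressionSummary", genes = rownames(means),
        conditions = colnames(means), control = control,
        means = means, sds = sds, p = as.numeric(p), values = values,
        sampleConditions = sampleConditions)
}

#' @rdname geneSymbols
#' @export
setMethod("geneSymbols", "ExpressionSummary", function(x) x@genes)

#' @rdname conditionLabels
#' @export
setMethod("conditionLabels", "ExpressionSummary", function(x) x@conditions)

#' @rdname controlLabel
#' @export
setMethod("controlLabel", "ExpressionSummary", function(x) x@control)

#' @describeIn ExpressionSummary number of genes summarised.
#' @param x an ExpressionSummary.
#' @export
setMethod("length", "ExpressionSummary", function(x) length(x@genes))

setMethod("show", "ExpressionSummary", function(object) {
    cat("ExpressionSummary:", length(object@genes), "genes x",
        length(object@conditions), "conditions (control:",
        object@control, ")\n")
    cat("  NaN omnibus p:", sum(is.nan(object@p)), "genes;",
        "per-sample values:",
        if (ncol(object@values)) "attached" else "none", "\n")
})

#' Read / write the expression-summary TSV schema
#'
#' Columns: \code{gene}, then \code{<condition>_mean} and
#' \code{<condition>_sd} per condition, then \code{p}. The literal string
#' \code{NaN} in the p column is preserved as NaN through a round trip.
#'
#' @param path file path.
#' @param control control condition label.
#' @return `readExpressionSummary()` returns an [ExpressionSummary-class];
#'   `writeExpressionSummary()` returns `path` invisibly.
#' @export
readExpressionSummary <- function(path, control = "inactivity") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!"gene" %in% names(df) || !"p" %in% names(df))
        stop("summary table needs 'gene' and 'p' columns: ", path)
    mcols <- grep("_mean$", names(df), value = TRUE)
    conds <- sub("_mean$", "", mcols)
    scols <- paste0(conds, "_sd")
    if (!all(scols %in% names(df)))
        stop("missing '<condition>_sd' columns in ", path)
    means <- as.matrix(df[, mcols, drop = FALSE])
    sds <- as.matrix(df[, scols, drop = FALSE])
    dimnames(means) <- dimnames(sds) <- list(df$gene, conds)
    ExpressionSummary(means, sds, df$p, control = control)
}

#' @rdname readExpressionSummary
#' @param summary an [ExpressionSummary-class].
#' @export
writeExpressionSummary <- function(summary, path) {
    stopifnot(is(summary, "ExpressionSummary"))
    df <- data.frame(gene = summary@genes, stringsAsFactors = FALSE)
    for (cond in summary@conditions) {
        df[[paste0(cond, "_mean")]] <- summary@means[, cond]
        df[[paste0(cond, "_sd")]] <- summary@sds[, cond]
    }
    # write.table would render NaN as the NA string; the literal token
    # must survive the round trip
    df$p <- vapply(summary@p, function(v)
        if (is.nan(v)) "NaN" else format(v, digits = 15), character(1))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' In-package expression-summary fixture of the candidate EPO panel
#'
#' Convenience loader for the shipped GEPREP-style summary table of
#' candidate rHuEPO-responsive genes (condition-wise mean/SD of normalised
#' expression across five exercise modalities plus inactivity, and the
#' omnibus p with NaN entries).
#'
#' @return an [ExpressionSummary-class].
#' @export
geprepSummaryFixture <- function() {
    readExpressionSummary(system.file("extdata", "geprep_summary.tsv",
                                      package = "epoScreen",
                                      mustWork = TRUE))
}
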