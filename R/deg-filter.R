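#' @include AllClasses.R AllGenerics.R GenePanel.R
NULL

#' Construct a ThresholdConfig
#'
#' Exactly one of \code{minAbsFc} (linear fold change) or
#' \code{minAbsLog2fc} must be given; a linear bound is converted to the
#' log2 scale internally so both forms are treated identically.
#'
#' @param studyId study label.
#' @param minAbsFc linear fold-change bound (e.g. 1.2), or NULL.
#' @param minAbsLog2fc log2 fold-change bound (e.g. 0.5), or NULL.
#' @param fcInclusive effect bound inclusive (>=, default) or strict (>).
#' @param maxAdjP adjusted-p bound; NA when the study applied none.
#' @param adjPInclusive p bound inclusive (<=, default) or strict (<).
#' @param twoSided apply the bound to |log2FC| (default TRUE); set FALSE
#'   for a strictly one-sided (up-regulation only) reading.
#' @return a [ThresholdConfig-class].
#' @export
ThresholdConfig <- function(studyId, minAbsFc = NULL, minAbsLog2fc = NULL,
                            fcInclusive = TRUE, maxAdjP = NA_real_,
                            adjPInclusive = TRUE, twoSided = TRUE) {
    if (is.null(minAbsFc) == is.null(minAbsLog2fc))
        stop("give exactly one of minAbsFc or minAbsLog2fc")
    if (!is.null(minAbsFc)) {
        if (minAbsFc <= 0) stop("linear fold change must be > 0")
        bound <- log2(minAbsFc); scale <- "linear"
    } else {
        bound <- minAbsLog2fc; scale <- "log2"
    }
    new("ThresholdConfig", studyId = studyId, minAbsLog2fc = bound,
        effectScale = scale, fcInclusive = fcInclusive,
        maxAdjP = as.numeric(maxAdjP), adjPInclusive = adjPInclusive,
        twoSided = twoSided)
}

setMethod("show", "ThresholdConfig", function(object) {
    cat("ThresholdConfig '", object@studyId, "': ",
        if (object@twoSided) "|log2FC|" else "log2FC",
        if (object@fcInclusive) " >= " else " > ",
        signif(object@minAbsLog2fc, 4),
        if (!is.na(object@maxAdjP))
            paste0(", adj p", if (object@adjPInclusive) " <= " else " < ",
                   object@maxAdjP) else ", no p criterion",
        "\n", sep = "")
})

#' Published per-study DEG thresholds
#'
#' The three reproducible altitude studies' author-defined cut-offs, with
#' the printed operator's inclusivity respected exactly:
#' \describe{
#'   \item{sutehall}{linear FC >= 1.2 and FDR <= 5\% (both inclusive).}
#'   \item{pham}{|log2FC| >= 1 (FC >= 2); no p criterion was printed.}
#'   \item{manella}{adjusted p (q) < 0.01 and |log2FC| > 0.5 (both
#'     strict).}
#' }
#' All are applied two-sided by default (down-regulation included).
#'
#' @param study one of "sutehall", "pham", "manella".
#' @return a [ThresholdConfig-class].
#' @export
studyThresholds <- function(study = c("sutehall", "pham", "manella")) {
    switch(match.arg(study),
        sutehall = ThresholdConfig("sutehall", minAbsFc = 1.2,
            fcInclusive = TRUE, maxAdjP = 0.05, adjPInclusive = TRUE),
        pham = ThresholdConfig("pham", minAbsLog2fc = 1,
            fcInclusive = TRUE, maxAdjP = NA_real_),
        manella = ThresholdConfig("manella", minAbsLog2fc = 0.5,
            fcInclusive = FALSE, maxAdjP = 0.01, adjPInclusive = FALSE))
}

## canonical DEG columns: gene, fc, log2fc, base_mean, lfcSE, stat, p,
## p_adj, contrast. Returns log2fc, deriving it from fc when needed.
.rowLog2fc <- function(rows) {
    l2 <- if ("log2fc" %in% names(rows)) rows$log2fc
          else rep(NA_real_, nrow(rows))
    fc <- if ("fc" %in% names(rows)) rows$fc else rep(NA_real_, nrow(rows))
    use <- is.na(l2) & !is.na(fc)
    if (any(!is.na(fc) & fc <= 0))
        stop("linear fold changes must be > 0")
    # snap the 1-ulp noise of the fc -> log2 conversion so a bound stated
    # on either scale treats equivalent rows identically
    l2[use] <- signif(log2(fc[use]), 12)
    if (any(is.na(l2)))
        stop("row lacks both fc and log2fc")
    l2
}

.rowsPass <- function(rows, config) {
    l2 <- .rowLog2fc(rows)
    eff <- if (config@twoSided) abs(l2) else l2
    passEffect <- if (config@fcInclusive) eff >= config@minAbsLog2fc
                  else eff > config@minAbsLog2fc
    if (is.na(config@maxAdjP)) return(passEffect)
    padj <- if ("p_adj" %in% names(rows)) rows$p_adj
            else rep(NA_real_, nrow(rows))
    passP <- !is.na(padj) &
        (if (config@adjPInclusive) padj <= config@maxAdjP
         else padj < config@maxAdjP)
    passEffect & passP
}

#' Does one differential-expression row pass a study's cut-offs?
#'
#' Linear and log2 effect fields are interchangeable (log2fc = log2(fc));
#' a row missing the adjusted p when the study requires one fails. The
#' inclusivity of each bound follows the study's printed operator.
#'
#' @param row a one-row data.frame or named list with canonical fields
#'   (\code{gene}, \code{fc} and/or \code{log2fc}, optional \code{p},
#'   \code{p_adj}, \code{contrast}).
#' @param config a [ThresholdConfig-class].
#' @return TRUE/FALSE.
#' @examples
#' rowPasses(list(log2fc = 0.5, p_adj = 0.005), studyThresholds("manella"))
#' # FALSE: the 0.5 bound is strict
#' @export
rowPasses <- function(row, config) {
    stopifnot(is(config, "ThresholdConfig"))
    rows <- as.data.frame(row[!vapply(row, is.null, logical(1))],
                          stringsAsFactors = FALSE)
    .rowsPass(rows, config)
}

#' Filter a DEG table by a study's thresholds
#'
#' @param table data.frame in canonical DEG columns (see
#'   [readDegTable()]).
#' @param config a [ThresholdConfig-class].
#' @return a [FilteredSet-class]: the duplicate-free set of passing genes,
#'   with a per-contrast breakdown when the table has a contrast column.
#' @export
filterDegTable <- function(table, config) {
    stopifnot(is(config, "ThresholdConfig"))
    if (nrow(table) == 0L)
        return(new("FilteredSet", studyId = config@studyId,
                   genes = character(), contrasts = list()))
    pass <- .rowsPass(table, config)
    genes <- unique(table$gene[pass])
    contrasts <- list()
    if ("contrast" %in% names(table) && any(!is.na(table$contrast))) {
        keep <- pass & !is.na(table$contrast)
        contrasts <- lapply(split(table$gene[keep], table$contrast[keep]),
                            unique)
    }
    new("FilteredSet", studyId = config@studyId, genes = genes,
        contrasts = contrasts)
}

#' @rdname geneSymbols
#' @export
setMethod("geneSymbols", "FilteredSet", function(x) x@genes)

setMethod("show", "FilteredSet", function(object) {
    cat("FilteredSet '", object@studyId, "': ", length(object@genes),
        " genes", sep = "")
    if (length(object@contrasts))
        cat(" across ", length(object@contrasts), " contrasts", sep = "")
    cat("\n")
})

#' Aggregate altitude-responsive genes across studies
#'
#' Builds the hypoxia-responsive union panel from per-study filtered sets,
#' plus the per-study TRUE/FALSE presence matrix with the
#' number-of-studies column.
#'
#' @param sets list of [FilteredSet-class] objects (or character vectors);
#'   names default to the study ids.
#' @param name name for the union panel.
#' @return list with \code{panel} (a [GenePanel-class]) and
#'   \code{presence} (data.frame: gene, one logical column per study,
#'   \code{n_altitude_studies}).
#' @export
altitudeUnion <- function(sets, name = "altitude_union") {
    if (is.null(names(sets)) || any(!nzchar(names(sets))))
        names(sets) <- vapply(seq_along(sets), function(i) {
            s <- sets[[i]]
            if (is(s, "FilteredSet")) s@studyId else paste0("study", i)
        }, character(1))
    lists <- lapply(sets, .asGeneSet)
    genes <- sort(unique(unlist(lists, use.names = FALSE)))
    presence <- data.frame(gene = genes, stringsAsFactors = FALSE)
    for (s in names(lists)) presence[[s]] <- genes %in% lists[[s]]
    presence$n_altitude_studies <-
        rowSums(as.matrix(presence[, names(lists), drop = FALSE]))
    prov <- do.call(rbind, lapply(names(lists), function(s)
        data.frame(symbol = lists[[s]], source = s,
                   stringsAsFactors = FALSE)))
    list(panel = GenePanel(name, genes, provenance = prov),
         presence = presence)
}
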