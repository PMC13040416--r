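#' @include AllClasses.R AllGenerics.R GenePanel.R
NULL

#' Construct an AnnotationSet
#'
#' @param terms named list, term id -> character vector of member genes.
#' @param termNames optional named character of descriptions (defaults to
#'   the ids).
#' @return an [AnnotationSet-class].
#' @export
AnnotationSet <- function(terms, termNames = NULL) {
    terms <- lapply(terms, function(g) unique(as.character(g)))
    if (is.null(termNames))
        termNames <- stats::setNames(names(terms), names(terms))
    new("AnnotationSet", terms = terms, termNames = termNames)
}

#' @describeIn AnnotationSet number of terms.
#' @param x an AnnotationSet.
#' @export
setMethod("length", "AnnotationSet", function(x) length(x@terms))

setMethod("show", "AnnotationSet", function(object) {
    sz <- lengths(object@terms)
    cat("AnnotationSet with", length(object@terms), "terms; sizes",
        min(sz), "-", max(sz), "\n")
})

#' Read / write GMT gene-set files
#'
#' Standard tab-separated GMT: term id, description, then member genes.
#' Duplicate term ids are an error (the duplicate is named).
#'
#' @param path file path.
#' @return `readGmt()` returns an [AnnotationSet-class]; `writeGmt()`
#'   returns `path` invisibly.
#' @export
readGmt <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    short <- vapply(parts, length, integer(1)) < 3L
    if (any(short))
        stop("malformed GMT row (need id, description, >=1 gene) at line ",
             which(short)[1L], " of ", path)
    ids <- vapply(parts, `[[`, character(1), 1L)
    if (anyDuplicated(ids))
        stop("duplicate GMT term id: ", ids[duplicated(ids)][1L])
    terms <- lapply(parts, function(p) p[-c(1L, 2L)])
    names(terms) <- ids
    AnnotationSet(terms,
        stats::setNames(vapply(parts, `[[`, character(1), 2L), ids))
}

#' @rdname readGmt
#' @param annotation an [AnnotationSet-class].
#' @export
writeGmt <- function(annotation, path) {
    stopifnot(is(annotation, "AnnotationSet"))
    lines <- vapply(names(annotation@terms), function(id)
        paste(c(id, annotation@termNames[[id]], annotation@terms[[id]]),
              collapse = "\t"), character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Upper-tail hypergeometric probability
#'
#' \eqn{P(X \ge k)} for X ~ Hypergeometric(N, K, n): the probability of
#' drawing at least k annotated genes when n genes are drawn without
#' replacement from a universe of N genes of which K are annotated.
#' Evaluated through the log-space survival function for numerical
#' stability. Vectorised over all arguments.
#'
#' @param k observed overlap (input genes in the term).
#' @param K universe genes in the term.
#' @param n input-set size.
#' @param N universe size.
#' @return the upper-tail probability.
#' @examples
#' hypergeomUpperTail(4, 4, 5, 10)   # 6/252
#' @export
hypergeomUpperTail <- function(k, K, n, N) {
    bad <- k < 0 | K < 0 | n < 0 | K > N | n > N | k > pmin(n, K)
    if (any(bad))
        stop("hypergeometric bounds violated: need 0 <= k <= min(n, K), ",
             "K <= N, n <= N")
    exp(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE,
                      log.p = TRUE))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement; the mapping back
#' to input positions is order-preserving (delegated to
#' [stats::p.adjust()]).
#'
#' @param pvalues numeric vector of p-values in [0, 1].
#' @return adjusted p-values, same order as the input.
#' @export
bhAdjust <- function(pvalues) {
    if (any(is.na(pvalues)) ||
        any(pvalues < 0 | pvalues > 1))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(pvalues, method = "BH")
}

## Storey-style q-values with a single fixed lambda; optional alternative
## to the default BH q column.
.storeyQ <- function(p, lambda = 0.5) {
    pi0 <- min(1, mean(p > lambda) / (1 - lambda))
    pmin(1, pi0 * stats::p.adjust(p, method = "BH"))
}

#' Build a background universe
#'
#' The measured mode restricts the background to the genes actually
#' detected/tested in the source experiment (the honest testable space);
#' the genome mode uses a full annotation table's gene set, the
#' conventional fallback when no measured background exists.
#'
#' @param mode "measured" or "genome".
#' @param genes character vector of universe genes (measured mode), or for
#'   genome mode either a character vector or a data.frame with a
#'   \code{symbol} column (e.g. a symbol/biotype genome table).
#' @return a [UniverseSpec-class].
#' @export
buildUniverse <- function(mode = c("measured", "genome"), genes) {
    mode <- match.arg(mode)
    if (is.data.frame(genes)) {
        if (!"symbol" %in% names(genes))
            stop("genome table needs a 'symbol' column")
        genes <- genes$symbol
    }
    genes <- unique(as.character(genes))
    if (length(genes) == 0L) stop("universe source must be non-empty")
    new("UniverseSpec", mode = mode, genes = genes)
}

#' @rdname geneSymbols
#' @export
setMethod("geneSymbols", "UniverseSpec", function(x) x@genes)

setMethod("show", "UniverseSpec", function(object) {
    cat("UniverseSpec (", object@mode, "): N = ",
        length(object@genes), "\n", sep = "")
})

#' Over-representation analysis of a gene set
#'
#' Hypergeometric upper-tail test of every annotation term against a
#' background universe, with Benjamini-Hochberg adjustment, fold
#' enrichment ((k/n)/(K/N)) and rich factor (k/K). Input genes carrying an
#' excluded biotype (e.g. pseudogenes) are removed before testing, as are
#' genes outside the universe (dropped with a warning, never an error).
#' Terms are restricted to their universe members; terms with no universe
#' member are skipped. Results are sorted by (pvalue, ID) -- a total
#' ordering.
#'
#' @param genes input gene set (character or [GenePanel-class]).
#' @param annotation an [AnnotationSet-class].
#' @param universe a [UniverseSpec-class].
#' @param excludeBiotypes biotypes to drop from the input (requires
#'   \code{biotypes}).
#' @param biotypes optional data.frame(symbol, biotype) used for the
#'   exclusion.
#' @param qMethod "BH" (default: q equals the BH-adjusted p) or "storey"
#'   (single fixed-lambda pi0 estimate).
#' @param withZ also report a normal-approximation z-score
#'   (k - nK/N) / sd; a descriptive extra, not part of the test.
#' @param minTermSize,maxTermSize optional term-size window (defaults: no
#'   filtering).
#' @return an [EnrichmentResult-class].
#' @export
enrich <- function(genes, annotation, universe,
                   excludeBiotypes = character(), biotypes = NULL,
                   qMethod = c("BH", "storey"), withZ = FALSE,
                   minTermSize = 0L, maxTermSize = Inf) {
    qMethod <- match.arg(qMethod)
    stopifnot(is(annotation, "AnnotationSet"), is(universe, "UniverseSpec"))
    input <- .asGeneSet(genes)
    excludedByBiotype <- character()
    if (length(excludeBiotypes)) {
        if (is.null(biotypes))
            stop("excludeBiotypes requires a 'biotypes' table")
        bad <- biotypes$symbol[biotypes$biotype %in% excludeBiotypes]
        excludedByBiotype <- intersect(input, bad)
        input <- setdiff(input, bad)
    }
    mapped <- intersect(input, universe@genes)
    droppedOutside <- setdiff(input, mapped)
    if (length(droppedOutside))
        warning(length(droppedOutside),
                " input gene(s) outside the universe were dropped")
    n <- length(mapped)
    if (n == 0L) stop("no input genes map into the universe")
    N <- length(universe@genes)

    rows <- lapply(names(annotation@terms), function(id) {
        termU <- intersect(annotation@terms[[id]], universe@genes)
        K <- length(termU)
        if (K == 0L || K < minTermSize || K > maxTermSize) return(NULL)
        hits <- intersect(mapped, termU)
        k <- length(hits)
        data.frame(ID = id, Description = annotation@termNames[[id]],
                   k = k, n = n, K = K, N = N,
                   GeneRatio = paste0(k, "/", n),
                   BgRatio = paste0(K, "/", N),
                   RichFactor = k / K,
                   FoldEnrichment = (k / n) / (K / N),
                   pvalue = hypergeomUpperTail(k, K, n, N),
                   geneID = paste(sort(hits), collapse = "/"),
                   Count = k, stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    if (is.null(tab))
        stop("no annotation term intersects the universe")
    tab$p.adjust <- bhAdjust(tab$pvalue)
    tab$qvalue <- if (qMethod == "BH") tab$p.adjust
                  else .storeyQ(tab$pvalue)
    if (withZ) {
        pK <- tab$K / tab$N
        v <- tab$n * pK * (1 - pK) * (tab$N - tab$n) / (tab$N - 1)
        tab$zscore <- ifelse(v > 0, (tab$k - tab$n * pK) / sqrt(v),
                             NA_real_)
    }
    tab <- tab[order(tab$pvalue, tab$ID), , drop = FALSE]
    rownames(tab) <- NULL
    new("EnrichmentResult", table = tab, nInput = as.integer(n),
        mapped = mapped,
        unmapped = c(excludedByBiotype, droppedOutside),
        universe = universe)
}

#' @rdname resultTable
#' @export
setMethod("resultTable", "EnrichmentResult", function(x) x@table)

setMethod("show", "EnrichmentResult", function(object) {
    cat("EnrichmentResult:", nrow(object@table), "terms tested;",
        sum(object@table$p.adjust <= 0.05), "with adjusted p <= 0.05\n")
    cat("  input n =", object@nInput, "mapped (",
        length(object@unmapped), "dropped ), universe N =",
        length(object@universe@genes), "(", object@universe@mode, ")\n")
})

#' Write an enrichment table in the standard column layout
#'
#' @param result an [EnrichmentResult-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeEnrichment <- function(result, path) {
    stopifnot(is(result, "EnrichmentResult"))
    cols <- c("ID", "Description", "GeneRatio", "BgRatio", "RichFactor",
              "FoldEnrichment", "pvalue", "p.adjust", "qvalue", "geneID",
              "Count")
    if ("zscore" %in% names(result@table)) cols <- c(cols, "zscore")
    utils::write.table(result@table[, cols], path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}
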