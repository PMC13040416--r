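#' @include AllClasses.R AllGenerics.R GenePanel.R
NULL

#' Construct a ScreenConfig
#'
#' Defaults follow the screening rule used throughout the package: a gene
#' is exercise-responsive when its omnibus p is below 0.05 *or* NaN
#' (non-computable because of zero within-group variance) and at least one
#' exercise modality shows |Cohen's d| >= 0.5 against the sedentary
#' control. Set \code{gateOnP = FALSE} to apply the effect-size rule
#' irrespective of significance.
#'
#' @param alpha significance level (default 0.05).
#' @param dThreshold |d| cut-off (default 0.5).
#' @param controlLabel control condition (default "inactivity").
#' @param gateOnP gate effects on the p rule (default TRUE).
#' @param alphaInclusive use p <= alpha instead of the default strict
#'   p < alpha.
#' @param undefinedIsHit count an undefined d (both SDs zero, means
#'   differing) as a threshold hit (default FALSE).
#' @return a [ScreenConfig-class].
#' @export
ScreenConfig <- function(alpha = 0.05, dThreshold = 0.5,
                         controlLabel = "inactivity", gateOnP = TRUE,
                         alphaInclusive = FALSE, undefinedIsHit = FALSE) {
    new("ScreenConfig", alpha = alpha, dThreshold = dThreshold,
        controlLabel = controlLabel, gateOnP = gateOnP,
        alphaInclusive = alphaInclusive, undefinedIsHit = undefinedIsHit)
}

setMethod("show", "ScreenConfig", function(object) {
    cat("ScreenConfig: ",
        if (object@gateOnP) sprintf("p %s %g or NaN, ",
            if (object@alphaInclusive) "<=" else "<", object@alpha)
        else "no p gate, ",
        "|d| >= ", object@dThreshold, " vs '", object@controlLabel,
        "'\n", sep = "")
})

#' Cohen's d from summary statistics
#'
#' Standardized mean difference with the equal-weight pooled SD,
#' \eqn{d = (m_a - m_b) / \sqrt{(s_a^2 + s_b^2)/2}}. Group sizes are not
#' required (the source database does not expose them), so the pooling is
#' unweighted. When both SDs are zero: equal means give d = 0; differing
#' means give NaN (the undefined flag; its sign is recoverable from the
#' mean difference, see [effectSizes()]).
#'
#' @param meanA,sdA mean and SD of the comparison group.
#' @param meanB,sdB mean and SD of the reference group.
#' @return numeric vector of d values (NaN where undefined).
#' @examples
#' cohensD(3.36, 4.32, 0.72, 1.97)   # ~0.79
#' @export
cohensD <- function(meanA, sdA, meanB, sdB) {
    if (any(sdA < 0, na.rm = TRUE) || any(sdB < 0, na.rm = TRUE))
        stop("standard deviations must be >= 0")
    pooled <- sqrt((sdA^2 + sdB^2) / 2)
    diff <- meanA - meanB
    d <- diff / pooled
    zero <- pooled == 0
    # both SDs zero: identical constants are a true null, not an error
    d[zero & diff == 0] <- 0
    d[zero & diff != 0] <- NaN
    d
}

#' Kruskal-Wallis omnibus rank test
#'
#' Standard tie-corrected H statistic with the chi-squared approximation
#' for p (delegated to [stats::kruskal.test()]). When every observation
#' across every group is identical the tie correction denominator is zero
#' and both the statistic and p are NaN -- the "non-computable p" state the
#' screening rule treats as a pass-through to the effect-size criterion.
#'
#' @param groups list of >= 2 numeric vectors (>= 1 value each).
#' @return list with \code{statistic} and \code{p.value} (both NaN for
#'   all-constant input).
#' @export
kruskalWallis <- function(groups) {
    if (!is.list(groups) || length(groups) < 2L)
        stop("need at least 2 groups")
    if (any(lengths(groups) < 1L))
        stop("every group needs at least one value")
    x <- unlist(groups, use.names = FALSE)
    g <- factor(rep(seq_along(groups), lengths(groups)))
    kt <- stats::kruskal.test(x, g)
    list(statistic = unname(kt$statistic), p.value = kt$p.value)
}

#' Per-modality effect sizes of an expression summary
#'
#' One record per gene and non-control condition, computed strictly from
#' the summary means and SDs (never from per-sample values, so results are
#' identical whether or not raw values are attached).
#'
#' @param summary an [ExpressionSummary-class].
#' @param config a [ScreenConfig-class]; its \code{controlLabel} selects
#'   the reference condition.
#' @return data.frame with columns gene, modality, d, undefined (logical)
#'   and direction (sign of the mean difference, informative when d is
#'   undefined).
#' @export
effectSizes <- function(summary, config = ScreenConfig()) {
    stopifnot(is(summary, "ExpressionSummary"))
    ctl <- config@controlLabel
    if (!ctl %in% summary@conditions)
        stop("control condition '", ctl, "' missing from summary")
    mods <- setdiff(summary@conditions, ctl)
    if (length(mods) == 0L)
        return(data.frame(gene = character(), modality = character(),
                          d = numeric(), undefined = logical(),
                          direction = numeric()))
    out <- do.call(rbind, lapply(mods, function(m) {
        d <- cohensD(summary@means[, m], summary@sds[, m],
                     summary@means[, ctl], summary@sds[, ctl])
        data.frame(gene = summary@genes, modality = m, d = d,
                   undefined = is.nan(d),
                   direction = sign(summary@means[, m] -
                                    summary@means[, ctl]),
                   stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
}

.pStatus <- function(p, config) {
    # NA and NaN are both "no computable p" for a gene that is present
    if (is.na(p)) return("nan_p")
    sig <- if (config@alphaInclusive) p <= config@alpha else p < config@alpha
    if (sig) "significant" else "not_significant"
}

#' Classify one gene under the screening rule
#'
#' Status comes from the omnibus p (significant / nan_p / not_significant /
#' missing). The gene is responsive when the p gate is open (significant or
#' NaN when \code{gateOnP}; always when not) and at least one modality
#' reaches the |d| threshold. Undefined d counts as a hit only when the
#' config allows it.
#'
#' @param p omnibus p-value (may be NaN).
#' @param records effect-size rows for this gene (as from [effectSizes()]).
#' @param present is the gene present in the expression resource at all?
#' @param config a [ScreenConfig-class].
#' @return list with \code{status}, \code{responsive} and
#'   \code{hitModalities}.
#' @export
classifyGene <- function(p, records, present = TRUE,
                         config = ScreenConfig()) {
    if (!present)
        return(list(status = "missing", responsive = FALSE,
                    hitModalities = character()))
    status <- .pStatus(p, config)
    hit <- (!records$undefined & abs(records$d) >= config@dThreshold) |
           (records$undefined & config@undefinedIsHit)
    hits <- records$modality[hit]
    gate <- if (config@gateOnP) status %in% c("significant", "nan_p")
            else TRUE
    list(status = status, responsive = gate && length(hits) > 0L,
         hitModalities = hits)
}

#' Screen a candidate panel for exercise responsiveness
#'
#' Applies [classifyGene()] to every panel gene against an expression
#' summary. Genes absent from the summary are counted "missing"; the four
#' status counts always partition the panel.
#'
#' @param panel a [GenePanel-class] or character vector (must be
#'   duplicate-free, i.e. harmonised first).
#' @param summary an [ExpressionSummary-class].
#' @param config a [ScreenConfig-class].
#' @return a [ScreenResult-class].
#' @export
screenPanel <- function(panel, summary, config = ScreenConfig()) {
    symbols <- if (is(panel, "GenePanel")) panel@genes
               else as.character(panel)
    if (anyDuplicated(symbols))
        stop("panel contains duplicate symbols; harmonise it first")
    stopifnot(is(summary, "ExpressionSummary"))
    es <- effectSizes(summary, config)
    mods <- setdiff(summary@conditions, config@controlLabel)
    p <- stats::setNames(summary@p, summary@genes)

    rows <- lapply(symbols, function(g) {
        present <- g %in% summary@genes
        rec <- es[es$gene == g, , drop = FALSE]
        cls <- classifyGene(if (present) p[[g]] else NA_real_, rec,
                            present, config)
        dvals <- stats::setNames(rep(NA_real_, length(mods)), mods)
        if (present) dvals[rec$modality] <- rec$d
        c(list(gene = g, status = cls$status,
               responsive = cls$responsive,
               hit_modalities = paste(cls$hitModalities, collapse = ","),
               max_abs_d = if (all(is.na(dvals) | is.nan(dvals)))
                   NA_real_ else max(abs(dvals[!is.nan(dvals)]),
                                     na.rm = TRUE)),
          as.list(dvals))
    })
    tab <- do.call(rbind, lapply(rows, function(r)
        as.data.frame(r, stringsAsFactors = FALSE)))
    counts <- stats::setNames(integer(4),
        c("significant", "nan_p", "not_significant", "missing"))
    tc <- table(tab$status)
    counts[names(tc)] <- as.integer(tc)
    new("ScreenResult", table = tab, counts = counts,
        responsive = tab$gene[tab$responsive], config = config)
}

#' @rdname resultTable
#' @export
setMethod("resultTable", "ScreenResult", function(x) x@table)

#' @rdname screenCounts
#' @export
setMethod("screenCounts", "ScreenResult", function(x) x@counts)

#' @rdname responsiveGenes
#' @export
setMethod("responsiveGenes", "ScreenResult", function(x) x@responsive)

setMethod("show", "ScreenResult", function(object) {
    cat("ScreenResult over", nrow(object@table), "panel genes\n")
    print(object@counts)
    cat("responsive:", length(object@responsive), "genes\n")
})
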