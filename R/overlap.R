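#' @include AllClasses.R AllGenerics.R GenePanel.R deg-filter.R
NULL

.regionLabel <- function(a, b, c, names3) {
    key <- paste(names3[c(a, b, c)], collapse = "&")
    if (!nzchar(key)) stop("gene belongs to no set")  # cannot happen
    key
}

.regionNames <- function(names3) {
    c(names3[1], names3[2], names3[3],
      paste(names3[1], names3[2], sep = "&"),
      paste(names3[1], names3[3], sep = "&"),
      paste(names3[2], names3[3], sep = "&"),
      paste(names3, collapse = "&"))
}

#' Two-step overlap of a candidate panel with its confounder sets
#'
#' Step 1 aggregates the per-study altitude sets into one
#' hypoxia-responsive union; step 2 decomposes candidate vs altitude vs
#' exercise membership into the seven exclusive Venn regions (each gene
#' falls in exactly one; counts sum to the union of the three sets).
#' When per-study altitude sets are supplied, the candidate-altitude
#' overlap is additionally attributed to study intersection patterns via
#' [studyAttribution()].
#'
#' @param epo candidate panel: a [GenePanel-class] or character vector
#'   (must be non-empty).
#' @param altitudeSets a list of per-study [FilteredSet-class] objects /
#'   character vectors, or a single pre-built union set.
#' @param exercise the exercise-responsive set ([GenePanel-class],
#'   [ScreenResult-class] or character vector).
#' @param setNames labels for the three sets in the region names.
#' @return an [OverlapResult-class].
#' @examples
#' ov <- twoStepOverlap(GenePanel("epo", paste0("g", 1:5)),
#'                      list(alt = paste0("g", 4:8)),
#'                      paste0("g", 5:6))
#' regionCounts(ov)
#' @export
twoStepOverlap <- function(epo, altitudeSets, exercise,
                           setNames = c("epo", "altitude", "exercise")) {
    a <- .asGeneSet(epo)
    if (length(a) == 0L) stop("candidate (EPO) panel must be non-empty")
    perStudy <- NULL
    if (is.list(altitudeSets) && !is.data.frame(altitudeSets)) {
        u <- altitudeUnion(altitudeSets)
        b <- geneSymbols(u$panel)
        perStudy <- lapply(altitudeSets, .asGeneSet)
        names(perStudy) <- names(u$presence)[
            !names(u$presence) %in% c("gene", "n_altitude_studies")]
    } else {
        b <- .asGeneSet(altitudeSets)
    }
    cc <- if (is(exercise, "ScreenResult")) exercise@responsive
          else .asGeneSet(exercise)

    genes <- sort(unique(c(a, b, cc)))
    inA <- genes %in% a; inB <- genes %in% b; inC <- genes %in% cc
    region <- vapply(seq_along(genes), function(i)
        .regionLabel(inA[i], inB[i], inC[i], setNames), character(1))
    membership <- data.frame(gene = genes, stringsAsFactors = FALSE)
    membership[[setNames[1]]] <- inA
    membership[[setNames[2]]] <- inB
    membership[[setNames[3]]] <- inC
    membership$region <- region
    counts <- stats::setNames(numeric(7), .regionNames(setNames))
    tc <- table(region)
    counts[names(tc)] <- as.numeric(tc)

    attribution <- data.frame()
    overlapAB <- intersect(a, b)
    if (!is.null(perStudy) && length(overlapAB))
        attribution <- studyAttribution(overlapAB, perStudy)
    new("OverlapResult", setNames = setNames, regionCounts = counts,
        membership = membership, attribution = attribution)
}

#' @rdname regionCounts
#' @export
setMethod("regionCounts", "OverlapResult", function(x) x@regionCounts)

#' @rdname resultTable
#' @export
setMethod("resultTable", "OverlapResult", function(x) x@membership)

setMethod("show", "OverlapResult", function(object) {
    cat("OverlapResult (", paste(object@setNames, collapse = " / "),
        "), union of ", nrow(object@membership), " genes\n", sep = "")
    print(object@regionCounts)
})

#' Derive the confounder-free candidate panel
#'
#' Candidate genes touched by neither the altitude union nor the exercise
#' set: \code{epo \ (altitude U exercise)}. Provenance of the surviving
#' genes is preserved.
#'
#' @param epo candidate [GenePanel-class] (or character vector).
#' @param altitude altitude union ([GenePanel-class], [FilteredSet-class]
#'   or character vector).
#' @param exercise exercise set (same forms, or a [ScreenResult-class]).
#' @param name name for the derived panel.
#' @return a [GenePanel-class].
#' @export
deriveUniquePanel <- function(epo, altitude, exercise,
                              name = "epo_unique") {
    a <- .asGeneSet(epo)
    b <- .asGeneSet(altitude)
    cc <- if (is(exercise, "ScreenResult")) exercise@responsive
          else .asGeneSet(exercise)
    keep <- setdiff(a, union(b, cc))
    prov <- if (is(epo, "GenePanel")) {
        pr <- provenance(epo)
        pr[pr$symbol %in% keep, , drop = FALSE]
    } else NULL
    GenePanel(name, keep, provenance = prov)
}

#' Attribute overlap genes to study intersection patterns
#'
#' Partitions a set of overlap genes by which per-study sets contain them:
#' unique-to-one-study categories plus every pairwise and higher sharing
#' pattern. Categories are exclusive and exhaustive, so counts sum to the
#' overlap size; zero-count patterns are reported too.
#'
#' @param overlapGenes character vector of genes to attribute.
#' @param perStudySets named list of per-study gene sets; together they
#'   must cover every overlap gene (else a consistency error).
#' @return data.frame with columns \code{category}, \code{studies},
#'   \code{count} and \code{genes} (comma-collapsed).
#' @export
studyAttribution <- function(overlapGenes, perStudySets) {
    overlapGenes <- unique(as.character(overlapGenes))
    sets <- lapply(perStudySets, .asGeneSet)
    if (is.null(names(sets)) || any(!nzchar(names(sets))))
        stop("perStudySets must be named")
    memb <- vapply(sets, function(s) overlapGenes %in% s,
                   logical(length(overlapGenes)))
    memb <- matrix(memb, nrow = length(overlapGenes),
                   dimnames = list(overlapGenes, names(sets)))
    if (any(rowSums(memb) == 0L))
        stop("consistency error: overlap gene absent from every study set: ",
             paste(overlapGenes[rowSums(memb) == 0L], collapse = ", "))
    ns <- names(sets)
    patterns <- unlist(lapply(seq_along(ns), function(k)
        utils::combn(ns, k, simplify = FALSE)), recursive = FALSE)
    rows <- lapply(patterns, function(pt) {
        inPt <- rowSums(memb[, pt, drop = FALSE]) == length(pt) &
                rowSums(memb) == length(pt)
        g <- overlapGenes[inPt]
        data.frame(
            category = if (length(pt) == 1L)
                paste0("unique_to_", pt)
            else paste0("shared_", paste(pt, collapse = "_")),
            studies = paste(pt, collapse = ","),
            count = length(g),
            genes = paste(g, collapse = ","),
            stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
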