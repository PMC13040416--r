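#' @import methods
NULL

## Central S4 containers. Constructors live next to the functions that
## produce each object; validity methods enforce the structural invariants
## the downstream stages rely on.

#' GenePanel: a named set of gene symbols with per-gene provenance
#'
#' A panel is a named, duplicate-free set of (ideally approved) gene symbols.
#' Provenance rows record where each symbol came from (source study, original
#' spelling, direction of regulation where known); a symbol may have several
#' provenance rows when independent sources contributed it.
#'
#' @slot name single non-empty panel name.
#' @slot genes character vector of unique symbols.
#' @slot provenance data.frame with at least a \code{symbol} column; every
#'   \code{symbol} must be a member of \code{genes}.
#'
#' @seealso [GenePanel()], [harmonisePanel()], [deriveUniquePanel()]
#' @exportClass GenePanel
setClass("GenePanel",
    representation(name = "character", genes = "character",
                   provenance = "data.frame"))

setValidity("GenePanel", function(object) {
    msg <- character()
    if (length(object@name) != 1L || !nzchar(object@name))
        msg <- c(msg, "'name' must be a single non-empty string")
    if (anyDuplicated(object@genes))
        msg <- c(msg, "panel symbols must be unique")
    if (any(is.na(object@genes)) || any(!nzchar(object@genes)))
        msg <- c(msg, "panel symbols must be non-empty and non-NA")
    if (nrow(object@provenance) > 0L) {
        if (!"symbol" %in% names(object@provenance))
            msg <- c(msg, "provenance must have a 'symbol' column")
        else if (!all(object@provenance$symbol %in% object@genes))
            msg <- c(msg, "provenance refers to symbols outside the panel")
    }
    if (length(msg)) msg else TRUE
})

#' AliasTable: an offline gene-nomenclature snapshot
#'
#' One row per approved symbol, with pipe-separated synonyms, biotype,
#' free-text description, stable identifiers and an approval status. A
#' synonym may legitimately point at several approved symbols; that ambiguity
#' is data, resolved by [resolveSymbol()]'s tie-breaking tiers.
#'
#' @slot records data.frame with columns \code{approved_symbol},
#'   \code{synonyms}, \code{biotype}, \code{description}, \code{ensembl_id},
#'   \code{entrez_id}, \code{status}.
#' @exportClass AliasTable
setClass("AliasTable", representation(records = "data.frame"))

.aliasCols <- c("approved_symbol", "synonyms", "biotype", "description",
                "ensembl_id", "entrez_id", "status")

setValidity("AliasTable", function(object) {
    msg <- character()
    if (!all(.aliasCols %in% names(object@records)))
        msg <- c(msg, paste("records must have columns:",
                            paste(.aliasCols, collapse = ", ")))
    else if (anyDuplicated(object@records$approved_symbol))
        msg <- c(msg, "approved symbols must be unique")
    if (length(msg)) msg else TRUE
})

#' ExpressionSummary: condition-wise expression summaries per gene
#'
#' Per-gene mean and standard deviation of normalised expression in each
#' condition, plus one omnibus p-value per gene which may be NaN (the
#' database's reported failure mode when a condition has zero within-group
#' variance). Optionally carries the per-sample matrix the summaries were
#' computed from.
#'
#' @slot genes character vector of gene symbols (unique).
#' @slot conditions condition labels; must include the control.
#' @slot control the designated control condition label.
#' @slot means,sds numeric matrices, genes x conditions; sds >= 0.
#' @slot p named numeric vector of omnibus p-values (NaN allowed).
#' @slot values optional per-sample matrix (genes x samples); may be 0-col.
#' @slot sampleConditions condition label per column of \code{values}.
#' @exportClass ExpressionSummary
setClass("ExpressionSummary",
    representation(genes = "character", conditions = "character",
                   control = "character", means = "matrix", sds = "matrix",
                   p = "numeric", values = "matrix",
                   sampleConditions = "character"))

setValidity("ExpressionSummary", function(object) {
    msg <- character()
    ng <- length(object@genes); nc <- length(object@conditions)
    if (anyDuplicated(object@genes))
        msg <- c(msg, "gene symbols must be unique")
    if (length(object@control) != 1L ||
        !object@control %in% object@conditions)
        msg <- c(msg, "exactly one control condition must be present")
    if (!identical(dim(object@means), c(ng, nc)) ||
        !identical(dim(object@sds), c(ng, nc)))
        msg <- c(msg, "means/sds must be genes x conditions matrices")
    if (any(object@sds < 0, na.rm = TRUE))
        msg <- c(msg, "standard deviations must be >= 0")
    if (length(object@p) != ng)
        msg <- c(msg, "one omnibus p-value per gene is required")
    if (ncol(object@values) > 0L &&
        (nrow(object@values) != ng ||
         length(object@sampleConditions) != ncol(object@values)))
        msg <- c(msg, "per-sample values inconsistent with genes/conditions")
    if (length(msg)) msg else TRUE
})

#' ScreenConfig: parameters of the exercise-responsiveness screen
#'
#' @slot alpha significance level for the p gate (default 0.05).
#' @slot dThreshold absolute Cohen's d cut-off for a biologically meaningful
#'   response (default 0.5).
#' @slot controlLabel control condition name (default "inactivity").
#' @slot gateOnP if TRUE (default) a gene must be significant or have a NaN
#'   p before its effect sizes are considered; if FALSE the |d| rule applies
#'   irrespective of significance.
#' @slot alphaInclusive compare p <= alpha instead of p < alpha.
#' @slot undefinedIsHit count an undefined d (both SDs zero, means differ)
#'   as a threshold hit.
#' @exportClass ScreenConfig
setClass("ScreenConfig",
    representation(alpha = "numeric", dThreshold = "numeric",
                   controlLabel = "character", gateOnP = "logical",
                   alphaInclusive = "logical", undefinedIsHit = "logical"))

setValidity("ScreenConfig", function(object) {
    msg <- character()
    if (object@alpha <= 0 || object@alpha >= 1)
        msg <- c(msg, "alpha must be in (0, 1)")
    if (object@dThreshold <= 0)
        msg <- c(msg, "dThreshold must be > 0")
    if (length(msg)) msg else TRUE
})

#' ScreenResult: per-gene screen statuses, counts and the responsive set
#'
#' @slot table one row per panel gene: status, per-modality d, max |d|,
#'   responsiveness and hit modalities.
#' @slot counts named integer vector (significant, nan_p, not_significant,
#'   missing); always partitions the panel.
#' @slot responsive symbols flagged as exercise-responsive.
#' @slot config the [ScreenConfig-class] used.
#' @exportClass ScreenResult
setClass("ScreenResult",
    representation(table = "data.frame", counts = "integer",
                   responsive = "character", config = "ScreenConfig"))

setValidity("ScreenResult", function(object) {
    msg <- character()
    need <- c("significant", "nan_p", "not_significant", "missing")
    if (!identical(sort(names(object@counts)), sort(need)))
        msg <- c(msg, "counts must be named significant/nan_p/not_significant/missing")
    else if (sum(object@counts) != nrow(object@table))
        msg <- c(msg, "status counts must partition the panel")
    if (!all(object@responsive %in% object@table$gene))
        msg <- c(msg, "responsive genes must come from the panel")
    if (length(msg)) msg else TRUE
})

#' ThresholdConfig: one study's differential-expression cut-offs
#'
#' Exactly one effect-size criterion is active, stored internally on the
#' log2 scale (a linear fold-change bound fc is stored as log2(fc)).
#'
#' @slot studyId study label.
#' @slot minAbsLog2fc the effect bound on the log2 scale.
#' @slot effectScale "linear" or "log2": the scale the bound was stated on.
#' @slot fcInclusive whether the effect bound is inclusive (>=) or strict (>).
#' @slot maxAdjP adjusted-p bound, or NA when the study used none.
#' @slot adjPInclusive whether the p bound is inclusive (<=) or strict (<).
#' @slot twoSided apply the effect criterion to |log2FC| (default TRUE).
#' @exportClass ThresholdConfig
setClass("ThresholdConfig",
    representation(studyId = "character", minAbsLog2fc = "numeric",
                   effectScale = "character", fcInclusive = "logical",
                   maxAdjP = "numeric", adjPInclusive = "logical",
                   twoSided = "logical"))

setValidity("ThresholdConfig", function(object) {
    msg <- character()
    if (!is.finite(object@minAbsLog2fc) || object@minAbsLog2fc < 0)
        msg <- c(msg, "effect bound must be a non-negative finite number")
    if (!is.na(object@maxAdjP) &&
        (object@maxAdjP <= 0 || object@maxAdjP > 1))
        msg <- c(msg, "maxAdjP must be in (0, 1] or NA")
    if (length(msg)) msg else TRUE
})

#' FilteredSet: genes passing one study's cut-offs
#'
#' @slot studyId study label.
#' @slot genes unique symbols passing the study's thresholds.
#' @slot contrasts named list of per-contrast gene sets (empty when the
#'   table had no contrast labels).
#' @exportClass FilteredSet
setClass("FilteredSet",
    representation(studyId = "character", genes = "character",
                   contrasts = "list"))

setValidity("FilteredSet", function(object) {
    msg <- character()
    if (anyDuplicated(object@genes))
        msg <- c(msg, "filtered gene set must be duplicate-free")
    if (length(object@contrasts) &&
        !all(unlist(object@contrasts) %in% object@genes))
        msg <- c(msg, "contrast sets must be subsets of the study set")
    if (length(msg)) msg else TRUE
})

#' OverlapResult: three-set Venn decomposition with study attribution
#'
#' @slot setNames labels of the three input sets, in order.
#' @slot regionCounts named numeric of the 7 Venn regions; sums to the size
#'   of the three-set union.
#' @slot membership one row per gene in the union, with the three membership
#'   flags and the (single) region the gene falls in.
#' @slot attribution per-study attribution of the candidate-vs-altitude
#'   overlap (may be empty).
#' @exportClass OverlapResult
setClass("OverlapResult",
    representation(setNames = "character", regionCounts = "numeric",
                   membership = "data.frame", attribution = "data.frame"))

setValidity("OverlapResult", function(object) {
    msg <- character()
    if (length(object@regionCounts) != 7L)
        msg <- c(msg, "exactly 7 Venn regions are required")
    if (sum(object@regionCounts) != nrow(object@membership))
        msg <- c(msg, "region counts must sum to the union size")
    if (nrow(object@membership) &&
        anyDuplicated(object@membership$gene))
        msg <- c(msg, "each gene occupies exactly one region")
    if (length(msg)) msg else TRUE
})

#' AnnotationSet: gene-set annotations (GMT-style)
#'
#' @slot terms named list, term id -> character vector of member genes.
#' @slot termNames named character, term id -> human-readable description.
#' @exportClass AnnotationSet
setClass("AnnotationSet",
    representation(terms = "list", termNames = "character"))

setValidity("AnnotationSet", function(object) {
    msg <- character()
    if (is.null(names(object@terms)) || anyDuplicated(names(object@terms)))
        msg <- c(msg, "term ids must be present and unique")
    if (any(lengths(object@terms) == 0L))
        msg <- c(msg, "term gene sets must be non-empty")
    if (!all(names(object@terms) %in% names(object@termNames)))
        msg <- c(msg, "every term needs a description entry")
    if (length(msg)) msg else TRUE
})

#' UniverseSpec: the background gene space of an enrichment analysis
#'
#' @slot mode "measured" (detected genes only) or "genome".
#' @slot genes the universe members.
#' @exportClass UniverseSpec
setClass("UniverseSpec",
    representation(mode = "character", genes = "character"))

setValidity("UniverseSpec", function(object) {
    msg <- character()
    if (!object@mode %in% c("measured", "genome"))
        msg <- c(msg, "mode must be 'measured' or 'genome'")
    if (length(object@genes) < 1L)
        msg <- c(msg, "universe must contain at least one gene")
    if (anyDuplicated(object@genes))
        msg <- c(msg, "universe genes must be unique")
    if (length(msg)) msg else TRUE
})

#' EnrichmentResult: per-term over-representation statistics
#'
#' @slot table one row per tested term, sorted by (pvalue, ID).
#' @slot nInput number of input genes after mapping/exclusions (the n of the
#'   hypergeometric draw).
#' @slot mapped input symbols retained.
#' @slot unmapped input symbols dropped (not in the universe, or excluded
#'   by biotype).
#' @slot universe the [UniverseSpec-class] used.
#' @exportClass EnrichmentResult
setClass("EnrichmentResult",
    representation(table = "data.frame", nInput = "integer",
                   mapped = "character", unmapped = "character",
                   universe = "UniverseSpec"))

setValidity("EnrichmentResult", function(object) {
    tab <- object@table
    msg <- character()
    if (nrow(tab)) {
        if (any(tab$k > pmin(tab$n, tab$K)))
            msg <- c(msg, "k must not exceed min(n, K)")
        if (any(tab$p.adjust < tab$pvalue - 1e-12))
            msg <- c(msg, "adjusted p must dominate raw p")
    }
    if (length(msg)) msg else TRUE
})

#' SimConfig: parameters of the synthetic-data generators
#'
#' Holds everything the generators need: the statistical structure of the
#' expression emulation (six exercise conditions against a sedentary
#' control, group-wise Gaussian noise, planted standardized effects, forced
#' zero-variance groups), the per-dialect planted DEG fractions, the
#' annotation-set layout and the alias-corruption rates. A fixed seed makes
#' every generator byte-reproducible; each generator draws from its own
#' stream derived from the master seed by a fixed offset.
#'
#' @slot seed master RNG seed.
#' @slot nGenes number of genes to simulate.
#' @slot conditionLabels the condition names (control included).
#' @slot controlLabel which condition is the sedentary control.
#' @slot groupSizes named integer, samples per condition.
#' @slot plantedEffects data.frame(gene, condition, d) of true standardized
#'   mean differences versus control.
#' @slot zeroVarianceFraction fraction of genes given one all-constant
#'   group (their omnibus p is NaN by construction).
#' @slot degFractions named fractions of genes planted as true DEGs per
#'   dialect (sutehall, pham, manella).
#' @slot nTerms,termSizeRange,plantedTerms annotation-set parameters.
#' @slot aliasNoise named fractions of panel symbols emitted as synonyms,
#'   case/whitespace damage, or LOC placeholders.
#' @slot dThreshold the |d| cut-off used to define the truth responsive set.
#' @exportClass SimConfig
setClass("SimConfig",
    representation(seed = "integer", nGenes = "integer",
                   conditionLabels = "character", controlLabel = "character",
                   groupSizes = "integer", plantedEffects = "data.frame",
                   zeroVarianceFraction = "numeric",
                   degFractions = "numeric", nTerms = "integer",
                   termSizeRange = "integer", plantedTerms = "integer",
                   aliasNoise = "numeric", dThreshold = "numeric"))

setValidity("SimConfig", function(object) {
    msg <- character()
    fr <- c(object@zeroVarianceFraction, object@degFractions,
            object@aliasNoise)
    if (any(fr < 0 | fr > 1))
        msg <- c(msg, "all fractions must lie in [0, 1]")
    if (!object@controlLabel %in% object@conditionLabels)
        msg <- c(msg, "controlLabel must be one of conditionLabels")
    if (!identical(sort(names(object@groupSizes)),
                   sort(object@conditionLabels)))
        msg <- c(msg, "groupSizes must be named by condition")
    if (any(object@groupSizes < 1L))
        msg <- c(msg, "group sizes must be >= 1")
    if (!all(c("sutehall", "pham", "manella") %in%
             names(object@degFractions)))
        msg <- c(msg, "degFractions needs sutehall/pham/manella entries")
    if (!all(c("synonym", "damage", "loc") %in% names(object@aliasNoise)))
        msg <- c(msg, "aliasNoise needs synonym/damage/loc entries")
    if (length(object@termSizeRange) != 2L ||
        object@termSizeRange[1] > object@termSizeRange[2])
        msg <- c(msg, "termSizeRange must be an increasing pair")
    if (nrow(object@plantedEffects) &&
        !all(c("gene", "condition", "d") %in% names(object@plantedEffects)))
        msg <- c(msg, "plantedEffects needs gene/condition/d columns")
    if (length(msg)) msg else TRUE
})

#' TruthSet: planted ground truth of a synthetic-data generator
#'
#' Each generator fills the slots it knows about and leaves the rest empty;
#' recovery tests compare pipeline output against these slots.
#'
#' @slot responsiveGenes genes planted with |d| >= the configured threshold.
#' @slot degSets named list of per-dialect true DEG symbol sets.
#' @slot enrichedTerms ids of terms planted as truly enriched.
#' @slot aliasMap named character, raw (corrupted) symbol -> intended
#'   approved symbol.
#' @slot aliasRoutes named character, raw symbol -> expected resolution
#'   route (approved/synonym/second_pass).
#' @exportClass TruthSet
setClass("TruthSet",
    representation(responsiveGenes = "character", degSets = "list",
                   enrichedTerms = "character", aliasMap = "character",
                   aliasRoutes = "character"))
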