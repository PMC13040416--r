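#' @include AllClasses.R AllGenerics.R ExpressionSummary.R screen.R deg-filter.R harmonise.R enrichment.R
NULL

#' Construct a SimConfig
#'
#' Defaults emulate the study conditions the analysis assumes: six
#' exercise conditions (acute aerobic/anaerobic, long-term
#' aerobic/resistance, other modalities) against a sedentary control
#' ("inactivity"), group-wise Gaussian noise on the normalised-expression
#' scale, 30 samples per condition, and |d| >= 0.5 as the responsiveness
#' threshold. All randomness derives from \code{seed}; each generator uses
#' its own stream (fixed offsets), so adding one generator never perturbs
#' another's output.
#'
#' @param seed master seed (integer).
#' @param nGenes number of genes (default 500).
#' @param conditionLabels condition names; default the six standard ones.
#' @param controlLabel the sedentary control (default "inactivity").
#' @param groupSizes samples per condition: a single number or a named
#'   vector (default 30 each).
#' @param plantedEffects data.frame(gene, condition, d) of true
#'   standardized effects vs control (default none).
#' @param zeroVarianceFraction fraction of genes with one forced
#'   all-constant group, whose omnibus p becomes NaN (default 0).
#' @param degFractions per-dialect fractions of genes planted as true DEGs
#'   (default 0.05 each).
#' @param nTerms,termSizeRange,plantedTerms annotation parameters
#'   (defaults: 50 terms of 10-50 genes, none planted).
#' @param aliasNoise fractions of panel symbols emitted as synonyms,
#'   case/whitespace damage, or LOC placeholders (defaults 0.15/0.10/0.05).
#' @param dThreshold |d| threshold defining the truth responsive set.
#' @return a [SimConfig-class].
#' @export
SimConfig <- function(seed = 1L, nGenes = 500L,
                      conditionLabels = c("acute_aerobic",
                          "acute_anaerobic", "longterm_aerobic",
                          "longterm_resistance", "other", "inactivity"),
                      controlLabel = "inactivity",
                      groupSizes = 30L,
                      plantedEffects = data.frame(gene = character(),
                          condition = character(), d = numeric()),
                      zeroVarianceFraction = 0,
                      degFractions = c(sutehall = 0.05, pham = 0.05,
                                       manella = 0.05),
                      nTerms = 50L, termSizeRange = c(10L, 50L),
                      plantedTerms = 0L,
                      aliasNoise = c(synonym = 0.15, damage = 0.10,
                                     loc = 0.05),
                      dThreshold = 0.5) {
    if (length(groupSizes) == 1L && is.null(names(groupSizes)))
        groupSizes <- stats::setNames(rep(as.integer(groupSizes),
                                          length(conditionLabels)),
                                      conditionLabels)
    new("SimConfig", seed = as.integer(seed), nGenes = as.integer(nGenes),
        conditionLabels = conditionLabels, controlLabel = controlLabel,
        groupSizes = as.integer(groupSizes) |>
            stats::setNames(names(groupSizes)),
        plantedEffects = plantedEffects,
        zeroVarianceFraction = zeroVarianceFraction,
        degFractions = degFractions, nTerms = as.integer(nTerms),
        termSizeRange = as.integer(termSizeRange),
        plantedTerms = as.integer(plantedTerms),
        aliasNoise = aliasNoise, dThreshold = dThreshold)
}

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig: seed", object@seed, "|", object@nGenes, "genes x",
        length(object@conditionLabels), "conditions,",
        nrow(object@plantedEffects), "planted effects\n")
})

## one RNG stream per generator, derived from the master seed by a fixed
## offset; kept well below 2^31
.simSeed <- function(cfg, offset) {
    (abs(cfg@seed) %% 2000000L) * 1000L + offset
}

.geneNames <- function(n) sprintf("GENE%05d", seq_len(n))

#' Generate per-sample expression with planted standardized effects
#'
#' Group-wise Gaussian values per gene: each gene gets a baseline level
#' and noise SD; a planted effect (gene, condition, d) shifts that
#' condition's mean by d standard deviations relative to the control.
#' Zero-variance genes have one non-control group frozen at a constant
#' (all samples identical); their omnibus p is NaN, emulating the
#' rank-test failure on degenerate groups. All other genes get the
#' Kruskal-Wallis omnibus p across all conditions.
#'
#' @param cfg a [SimConfig-class]. Group sizes below 2 are an error unless
#'   zero-variance groups are requested.
#' @return list with \code{values} (genes x samples matrix),
#'   \code{sampleConditions}, \code{summary} (an
#'   [ExpressionSummary-class] with values attached) and \code{truth}
#'   (a [TruthSet-class]: genes planted at |d| >= the configured
#'   threshold).
#' @export
genExpression <- function(cfg) {
    stopifnot(is(cfg, "SimConfig"))
    if (any(cfg@groupSizes < 2L) && cfg@zeroVarianceFraction == 0)
        stop("invalid config: group sizes < 2 without zero-variance intent")
    set.seed(.simSeed(cfg, 101L))
    genes <- .geneNames(cfg@nGenes)
    conds <- cfg@conditionLabels
    ctl <- cfg@controlLabel
    sigma <- stats::runif(cfg@nGenes, 0.5, 1.5)
    mu <- stats::runif(cfg@nGenes, 2, 10)

    effect <- matrix(0, cfg@nGenes, length(conds),
                     dimnames = list(genes, conds))
    pe <- cfg@plantedEffects
    if (nrow(pe)) {
        if (!all(pe$gene %in% genes))
            stop("planted effect names an unknown gene")
        if (!all(pe$condition %in% setdiff(conds, ctl)))
            stop("planted effects must target non-control conditions")
        effect[cbind(match(pe$gene, genes), match(pe$condition, conds))] <-
            pe$d
    }

    nZv <- floor(cfg@zeroVarianceFraction * cfg@nGenes)
    zvGenes <- if (nZv > 0) sample(genes, nZv) else character()
    zvGroup <- stats::setNames(
        sample(setdiff(conds, ctl), nZv, replace = TRUE), zvGenes)

    sampleConditions <- rep(conds, cfg@groupSizes[conds])
    values <- matrix(NA_real_, cfg@nGenes, length(sampleConditions),
                     dimnames = list(genes, NULL))
    for (j in seq_along(conds)) {
        cols <- which(sampleConditions == conds[j])
        m <- mu + effect[, j] * sigma
        values[, cols] <- m + stats::rnorm(cfg@nGenes * length(cols)) *
            sigma
    }
    if (nZv > 0)
        for (g in zvGenes) {
            cols <- which(sampleConditions == zvGroup[[g]])
            values[g, cols] <- mu[match(g, genes)] +
                effect[g, zvGroup[[g]]] * sigma[match(g, genes)]
        }

    means <- matrix(NA_real_, cfg@nGenes, length(conds),
                    dimnames = list(genes, conds))
    sds <- means
    for (cd in conds) {
        sub <- values[, sampleConditions == cd, drop = FALSE]
        means[, cd] <- rowMeans(sub)
        sds[, cd] <- apply(sub, 1, stats::sd)
    }

    p <- vapply(seq_len(cfg@nGenes), function(i) {
        if (genes[i] %in% zvGenes) return(NaN)
        kruskalWallis(split(values[i, ], sampleConditions))$p.value
    }, numeric(1))

    responsive <- unique(pe$gene[abs(pe$d) >= cfg@dThreshold])
    list(values = values, sampleConditions = sampleConditions,
         summary = ExpressionSummary(means, sds, p, control = ctl,
                                     values = values,
                                     sampleConditions = sampleConditions),
         truth = new("TruthSet", responsiveGenes = responsive,
                     degSets = list(), enrichedTerms = character(),
                     aliasMap = character(), aliasRoutes = character()))
}

.manellaContrasts <- c("200-3800M", "200-5100M", "3800-5100M")

## draw a log2FC that passes (planted) or fails (null) a dialect's effect
## bound, with random sign
.drawLog2fc <- function(n, bound, pass, inclusive) {
    eps <- 1e-3
    mag <- if (pass) stats::runif(n, bound + if (inclusive) 0 else eps,
                                  bound + 2.5)
           else stats::runif(n, 0, max(bound - eps, 0))
    mag * sample(c(-1, 1), n, replace = TRUE)
}

#' Generate per-dialect differential-expression tables
#'
#' One table per study dialect, conforming to that dialect's column schema
#' and published cut-offs. Planted true DEGs pass their dialect's filter by
#' construction; every other row fails at least one criterion (the
#' violated criterion is chosen at random when the dialect has two).
#'
#' @param cfg a [SimConfig-class]; \code{degFractions} sets the planted
#'   fraction per dialect.
#' @param dialects which tables to generate.
#' @return list with \code{tables} (named list of dialect data.frames in
#'   their native column schemas) and \code{truth} (planted DEG sets per
#'   dialect).
#' @export
genDegTables <- function(cfg,
                         dialects = c("sutehall", "pham", "manella")) {
    stopifnot(is(cfg, "SimConfig"))
    unknown <- setdiff(dialects, c("sutehall", "pham", "manella"))
    if (length(unknown))
        stop("unknown dialect: ", paste(unknown, collapse = ", "))
    set.seed(.simSeed(cfg, 211L))
    genes <- .geneNames(cfg@nGenes)
    tables <- list(); truthSets <- list()
    for (dl in dialects) {
        nDeg <- floor(cfg@degFractions[[dl]] * cfg@nGenes)
        planted <- sort(sample(genes, nDeg))
        isDeg <- genes %in% planted
        ng <- length(genes)
        if (dl == "sutehall") {
            l2 <- numeric(ng); fdr <- numeric(ng)
            l2[isDeg] <- .drawLog2fc(nDeg, log2(1.2), TRUE, TRUE)
            fdr[isDeg] <- stats::runif(nDeg, 0, 0.05)
            viol <- sample(c("effect", "p", "both"), ng - nDeg,
                           replace = TRUE)
            l2[!isDeg] <- ifelse(viol %in% c("effect", "both"),
                .drawLog2fc(ng - nDeg, log2(1.2), FALSE, TRUE),
                .drawLog2fc(ng - nDeg, log2(1.2), TRUE, TRUE))
            fdr[!isDeg] <- ifelse(viol %in% c("p", "both"),
                stats::runif(ng - nDeg, 0.051, 1),
                stats::runif(ng - nDeg, 0, 0.05))
            # linear scale; down-regulation is fc < 1 (two-sided filter)
            tables[[dl]] <- data.frame(gene = genes, fc = 2^l2,
                fdr = fdr, stringsAsFactors = FALSE)
        } else if (dl == "pham") {
            l2 <- numeric(ng)
            l2[isDeg] <- .drawLog2fc(nDeg, 1, TRUE, TRUE)
            l2[!isDeg] <- .drawLog2fc(ng - nDeg, 1, FALSE, TRUE)
            tables[[dl]] <- data.frame(gene = genes, log2fc = l2,
                p = stats::runif(ng), padj = stats::runif(ng),
                day_label = sample(c("HA1", "HA3"), ng, replace = TRUE),
                stringsAsFactors = FALSE)
        } else {  # manella: DESeq2-style contrast rows, strict bounds
            l2 <- numeric(ng); padj <- numeric(ng)
            l2[isDeg] <- .drawLog2fc(nDeg, 0.5, TRUE, FALSE)
            padj[isDeg] <- stats::runif(nDeg, 0, 0.0099)
            viol <- sample(c("effect", "p", "both"), ng - nDeg,
                           replace = TRUE)
            l2[!isDeg] <- ifelse(viol %in% c("effect", "both"),
                stats::runif(ng - nDeg, 0, 0.5) *
                    sample(c(-1, 1), ng - nDeg, replace = TRUE),
                .drawLog2fc(ng - nDeg, 0.5, TRUE, FALSE))
            padj[!isDeg] <- ifelse(viol %in% c("p", "both"),
                stats::runif(ng - nDeg, 0.01, 1),
                stats::runif(ng - nDeg, 0, 0.0099))
            lfcSE <- stats::runif(ng, 0.05, 0.5)
            tables[[dl]] <- data.frame(gene = genes,
                base_mean = stats::rlnorm(ng, 4, 1), log2fc = l2,
                lfcSE = lfcSE, stat = l2 / lfcSE,
                p = stats::runif(ng), padj = padj,
                contrast_label = sample(.manellaContrasts, ng,
                                        replace = TRUE),
                stringsAsFactors = FALSE)
        }
        truthSets[[dl]] <- planted
    }
    list(tables = tables,
         truth = new("TruthSet", responsiveGenes = character(),
                     degSets = truthSets, enrichedTerms = character(),
                     aliasMap = character(), aliasRoutes = character()))
}

#' Generate an alias table and a corrupted panel with known resolution
#'
#' Builds a primary nomenclature snapshot over a synthetic approved-symbol
#' panel, then corrupts configured fractions of the panel: replacement by
#' a deprecated synonym, case/whitespace damage, or replacement by a LOC
#' placeholder resolvable only through the secondary snapshot (the
#' second-pass route). The truth map records each corrupted spelling's
#' intended approved symbol and route.
#'
#' @param cfg a [SimConfig-class]; \code{aliasNoise} sets the corruption
#'   fractions.
#' @param nPanel panel size (default min(nGenes, 150)).
#' @return list with \code{primary} and \code{secondary}
#'   ([AliasTable-class]), \code{approvedPanel}, \code{corruptedPanel}
#'   and \code{truth} (aliasMap raw -> approved, aliasRoutes raw ->
#'   expected route).
#' @export
genAliasTable <- function(cfg, nPanel = NULL) {
    stopifnot(is(cfg, "SimConfig"))
    set.seed(.simSeed(cfg, 307L))
    if (is.null(nPanel)) nPanel <- min(cfg@nGenes, 150L)
    approved <- sprintf("SYM%04d", seq_len(nPanel))
    synonyms <- paste0(approved, "-OLD")
    primary <- AliasTable(data.frame(
        approved_symbol = approved, synonyms = synonyms,
        biotype = sample(c("protein_coding", "lncRNA", "pseudogene"),
                         nPanel, replace = TRUE, prob = c(.8, .1, .1)),
        description = paste("synthetic gene", approved),
        ensembl_id = sprintf("ENSG%011d", seq_len(nPanel)),
        entrez_id = as.character(seq_len(nPanel) + 1000L),
        status = "approved", stringsAsFactors = FALSE))

    corrupted <- approved
    nSyn <- floor(cfg@aliasNoise[["synonym"]] * nPanel)
    nDam <- floor(cfg@aliasNoise[["damage"]] * nPanel)
    nLoc <- floor(cfg@aliasNoise[["loc"]] * nPanel)
    idx <- sample(nPanel)
    iSyn <- idx[seq_len(nSyn)]
    iDam <- idx[nSyn + seq_len(nDam)]
    iLoc <- idx[nSyn + nDam + seq_len(nLoc)]
    corrupted[iSyn] <- synonyms[iSyn]
    corrupted[iDam] <- paste0("  ", tolower(approved[iDam]), " ")
    locIds <- sprintf("LOC%06d", sample(900000L, nLoc))
    corrupted[iLoc] <- locIds

    secondary <- AliasTable(data.frame(
        approved_symbol = approved[iLoc],
        synonyms = locIds,
        biotype = rep("pseudogene", nLoc),
        description = sprintf("secondary-resolved %s", approved[iLoc]),
        ensembl_id = rep("", nLoc), entrez_id = rep("", nLoc),
        status = rep("approved", nLoc), stringsAsFactors = FALSE))

    truthMap <- stats::setNames(approved, corrupted)
    routes <- stats::setNames(rep("approved", nPanel), corrupted)
    routes[corrupted[iSyn]] <- "synonym"
    routes[corrupted[iLoc]] <- "second_pass"

    list(primary = primary, secondary = secondary,
         approvedPanel = approved, corruptedPanel = corrupted,
         truth = new("TruthSet", responsiveGenes = character(),
                     degSets = list(), enrichedTerms = character(),
                     aliasMap = truthMap, aliasRoutes = routes))
}

#' Generate annotation sets with optionally planted enriched terms
#'
#' Terms are uniform random subsets of the universe except the planted
#' ones, which draw a configured proportion of their members from a
#' designated input set so that their over-representation is true by
#' construction.
#'
#' @param cfg a [SimConfig-class] (\code{nTerms}, \code{termSizeRange},
#'   \code{plantedTerms}).
#' @param universe character vector of universe genes.
#' @param inputGenes the input set planted terms are enriched for
#'   (required when \code{plantedTerms > 0}).
#' @param plantedOverlap proportion of a planted term drawn from the
#'   input set (default 0.8).
#' @return list with \code{annotation} ([AnnotationSet-class]) and
#'   \code{truth} (planted term ids).
#' @export
genAnnotations <- function(cfg, universe, inputGenes = NULL,
                           plantedOverlap = 0.8) {
    stopifnot(is(cfg, "SimConfig"))
    set.seed(.simSeed(cfg, 401L))
    if (cfg@termSizeRange[2] > length(universe))
        stop("term sizes exceed the universe size")
    sizes <- sample(seq(cfg@termSizeRange[1], cfg@termSizeRange[2]),
                    cfg@nTerms, replace = TRUE)
    ids <- sprintf("TERM%04d", seq_len(cfg@nTerms))
    plantedIds <- character()
    terms <- vector("list", cfg@nTerms)
    names(terms) <- ids
    if (cfg@plantedTerms > 0L) {
        if (is.null(inputGenes))
            stop("plantedTerms > 0 requires inputGenes")
        plantedIds <- ids[seq_len(min(cfg@plantedTerms, cfg@nTerms))]
    }
    for (i in seq_len(cfg@nTerms)) {
        if (ids[i] %in% plantedIds) {
            nIn <- ceiling(plantedOverlap * sizes[i])
            if (nIn > length(inputGenes))
                stop("planted term larger than the input set")
            rest <- setdiff(universe, inputGenes)
            terms[[i]] <- c(sample(inputGenes, nIn),
                            sample(rest, min(sizes[i] - nIn,
                                             length(rest))))
        } else {
            terms[[i]] <- sample(universe, sizes[i])
        }
    }
    list(annotation = AnnotationSet(terms,
             stats::setNames(paste("synthetic term", ids), ids)),
         truth = new("TruthSet", responsiveGenes = character(),
                     degSets = list(), enrichedTerms = plantedIds,
                     aliasMap = character(), aliasRoutes = character()))
}

#' Write a full synthetic-data bundle to disk
#'
#' Persists every generated input in its interchange format: per-sample
#' expression TSV (header \code{sample::condition}), summary TSV, one DEG
#' TSV per dialect, alias TSVs, annotation GMT and the truth JSON.
#'
#' @param cfg a [SimConfig-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the list of generated objects.
#' @export
writeSimulation <- function(cfg, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    expr <- genExpression(cfg)
    degs <- genDegTables(cfg)
    ali <- genAliasTable(cfg)
    ann <- genAnnotations(cfg, universe = .geneNames(cfg@nGenes))

    vals <- expr$values
    colnames(vals) <- paste0("s", seq_len(ncol(vals)), "::",
                             expr$sampleConditions)
    utils::write.table(data.frame(gene = rownames(vals), vals,
                                  check.names = FALSE),
                       file.path(dir, "expression_values.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeExpressionSummary(expr$summary,
                           file.path(dir, "expression_summary.tsv"))
    for (dl in names(degs$tables))
        utils::write.table(degs$tables[[dl]],
                           file.path(dir, paste0("deg_", dl, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    writeAliasTable(ali$primary, file.path(dir, "aliases_primary.tsv"))
    writeAliasTable(ali$secondary, file.path(dir, "aliases_secondary.tsv"))
    writeLines(ali$corruptedPanel, file.path(dir, "panel_corrupted.txt"))
    writeGmt(ann$annotation, file.path(dir, "annotations.gmt"))
    truth <- list(
        responsive_genes = expr$truth@responsiveGenes,
        deg_sets = degs$truth@degSets,
        enriched_terms = ann$truth@enrichedTerms,
        alias_map = as.list(ali$truth@aliasMap))
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(list(expression = expr, degs = degs, alias = ali,
                   annotations = ann))
}
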