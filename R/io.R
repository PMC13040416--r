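#' @include AllClasses.R AllGenerics.R GenePanel.R deg-filter.R
NULL

#' Read a differential-expression table in a study dialect
#'
#' Maps each study's native column layout onto the canonical DEG columns
#' (\code{gene}, \code{fc}, \code{log2fc}, \code{base_mean}, \code{lfcSE},
#' \code{stat}, \code{p}, \code{p_adj}, \code{contrast}):
#' \describe{
#'   \item{sutehall}{gene, fc (linear), fdr.}
#'   \item{pham}{gene, log2fc, optional p/padj, day_label (-> contrast).}
#'   \item{manella}{gene, base_mean, log2fc, lfcSE, stat, p, padj,
#'     contrast_label (-> contrast).}
#' }
#'
#' @param path TSV path.
#' @param dialect one of "sutehall", "pham", "manella".
#' @return data.frame in canonical columns.
#' @export
readDegTable <- function(path, dialect = c("sutehall", "pham",
                                           "manella")) {
    dialect <- match.arg(dialect)
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    .canonicaliseDegTable(df, dialect, where = path)
}

.requireCols <- function(df, cols, where) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
        stop("malformed DEG table (", where, "): missing column(s) ",
             paste(miss, collapse = ", "))
}

.canonicaliseDegTable <- function(df, dialect, where = "table") {
    out <- switch(dialect,
        sutehall = {
            .requireCols(df, c("gene", "fc", "fdr"), where)
            data.frame(gene = df$gene, fc = df$fc, p_adj = df$fdr,
                       stringsAsFactors = FALSE)
        },
        pham = {
            .requireCols(df, c("gene", "log2fc"), where)
            data.frame(gene = df$gene, log2fc = df$log2fc,
                       p = if ("p" %in% names(df)) df$p else NA_real_,
                       p_adj = if ("padj" %in% names(df)) df$padj
                               else NA_real_,
                       contrast = if ("day_label" %in% names(df))
                           df$day_label else NA_character_,
                       stringsAsFactors = FALSE)
        },
        manella = {
            .requireCols(df, c("gene", "log2fc", "padj",
                               "contrast_label"), where)
            data.frame(gene = df$gene,
                       base_mean = if ("base_mean" %in% names(df))
                           df$base_mean else NA_real_,
                       log2fc = df$log2fc,
                       lfcSE = if ("lfcSE" %in% names(df)) df$lfcSE
                               else NA_real_,
                       stat = if ("stat" %in% names(df)) df$stat
                              else NA_real_,
                       p = if ("p" %in% names(df)) df$p else NA_real_,
                       p_adj = df$padj, contrast = df$contrast_label,
                       stringsAsFactors = FALSE)
        })
    bad <- which(is.na(out$gene) | !nzchar(out$gene))
    if (length(bad))
        stop("malformed DEG table (", where, "): empty gene at row ",
             bad[1L])
    out
}

#' Read / write newline-delimited gene lists
#'
#' @param path file path.
#' @param name panel name for the returned [GenePanel-class].
#' @return `readGeneList()` returns a [GenePanel-class] (empty file gives
#'   an empty panel with a warning); `writeGeneList()` returns `path`
#'   invisibly.
#' @export
readGeneList <- function(path, name = basename(path)) {
    lines <- trimws(readLines(path))
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L)
        warning("empty gene-list file: ", path)
    GenePanel(name, lines)
}

#' @rdname readGeneList
#' @param genes a [GenePanel-class] or character vector.
#' @export
writeGeneList <- function(genes, path) {
    writeLines(.asGeneSet(genes), path)
    invisible(path)
}

#' Validate a declarative pipeline configuration
#'
#' Checks structure and the existence of every referenced file before any
#' stage runs.
#'
#' @param config a named list (or path to a YAML file) with entries:
#'   \code{panel} (gene-list path), \code{aliases} (primary path,
#'   optional \code{aliases_secondary}), \code{summary} (expression
#'   summary path), \code{deg} (named list: study -> list(path, dialect)),
#'   \code{gmt} (annotation path), \code{universe} (list: mode, optional
#'   \code{genes} path), optional \code{screen} (alpha, d_threshold,
#'   control, gate_on_p), \code{out_dir}, optional \code{seed}.
#' @return the normalised config list, invisibly on success.
#' @export
validateRunConfig <- function(config) {
    if (is.character(config) && length(config) == 1L)
        config <- yaml::read_yaml(config)
    need <- c("panel", "aliases", "summary", "deg", "gmt", "universe",
              "out_dir")
    miss <- setdiff(need, names(config))
    if (length(miss))
        stop("config is missing entries: ", paste(miss, collapse = ", "))
    paths <- c(config$panel, config$aliases, config$aliases_secondary,
               config$summary, config$gmt,
               vapply(config$deg, `[[`, character(1), "path"),
               if (identical(config$universe$mode, "measured"))
                   config$universe$genes)
    missing <- paths[!file.exists(paths)]
    if (length(missing))
        stop("config references missing file(s): ",
             paste(missing, collapse = ", "))
    if (is.null(names(config$deg)) || anyDuplicated(names(config$deg)))
        stop("deg entries must have unique study ids")
    invisible(config)
}

#' Run the whole screening pipeline
#'
#' Executes the stages in order: harmonise the candidate panel, screen it
#' for exercise responsiveness, filter each altitude study's DEG table and
#' build the altitude union, decompose the three-set overlap, derive the
#' confounder-free panel, and run over-representation analysis of that
#' panel. All intermediates are persisted under \code{out_dir};
#' re-running the same config reproduces identical outputs. A stage
#' failure aborts with a stage-tagged error, leaving earlier outputs in
#' place for inspection.
#'
#' @param config see [validateRunConfig()].
#' @return a report bundle: list with the harmonisation audit, screen
#'   result, per-study filtered sets, altitude union, overlap result,
#'   unique panel, enrichment result, and a provenance block (config
#'   hash, seed, package version).
#' @export
runPipeline <- function(config) {
    config <- validateRunConfig(config)
    outDir <- config$out_dir
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "' failed: ",
                 conditionMessage(e), call. = FALSE))
    }

    ## stage 1: harmonise
    harm <- stage("harmonise", {
        panel <- readGeneList(config$panel, name = "candidate_panel")
        primary <- readAliasTable(config$aliases)
        secondary <- if (!is.null(config$aliases_secondary))
            readAliasTable(config$aliases_secondary) else NULL
        harmonisePanel(panel, primary, secondary)
    })
    utils::write.table(harm$audit, file.path(outDir, "harmonisation_audit.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeGeneList(harm$panel, file.path(outDir, "panel_harmonised.txt"))

    ## stage 2: exercise screen
    scfg <- config$screen
    screenConfig <- ScreenConfig(
        alpha = if (is.null(scfg$alpha)) 0.05 else scfg$alpha,
        dThreshold = if (is.null(scfg$d_threshold)) 0.5
                     else scfg$d_threshold,
        controlLabel = if (is.null(scfg$control)) "inactivity"
                       else scfg$control,
        gateOnP = if (is.null(scfg$gate_on_p)) TRUE else scfg$gate_on_p)
    screen <- stage("screen", {
        summary <- readExpressionSummary(config$summary,
                                         control = screenConfig@controlLabel)
        screenPanel(harm$panel, summary, screenConfig)
    })
    utils::write.table(resultTable(screen),
                       file.path(outDir, "screen.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(as.list(screenCounts(screen)),
                         file.path(outDir, "screen_counts.json"),
                         auto_unbox = TRUE)

    ## stage 3: altitude filters + union
    filtered <- stage("filter", {
        sets <- lapply(names(config$deg), function(study) {
            entry <- config$deg[[study]]
            tab <- readDegTable(entry$path, entry$dialect)
            cfg <- studyThresholds(entry$dialect)
            cfg@studyId <- study
            filterDegTable(tab, cfg)
        })
        names(sets) <- names(config$deg)
        sets
    })
    for (study in names(filtered))
        writeGeneList(filtered[[study]],
                      file.path(outDir, paste0("deg_", study, ".txt")))
    au <- stage("union", altitudeUnion(filtered))
    writeGeneList(au$panel, file.path(outDir, "altitude_union.txt"))
    utils::write.table(au$presence, file.path(outDir, "altitude_presence.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    ## stage 4: overlap + unique panel
    overlap <- stage("overlap",
        twoStepOverlap(harm$panel, filtered, screen))
    jsonlite::write_json(as.list(regionCounts(overlap)),
                         file.path(outDir, "venn_regions.json"),
                         auto_unbox = TRUE)
    if (nrow(overlap@attribution))
        utils::write.table(overlap@attribution,
                           file.path(outDir, "attribution.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    unique_panel <- stage("unique_panel",
        deriveUniquePanel(harm$panel, au$panel, screen))
    writeGeneList(unique_panel, file.path(outDir, "unique_panel.txt"))

    ## stage 5: enrichment of the unique panel
    enr <- stage("enrich", {
        annotation <- readGmt(config$gmt)
        uni <- if (identical(config$universe$mode, "measured"))
            buildUniverse("measured",
                          geneSymbols(readGeneList(config$universe$genes)))
        else buildUniverse("genome",
                           unique(unlist(annotation@terms,
                                         use.names = FALSE)))
        enrich(unique_panel, annotation, uni)
    })
    writeEnrichment(enr, file.path(outDir, "enrichment.tsv"))

    provenance <- list(
        config_hash = .configHash(config),
        seed = if (is.null(config$seed)) NA else config$seed,
        package_version = as.character(utils::packageVersion("epoScreen")))
    bundle <- list(audit = harm$audit, unmapped = harm$unmapped,
                   panel = harm$panel, screen = screen,
                   filtered = filtered, altitude = au,
                   overlap = overlap, uniquePanel = unique_panel,
                   enrichment = enr, provenance = provenance)
    report <- list(
        provenance = provenance,
        counts = list(panel = length(harm$panel),
                      unmapped = length(harm$unmapped),
                      screen = as.list(screenCounts(screen)),
                      responsive = length(responsiveGenes(screen)),
                      altitude_union = length(au$panel),
                      venn = as.list(regionCounts(overlap)),
                      unique_panel = length(unique_panel)))
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(bundle)
}

## stable md5 of the normalised config (provenance only)
.configHash <- function(config) {
    tmp <- tempfile()
    on.exit(unlink(tmp))
    saveRDS(config[order(names(config))], tmp)
    unname(tools::md5sum(tmp))
}
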