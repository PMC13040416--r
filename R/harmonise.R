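#' @include AllClasses.R AllGenerics.R GenePanel.R
NULL

#' Construct an AliasTable
#'
#' @param records data.frame with columns \code{approved_symbol},
#'   \code{synonyms} (pipe-separated string), \code{biotype},
#'   \code{description}, \code{ensembl_id}, \code{entrez_id}, \code{status}.
#'   Missing optional columns are filled with empty strings.
#' @return an [AliasTable-class].
#' @export
AliasTable <- function(records) {
    records <- as.data.frame(records, stringsAsFactors = FALSE)
    for (col in .aliasCols)
        if (!col %in% names(records)) records[[col]] <- ""
    records <- records[, .aliasCols]
    for (col in .aliasCols)
        records[[col]][is.na(records[[col]])] <- ""
    new("AliasTable", records = records)
}

#' @describeIn AliasTable number of approved-symbol records.
#' @param x an AliasTable.
#' @export
setMethod("length", "AliasTable", function(x) nrow(x@records))

setMethod("show", "AliasTable", function(object) {
    cat("AliasTable with", nrow(object@records), "approved symbols\n")
})

#' Read / write the alias-table TSV schema
#'
#' Columns: approved_symbol, synonyms (pipe-separated), biotype,
#' description, ensembl_id, entrez_id, status.
#'
#' @param path file path.
#' @return `readAliasTable()` returns an [AliasTable-class];
#'   `writeAliasTable()` returns `path` invisibly.
#' @export
readAliasTable <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
    AliasTable(df)
}

#' @rdname readAliasTable
#' @param table an [AliasTable-class].
#' @export
writeAliasTable <- function(table, path) {
    stopifnot(is(table, "AliasTable"))
    utils::write.table(table@records, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Normalise a raw gene identifier
#'
#' Trims whitespace, uppercases to form the case-insensitive matching key
#' (the original spelling is preserved), and flags provisional LOC
#' placeholders (LOC followed by digits).
#'
#' @param raw a single raw identifier.
#' @return list with \code{original}, \code{cleaned} (trimmed, uppercased)
#'   and \code{locPlaceholder}.
#' @examples
#' normaliseSymbol(" alas2 ")$cleaned    # "ALAS2"
#' normaliseSymbol("LOC286444")$locPlaceholder
#' @export
normaliseSymbol <- function(raw) {
    if (length(raw) != 1L || is.na(raw))
        stop("invalid symbol: expected a single non-NA string")
    trimmed <- trimws(raw)
    if (!nzchar(trimmed))
        stop("invalid symbol: empty after trimming whitespace")
    cleaned <- toupper(trimmed)
    list(original = raw, cleaned = cleaned,
         locPlaceholder = grepl("^LOC[0-9]+$", cleaned))
}

## synonym lookup: rows whose pipe-separated synonym field contains the key
.synonymHits <- function(key, records) {
    syn <- strsplit(records$synonyms, "|", fixed = TRUE)
    which(vapply(syn, function(s) key %in% toupper(trimws(s)), logical(1)))
}

.emptyResolution <- function(input, cleaned, loc) {
    data.frame(input_symbol = input, cleaned_symbol = cleaned,
               resolved_symbol = NA_character_, route = "unmapped",
               loc_placeholder = loc, ambiguous = FALSE,
               biotype = NA_character_, description = NA_character_,
               ensembl_id = NA_character_, entrez_id = NA_character_,
               stringsAsFactors = FALSE)
}

#' Resolve a cleaned symbol against an alias table
#'
#' An exact approved-symbol match always wins. Otherwise synonym candidates
#' are reduced through total tie-breaking tiers: protein_coding biotype
#' first, then a non-empty description, then the lexicographically smallest
#' approved symbol. \code{ambiguous} is TRUE whenever more than one
#' candidate entered the tie-break. Unresolved symbols come back with
#' route "unmapped" (never an error).
#'
#' @param cleaned a raw or cleaned symbol (normalised internally).
#' @param table an [AliasTable-class].
#' @return one-row data.frame mirroring the audit-log schema:
#'   input_symbol, cleaned_symbol, resolved_symbol, route, loc_placeholder,
#'   ambiguous, biotype, description, ensembl_id, entrez_id.
#' @examples
#' tab <- AliasTable(data.frame(approved_symbol = "MARCHF8",
#'     synonyms = "MARCH8|c8orf108", biotype = "protein_coding",
#'     description = "membrane associated ring-CH-type finger 8",
#'     ensembl_id = "ENSG0", entrez_id = "1", status = "approved"))
#' resolveSymbol("MARCH8", tab)$resolved_symbol   # "MARCHF8"
#' @export
resolveSymbol <- function(cleaned, table) {
    stopifnot(is(table, "AliasTable"))
    norm <- normaliseSymbol(cleaned)
    res <- .emptyResolution(norm$original, norm$cleaned,
                            norm$locPlaceholder)
    rec <- table@records
    hit <- which(toupper(rec$approved_symbol) == norm$cleaned)
    route <- NULL
    if (length(hit)) {
        route <- "approved"
        idx <- hit[1L]
    } else {
        cand <- .synonymHits(norm$cleaned, rec)
        if (length(cand)) {
            route <- "synonym"
            res$ambiguous <- length(cand) > 1L
            if (length(cand) > 1L) {   # tier 1: protein-coding biotype
                pc <- cand[rec$biotype[cand] == "protein_coding"]
                if (length(pc)) cand <- pc
            }
            if (length(cand) > 1L) {   # tier 2: informative description
                de <- cand[nzchar(rec$description[cand])]
                if (length(de)) cand <- de
            }
            idx <- cand[order(rec$approved_symbol[cand])][1L]
        }
    }
    if (!is.null(route)) {
        res$route <- route
        res$resolved_symbol <- rec$approved_symbol[idx]
        res$biotype <- rec$biotype[idx]
        res$description <- rec$description[idx]
        res$ensembl_id <- rec$ensembl_id[idx]
        res$entrez_id <- rec$entrez_id[idx]
    }
    res
}

#' Second-pass resolution of unmapped identifiers
#'
#' Re-queries symbols that stayed unmapped after the first pass (typically
#' LOC placeholders) against a secondary snapshot. A hit yields route
#' "second_pass"; its metadata is re-populated from the primary table when
#' the resolved symbol exists there (the primary's biotype wins on
#' disagreement), otherwise from the secondary. Symbols absent from both
#' stay "unmapped".
#'
#' @param unresolved data.frame of route == "unmapped" audit rows (as
#'   produced by [resolveSymbol()]).
#' @param secondaryTable,primaryTable [AliasTable-class] snapshots.
#' @return the updated rows, same schema.
#' @export
secondPassResolve <- function(unresolved, secondaryTable,
                              primaryTable = NULL) {
    stopifnot(is(secondaryTable, "AliasTable"))
    if (nrow(unresolved) == 0L) return(unresolved)
    if (!all(unresolved$route == "unmapped"))
        stop("secondPassResolve() expects unmapped results only")
    for (i in seq_len(nrow(unresolved))) {
        hit <- resolveSymbol(unresolved$cleaned_symbol[i], secondaryTable)
        if (hit$route == "unmapped") next
        row <- hit
        if (!is.null(primaryTable)) {
            prim <- resolveSymbol(hit$resolved_symbol, primaryTable)
            if (prim$route == "approved") row <- prim
        }
        unresolved$resolved_symbol[i] <- row$resolved_symbol
        unresolved$route[i] <- "second_pass"
        unresolved$biotype[i] <- row$biotype
        unresolved$description[i] <- row$description
        unresolved$ensembl_id[i] <- row$ensembl_id
        unresolved$entrez_id[i] <- row$entrez_id
    }
    unresolved
}

#' Harmonise a gene panel to approved nomenclature
#'
#' Two-pass resolution of every input symbol: first against the primary
#' snapshot (approved symbols, then synonyms with total tie-breaking), then
#' unresolved entries against an optional secondary snapshot. Inputs that
#' resolve to the same approved symbol collapse into one panel member with
#' the union of their provenance; the full per-input audit log is retained.
#'
#' @param panel a [GenePanel-class] or character vector of raw symbols.
#' @param primary an [AliasTable-class].
#' @param secondary optional secondary [AliasTable-class] for the second
#'   pass.
#' @param name name for the harmonised panel.
#' @return list with \code{panel} (harmonised [GenePanel-class]),
#'   \code{audit} (one row per input symbol) and \code{unmapped} (cleaned
#'   symbols that stayed unresolved).
#' @export
harmonisePanel <- function(panel, primary, secondary = NULL,
                           name = NULL) {
    raw <- if (is(panel, "GenePanel")) panel@genes else as.character(panel)
    if (length(raw) == 0L) stop("panel must be non-empty")
    if (is.null(name))
        name <- if (is(panel, "GenePanel")) panel@name else "panel"
    audit <- do.call(rbind, lapply(raw, resolveSymbol, table = primary))
    if (!is.null(secondary)) {
        un <- audit$route == "unmapped"
        if (any(un))
            audit[un, ] <- secondPassResolve(audit[un, , drop = FALSE],
                                             secondary, primary)
    }
    ok <- !is.na(audit$resolved_symbol)
    prov <- data.frame(symbol = audit$resolved_symbol[ok],
                       input_symbol = audit$input_symbol[ok],
                       route = audit$route[ok], stringsAsFactors = FALSE)
    out <- GenePanel(name, audit$resolved_symbol[ok], provenance = prov)
    list(panel = out, audit = audit,
         unmapped = audit$cleaned_symbol[!ok])
}
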