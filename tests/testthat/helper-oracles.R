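# Independent oracles used across the suite. They deliberately avoid the
# package's own code paths (and the base functions those delegate to).

# Upper-tail hypergeometric probability by direct combinatorial summation.
oracleHyper <- function(k, K, n, N) {
    i <- seq(k, min(n, K))
    sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Tie-corrected Kruskal-Wallis H computed from first principles.
oracleKwH <- function(groups) {
    x <- unlist(groups)
    N <- length(x)
    r <- rank(x)
    Rj <- vapply(split(r, rep(seq_along(groups), lengths(groups))), sum,
                 numeric(1))
    H <- 12 / (N * (N + 1)) * sum(Rj^2 / lengths(groups)) - 3 * (N + 1)
    ties <- table(x)
    C <- 1 - sum(ties^3 - ties) / (N^3 - N)
    H / C
}

# Exact permutation tail probability of the two-group KW statistic.
oracleKwPermP <- function(a, b) {
    x <- c(a, b)
    obs <- oracleKwH(list(a, b))
    idx <- utils::combn(length(x), length(a))
    hs <- apply(idx, 2, function(i) oracleKwH(list(x[i], x[-i])))
    mean(hs >= obs - 1e-12)
}

# Exhaustive per-gene 7-region Venn decomposition.
oracleVenn <- function(a, b, c, names3 = c("A", "B", "C")) {
    genes <- unique(c(a, b, c))
    counts <- stats::setNames(numeric(7), c(names3,
        paste(names3[1], names3[2], sep = "&"),
        paste(names3[1], names3[3], sep = "&"),
        paste(names3[2], names3[3], sep = "&"),
        paste(names3, collapse = "&")))
    for (g in genes) {
        inA <- g %in% a; inB <- g %in% b; inC <- g %in% c
        lab <- paste(names3[c(inA, inB, inC)], collapse = "&")
        counts[lab] <- counts[lab] + 1
    }
    counts
}

# Literal per-row re-check of each study's printed cut-offs.
oracleDegPass <- function(row, study) {
    if (study == "sutehall")
        abs(log2(row$fc)) >= log2(1.2) &&
            !is.na(row$p_adj) && row$p_adj <= 0.05
    else if (study == "pham")
        abs(row$log2fc) >= 1
    else if (study == "manella")
        abs(row$log2fc) > 0.5 && !is.na(row$p_adj) && row$p_adj < 0.01
    else stop("unknown study")
}

# Effect sizes recomputed naively from a summary table row.
oracleD <- function(m1, s1, m2, s2) (m1 - m2) / sqrt((s1^2 + s2^2) / 2)

# Per-cell tolerance for reproducing published two-decimal effect sizes
# from two-decimal inputs: first-order propagation of the +/-0.005
# rounding of each printed mean and SD, plus the +/-0.005 rounding of the
# printed d itself.
roundingBound <- function(d, s1, s2) {
    sp2 <- (s1^2 + s2^2) / 2
    0.01 / sqrt(sp2) + abs(d) * 0.005 * (s1 + s2) / (2 * sp2) + 0.005
}

fixturePath <- function(name)
    system.file("extdata", name, package = "epoScreen", mustWork = TRUE)

# Alias fixtures mirroring the published resolution cases: a primary
# nomenclature snapshot and the secondary (NCBI-style) snapshot that
# resolves LOC placeholders.
paperAliasFixtures <- function() {
    primary <- AliasTable(data.frame(
        approved_symbol = c("ALAS2", "MARCHF8", "RPS2P55", "MKRN10P",
                            "STRADBP1", "RPS2P5", "TENT5C"),
        synonyms = c("ASB|ANH1", "MARCH8|c8orf108", "", "", "", "",
                     "FAM46C"),
        biotype = c("protein_coding", "protein_coding", "pseudogene",
                    "pseudogene", "pseudogene", "pseudogene",
                    "protein_coding"),
        description = c("5'-aminolevulinate synthase 2",
                        "membrane associated ring-CH-type finger 8",
                        "ribosomal protein S2 pseudogene 55",
                        "makorin ring finger pseudogene",
                        "STRADB pseudogene 1",
                        "ribosomal protein S2 pseudogene 5",
                        "terminal nucleotidyltransferase 5C"),
        ensembl_id = paste0("ENSG0000000000", 1:7),
        entrez_id = as.character(1:7),
        status = "approved", stringsAsFactors = FALSE))
    secondary <- AliasTable(data.frame(
        approved_symbol = c("RPS2P55", "MKRN10P", "STRADBP1", "RPS2P5"),
        synonyms = c("LOC286444", "LOC441455", "LOC389599",
                     "LOC100130562"),
        biotype = "pseudogene",
        description = "NCBI-resolved pseudogene",
        ensembl_id = "", entrez_id = "", status = "approved",
        stringsAsFactors = FALSE))
    list(primary = primary, secondary = secondary)
}
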