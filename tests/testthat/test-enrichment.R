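test_that("hypergeomUpperTail agrees with combinatorial enumeration", {
    expect_identical(hypergeomUpperTail(0, 3, 5, 10), 1)
    expect_equal(hypergeomUpperTail(4, 4, 5, 10), 6 / 252)
    expect_equal(hypergeomUpperTail(5, 5, 5, 5), 1)  # degenerate universe
    # full small grid against the choose()-based oracle
    for (N in 2:12)
        for (K in 0:N)
            for (n in 0:N)
                for (k in 0:min(n, K))
                    expect_equal(hypergeomUpperTail(k, K, n, N),
                                 oracleHyper(k, K, n, N),
                                 tolerance = 1e-12)
    expect_error(hypergeomUpperTail(6, 4, 5, 10), "bounds")
    expect_error(hypergeomUpperTail(1, 11, 5, 10), "bounds")
})

test_that("bhAdjust performs the step-up with monotone output", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
    expect_identical(bhAdjust(0.2), 0.2)
    # hand-computed step-up: p_(i) * m / i with cumulative min from the top
    p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205)
    m <- length(p)
    hand <- rev(cummin(rev(sort(p) * m / seq_len(m))))[rank(p)]
    expect_equal(bhAdjust(p), hand)
    expect_true(all(diff(bhAdjust(sort(runif(20)))) >= 0))
    expect_true(all(bhAdjust(p) >= p))
    expect_error(bhAdjust(c(0.1, 1.2)), "0, 1")
})

test_that("buildUniverse handles measured and genome modes", {
    u <- buildUniverse("measured", sprintf("G%03d", 1:147))
    expect_identical(length(geneSymbols(u)), 147L)
    g <- buildUniverse("genome",
                       data.frame(symbol = sprintf("G%05d", 1:1000),
                                  biotype = "protein_coding"))
    expect_identical(g@mode, "genome")
    expect_identical(length(geneSymbols(g)), 1000L)
    expect_error(buildUniverse("measured", character()), "non-empty")
})

test_that("enrich computes exact per-term statistics", {
    universe <- buildUniverse("measured", sprintf("G%03d", 1:40))
    ann <- AnnotationSet(list(
        whole = sprintf("G%03d", 1:40),          # the entire universe
        half = sprintf("G%03d", 1:20),
        none = sprintf("G%03d", 31:40)))
    input <- sprintf("G%03d", 1:10)
    res <- enrich(input, ann, universe)
    tab <- resultTable(res)
    expect_identical(tab$FoldEnrichment[tab$ID == "whole"], 1)
    expect_identical(tab$pvalue[tab$ID == "whole"], 1)
    # k = FoldEnrichment * (K/N) * n exactly, for every term
    expect_equal(tab$FoldEnrichment * (tab$K / tab$N) * tab$n, tab$k,
                 tolerance = 1e-12)
    expect_identical(tab$k[tab$ID == "none"], 0L)
    expect_identical(tab$pvalue[tab$ID == "none"], 1)
    # input == universe makes every fold enrichment 1
    all40 <- resultTable(enrich(geneSymbols(universe), ann, universe))
    expect_true(all(all40$FoldEnrichment == 1))
    # sorted by p then ID
    expect_false(is.unsorted(tab$pvalue))
})

test_that("genes outside the universe are dropped with a warning", {
    universe <- buildUniverse("measured", sprintf("G%03d", 1:30))
    ann <- AnnotationSet(list(t1 = sprintf("G%03d", 1:10)))
    expect_warning(res <- enrich(c(sprintf("G%03d", 1:5), "ALIEN"),
                                 ann, universe), "outside the universe")
    expect_identical(res@nInput, 5L)
    expect_identical(res@unmapped, "ALIEN")
    expect_error(suppressWarnings(enrich("ALIEN", ann, universe)),
                 "no input genes")
})

test_that("biotype exclusion reproduces the published 45-of-50 mapping", {
    panel <- read.delim(fixturePath("rhuepo_unique50_panel.tsv"),
                        stringsAsFactors = FALSE)
    expect_identical(nrow(panel), 50L)
    expect_identical(sum(panel$biotype == "pseudogene"), 5L)
    coding <- panel$symbol[panel$biotype != "pseudogene"]
    # synthetic genome universe holding every protein-coding panel gene
    universe <- buildUniverse("genome",
                              c(coding, sprintf("FILLER%04d", 1:500)))
    ann <- AnnotationSet(list(all = geneSymbols(universe),
                              some = coding[1:10]))
    res <- enrich(panel$symbol, ann, universe,
                  excludeBiotypes = "pseudogene",
                  biotypes = panel[, c("symbol", "biotype")])
    expect_identical(res@nInput, 45L)
    expect_setequal(res@unmapped, panel$symbol[panel$biotype ==
                                               "pseudogene"])
})

test_that("planted terms are recovered and the z/q options behave", {
    universe <- sprintf("GENE%05d", 1:300)
    input <- sprintf("GENE%05d", 1:30)
    sim <- genAnnotations(SimConfig(seed = 12L, nTerms = 40L,
                                    plantedTerms = 1L,
                                    termSizeRange = c(10L, 25L)),
                          universe, inputGenes = input)
    res <- enrich(input, sim$annotation,
                  buildUniverse("measured", universe), withZ = TRUE)
    tab <- resultTable(res)
    expect_identical(tab$ID[1], sim$truth@enrichedTerms)
    expect_lte(tab$p.adjust[1], 0.05)
    expect_true(all(is.finite(tab$zscore)))
    # Storey q never exceeds the BH q with pi0 <= 1
    resQ <- enrich(input, sim$annotation,
                   buildUniverse("measured", universe),
                   qMethod = "storey")
    expect_true(all(resultTable(resQ)$qvalue <=
                    resultTable(resQ)$p.adjust + 1e-12))
})
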