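test_that("rowPasses respects each study's printed operators", {
    man <- studyThresholds("manella")
    expect_false(rowPasses(list(log2fc = 0.5, p_adj = 0.005), man))
    expect_false(rowPasses(list(log2fc = 0.6, p_adj = 0.01), man))
    expect_true(rowPasses(list(log2fc = 0.51, p_adj = 0.0099), man))
    expect_true(rowPasses(list(log2fc = -0.6, p_adj = 0.001), man))
    sut <- studyThresholds("sutehall")
    expect_false(rowPasses(list(fc = 1.19, p_adj = 0.01), sut))
    expect_true(rowPasses(list(fc = 1.20, p_adj = 0.05), sut))
    expect_true(rowPasses(list(fc = 1 / 1.25, p_adj = 0.01), sut))
    pham <- studyThresholds("pham")
    expect_true(rowPasses(list(log2fc = 1.0), pham))
    expect_true(rowPasses(list(log2fc = -1.0), pham))
    expect_false(rowPasses(list(log2fc = 0.99), pham))
    # one-sided variant excludes down-regulation
    oneSided <- ThresholdConfig("pham1s", minAbsLog2fc = 1,
                                twoSided = FALSE)
    expect_false(rowPasses(list(log2fc = -2), oneSided))
    # a required adjusted p that is absent fails the row
    expect_false(rowPasses(list(log2fc = 2), man))
    expect_error(rowPasses(list(p_adj = 0.001), man), "fc")
})

test_that("linear and log2 effect fields are interchangeable", {
    for (cfg in list(studyThresholds("sutehall"),
                     studyThresholds("manella"),
                     studyThresholds("pham")))
        for (l2 in c(-1.5, -1, -0.5, 0.2, 0.5, 1, 1.5))
            expect_identical(
                rowPasses(list(fc = 2^l2, p_adj = 0.004), cfg),
                rowPasses(list(log2fc = l2, p_adj = 0.004), cfg))
})

test_that("filter output matches an independent row-scan oracle", {
    set.seed(31)
    n <- 1000
    boundary <- data.frame(
        gene = sprintf("B%02d", 1:8),
        log2fc = c(log2(1.2), log2(1.2) - 1e-9, 0.5, 0.5 + 1e-9,
                   1, 1 - 1e-9, -0.5, -1),
        p_adj = c(0.05, 0.05, 0.01, 0.01 - 1e-9, 0.2, 0.9, 0.005, NA))
    tab <- rbind(boundary, data.frame(
        gene = sprintf("R%04d", seq_len(n)),
        log2fc = runif(n, -2, 2),
        p_adj = ifelse(runif(n) < 0.05, NA, runif(n))))
    for (study in c("sutehall", "pham", "manella")) {
        # each dialect carries its native effect column
        native <- if (study == "sutehall") {
            nat <- data.frame(gene = tab$gene, fc = 2^tab$log2fc,
                              p_adj = tab$p_adj)
            nat$fc[1] <- 1.2            # printed boundary, exactly
            nat
        } else tab
        cfg <- studyThresholds(study)
        fs <- filterDegTable(native, cfg)
        expected <- native$gene[vapply(seq_len(nrow(native)), function(i)
            oracleDegPass(native[i, ], study), logical(1))]
        expect_setequal(geneSymbols(fs), expected)
    }
})

test_that("loosening a threshold never shrinks the filtered set", {
    set.seed(5)
    tab <- data.frame(gene = sprintf("G%04d", 1:400),
                      log2fc = runif(400, -2, 2), p_adj = runif(400))
    strict <- filterDegTable(tab, ThresholdConfig("s",
        minAbsLog2fc = 0.5, fcInclusive = FALSE, maxAdjP = 0.01,
        adjPInclusive = FALSE))
    looseFc <- filterDegTable(tab, ThresholdConfig("s",
        minAbsLog2fc = 0.2, fcInclusive = FALSE, maxAdjP = 0.01,
        adjPInclusive = FALSE))
    looseP <- filterDegTable(tab, ThresholdConfig("s",
        minAbsLog2fc = 0.5, fcInclusive = FALSE, maxAdjP = 0.2,
        adjPInclusive = FALSE))
    expect_true(all(geneSymbols(strict) %in% geneSymbols(looseFc)))
    expect_true(all(geneSymbols(strict) %in% geneSymbols(looseP)))
    expect_length(geneSymbols(filterDegTable(tab[0, ],
        studyThresholds("manella"))), 0L)
})

test_that("planted DEGs are recovered exactly in every dialect", {
    cfg <- SimConfig(seed = 55L, nGenes = 1000L,
                     degFractions = c(sutehall = 0.1, pham = 0.1,
                                      manella = 0.1))
    sim <- genDegTables(cfg)
    for (dl in names(sim$tables)) {
        canon <- epoScreen:::.canonicaliseDegTable(sim$tables[[dl]], dl)
        fs <- filterDegTable(canon, studyThresholds(dl))
        expect_identical(sort(geneSymbols(fs)),
                         sort(sim$truth@degSets[[dl]]))
        expect_length(geneSymbols(fs), 100L)
    }
    # no planting: every dialect filters to the empty set
    none <- genDegTables(SimConfig(seed = 56L, nGenes = 200L,
        degFractions = c(sutehall = 0, pham = 0, manella = 0)))
    for (dl in names(none$tables))
        expect_length(geneSymbols(filterDegTable(
            epoScreen:::.canonicaliseDegTable(none$tables[[dl]], dl),
            studyThresholds(dl))), 0L)
})

test_that("altitudeUnion builds the union panel and presence matrix", {
    a <- new("FilteredSet", studyId = "s1",
             genes = c("g1", "g2", "g3"), contrasts = list())
    b <- new("FilteredSet", studyId = "s2",
             genes = c("g4", "g5", "g6", "g7"), contrasts = list())
    u <- altitudeUnion(list(a, b))
    expect_length(u$panel, 7L)
    expect_true(all(u$presence$n_altitude_studies == 1))
    # row sums equal the per-gene study count, union bounds hold
    c3 <- new("FilteredSet", studyId = "s3",
              genes = c("g1", "g4", "g8"), contrasts = list())
    u3 <- altitudeUnion(list(a, b, c3))
    expect_identical(u3$presence$n_altitude_studies,
                     unname(rowSums(as.matrix(
                         u3$presence[, c("s1", "s2", "s3")]))))
    sizes <- lengths(list(a@genes, b@genes, c3@genes))
    expect_gte(length(u3$panel), max(sizes))
    expect_lte(length(u3$panel), sum(sizes))
})

test_that("per-contrast breakdown is retained for labelled tables", {
    cfg <- SimConfig(seed = 77L, nGenes = 300L)
    sim <- genDegTables(cfg, dialects = "manella")
    tab <- sim$tables$manella
    expect_true(all(tab$contrast_label %in%
                    c("200-3800M", "200-5100M", "3800-5100M")))
    canon <- epoScreen:::.canonicaliseDegTable(tab, "manella")
    fs <- filterDegTable(canon, studyThresholds("manella"))
    expect_true(length(fs@contrasts) >= 1L)
    expect_setequal(unlist(fs@contrasts, use.names = FALSE),
                    geneSymbols(fs))
    expect_error(genDegTables(cfg, dialects = "unknownStudy"),
                 "unknown dialect")
})
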