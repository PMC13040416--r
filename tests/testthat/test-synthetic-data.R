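test_that("generators are deterministic given the config seed", {
    cfg <- SimConfig(seed = 404L, nGenes = 60L,
                     zeroVarianceFraction = 0.1, plantedTerms = 1L)
    e1 <- genExpression(cfg); e2 <- genExpression(cfg)
    expect_identical(e1$values, e2$values)
    expect_identical(e1$summary@p, e2$summary@p)
    d1 <- genDegTables(cfg); d2 <- genDegTables(cfg)
    expect_identical(d1$tables, d2$tables)
    a1 <- genAliasTable(cfg); a2 <- genAliasTable(cfg)
    expect_identical(a1$corruptedPanel, a2$corruptedPanel)
    # generator streams are independent: running one generator first does
    # not perturb another
    genDegTables(cfg)
    expect_identical(genExpression(cfg)$values, e1$values)
    # a different seed changes the data
    expect_false(identical(
        genExpression(SimConfig(seed = 405L, nGenes = 60L,
                                zeroVarianceFraction = 0.1))$values,
        e1$values))
})

test_that("a null simulation produces null-calibrated screening", {
    # no planted effects: the summary means agree across conditions and
    # the significant fraction stays within Monte-Carlo error of alpha
    nSig <- 0L; nTot <- 0L
    for (seed in 1:8) {
        sim <- genExpression(SimConfig(seed = seed, nGenes = 150L))
        expect_length(sim$truth@responsiveGenes, 0L)
        nSig <- nSig + sum(sim$summary@p < 0.05)
        nTot <- nTot + length(sim$summary@p)
    }
    rate <- nSig / nTot
    expect_lte(rate, 0.05 + 2 * sqrt(0.05 * 0.95 / nTot))
})

test_that("planted standardized effects are recovered empirically", {
    # Monte-Carlo over replicate seeds: with d = 1 and n = 30 per group
    # the empirical Cohen's d stays within +/-0.3 of truth
    devs <- vapply(1:200, function(seed) {
        cfg <- SimConfig(seed = seed, nGenes = 2L,
                         plantedEffects = data.frame(
                             gene = "GENE00001",
                             condition = "acute_aerobic", d = 1.0))
        sim <- genExpression(cfg)
        es <- effectSizes(sim$summary)
        es$d[es$gene == "GENE00001" & es$modality == "acute_aerobic"]
    }, numeric(1))
    # the sampling SD of d-hat at n = 30/group is ~0.27, so the +/-0.3
    # band holds in expectation and for most single replicates
    expect_lt(abs(mean(devs) - 1.0), 0.06)
    expect_gte(mean(abs(devs - 1.0) <= 0.3), 0.6)
    # a null gene's effects hover around zero
    expect_lt(abs(mean(vapply(1:50, function(seed) {
        sim <- genExpression(SimConfig(seed = seed, nGenes = 1L))
        effectSizes(sim$summary)$d[1]
    }, numeric(1)))), 0.15)
})

test_that("zero-variance groups force NaN omnibus p", {
    cfg <- SimConfig(seed = 10L, nGenes = 30L,
                     conditionLabels = c("exercise", "inactivity"),
                     groupSizes = c(exercise = 10L, inactivity = 10L),
                     zeroVarianceFraction = 1)
    sim <- genExpression(cfg)
    expect_true(all(is.nan(sim$summary@p)))
    # the frozen group really is constant in the per-sample values
    constPerGene <- apply(sim$values[, sim$sampleConditions ==
                                     "exercise"], 1,
                          function(v) length(unique(v)) == 1L)
    expect_true(all(constPerGene))
    # group sizes below 2 are rejected unless zero variance is intended
    expect_error(genExpression(SimConfig(seed = 1, nGenes = 5L,
        groupSizes = 1L)), "zero-variance")
    # truth set only contains genes planted at or above the threshold
    cfg2 <- SimConfig(seed = 2L, nGenes = 10L, plantedEffects =
        data.frame(gene = c("GENE00001", "GENE00002"),
                   condition = "other", d = c(0.3, 0.8)))
    expect_identical(genExpression(cfg2)$truth@responsiveGenes,
                     "GENE00002")
})

test_that("alias corruption follows the configured noise profile", {
    # zero noise: the corrupted panel is the approved panel
    clean <- genAliasTable(SimConfig(seed = 3L, nGenes = 50L,
        aliasNoise = c(synonym = 0, damage = 0, loc = 0)))
    expect_identical(clean$corruptedPanel, clean$approvedPanel)
    noisy <- genAliasTable(SimConfig(seed = 4L, nGenes = 100L))
    routes <- noisy$truth@aliasRoutes
    expect_identical(unname(table(routes)["second_pass"]),
                     5L)                       # loc = 0.05 of 100
    expect_identical(unname(table(routes)["synonym"]), 15L)
    # every LOC corruption resolves through the secondary snapshot only
    locs <- names(routes)[routes == "second_pass"]
    expect_true(all(grepl("^LOC[0-9]+$", locs)))
    prim <- noisy$primary@records
    expect_false(any(locs %in% prim$approved_symbol))
})

test_that("annotation generator plants truth and validates sizes", {
    universe <- sprintf("GENE%05d", 1:100)
    expect_error(genAnnotations(SimConfig(seed = 1,
        termSizeRange = c(10L, 200L)), universe), "universe size")
    expect_error(genAnnotations(SimConfig(seed = 1, plantedTerms = 1L,
        termSizeRange = c(40L, 50L)), universe,
        inputGenes = universe[1:5]), "larger than the input set")
    sim <- genAnnotations(SimConfig(seed = 6L, nTerms = 30L,
        plantedTerms = 2L, termSizeRange = c(10L, 20L)), universe,
        inputGenes = universe[1:25])
    expect_length(sim$truth@enrichedTerms, 2L)
    sizes <- lengths(sim$annotation@terms)
    expect_true(all(sizes >= 10L & sizes <= 20L))
})

test_that("writeSimulation persists a reproducible bundle", {
    dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
    cfg <- SimConfig(seed = 21L, nGenes = 120L, plantedTerms = 0L)
    writeSimulation(cfg, dir1)
    writeSimulation(cfg, dir2)
    files <- list.files(dir1)
    expect_true(all(c("expression_summary.tsv", "deg_manella.tsv",
                      "aliases_primary.tsv", "annotations.gmt",
                      "truth.json") %in% files))
    for (f in files)
        expect_identical(readLines(file.path(dir1, f)),
                         readLines(file.path(dir2, f)))
})
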