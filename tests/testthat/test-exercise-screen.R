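test_that("cohensD reproduces published effect sizes from summary stats", {
    # printed (gene, modality) pairs; inputs are two-decimal summaries, so
    # agreement is asserted within the input-rounding propagation bound
    cases <- data.frame(
        gene = c("ALAS2", "GYPB", "CA1", "SNCA", "CDK6", "RHAG", "FEM1A"),
        m1 = c(3.36, 1.78, 2.69, 2.42, 1.13, 0.32, 7.10),
        s1 = c(4.32, 2.60, 3.79, 1.31, 0.39, 0.57, 0.25),
        m2 = c(0.72, 0.22, 0.37, 4.67, 0.81, 0.04, 7.27),
        s2 = c(1.97, 1.06, 1.55, 1.47, 0.44, 0.23, 0.23),
        printed = c(0.78, 0.78, 0.80, -1.61, 0.77, 0.64, -0.70))
    d <- cohensD(cases$m1, cases$s1, cases$m2, cases$s2)
    expect_true(all(abs(d - cases$printed) <= 0.01))
    expect_equal(d, oracleD(cases$m1, cases$s1, cases$m2, cases$s2))
})

test_that("cohensD handles degenerate and invalid inputs", {
    expect_identical(cohensD(3, 1.5, 3, 1.5), 0)     # identical groups
    expect_identical(cohensD(2, 0, 2, 0), 0)         # equal constants
    expect_true(is.nan(cohensD(1, 0, 0, 0)))         # undefined flag
    expect_error(cohensD(1, -0.1, 0, 1), "deviations")
})

test_that("cohensD is antisymmetric and scale invariant", {
    set.seed(11)
    for (i in 1:50) {
        m <- rnorm(2, 0, 5); s <- runif(2, 0.1, 3); c0 <- runif(1, .1, 10)
        d1 <- cohensD(m[1], s[1], m[2], s[2])
        expect_equal(d1, -cohensD(m[2], s[2], m[1], s[1]))
        expect_equal(d1, cohensD(c0 * m[1], c0 * s[1], c0 * m[2],
                                 c0 * s[2]))
    }
})

test_that("kruskalWallis matches exact enumeration and flags degeneracy", {
    expect_true(is.nan(kruskalWallis(list(c(5, 5, 5), c(5, 5)))$p.value))
    kw <- kruskalWallis(list(c(1, 2, 3), c(1, 2, 3)))
    expect_equal(kw$statistic, 0)
    expect_equal(kw$p.value, 1)
    # small-sample chi-square approximation vs exhaustive permutation null
    kw2 <- kruskalWallis(list(c(1, 2, 3), c(10, 11, 12)))
    expect_equal(kw2$statistic, oracleKwH(list(1:3, 10:12)))
    expect_lt(abs(kw2$p.value - oracleKwPermP(c(1, 2, 3),
                                              c(10, 11, 12))), 0.06)
    expect_error(kruskalWallis(list(1:3)), "2 groups")
    expect_error(kruskalWallis(list(1:3, numeric())), "at least one value")
})

test_that("effectSizes reproduces the published effect-size table", {
    summ <- geprepSummaryFixture()
    printed <- read.delim(fixturePath("geprep_cohens_d.tsv"))
    es <- effectSizes(summ)
    # one published gene (CD3D) has no summary row in the source tables
    absent <- setdiff(printed$gene, geneSymbols(summ))
    expect_identical(absent, "CD3D")
    mods <- c("acute_aerobic", "acute_anaerobic", "longterm_aerobic",
              "longterm_resistance", "other")
    checked <- 0L
    for (g in setdiff(printed$gene, absent)) {
        for (m in mods) {
            dHat <- es$d[es$gene == g & es$modality == m]
            dPub <- printed[printed$gene == g, m]
            i <- match(g, geneSymbols(summ))
            s1 <- summ@sds[i, m]; s2 <- summ@sds[i, "inactivity"]
            expect_lt(abs(dHat - dPub), roundingBound(dPub, s1, s2),
                      label = paste(g, m, "reproduction"))
            checked <- checked + 1L
        }
    }
    expect_identical(checked, 33L * 5L)
})

test_that("effectSizes requires a control and handles control-only input", {
    m <- matrix(1:4, 2, 2,
                dimnames = list(c("g1", "g2"), c("inactivity", "x")))
    s <- matrix(1, 2, 2, dimnames = dimnames(m))
    summ <- ExpressionSummary(m, s, c(0.5, 0.5))
    expect_error(effectSizes(summ, ScreenConfig(controlLabel = "absent")),
                 "missing from summary")
    mc <- m[, "inactivity", drop = FALSE]
    sc <- s[, "inactivity", drop = FALSE]
    expect_identical(nrow(effectSizes(
        ExpressionSummary(mc, sc, c(0.5, 0.5)))), 0L)
})

test_that("classifyGene applies the p-gate and |d| rule", {
    cfg <- ScreenConfig()
    rec <- function(d) data.frame(gene = "g", modality = "acute_aerobic",
                                  d = d, undefined = is.nan(d),
                                  direction = sign(d))
    sig <- classifyGene(1.94e-19, rec(0.78), TRUE, cfg)
    expect_identical(sig$status, "significant")
    expect_true(sig$responsive)
    expect_identical(sig$hitModalities, "acute_aerobic")
    nan <- classifyGene(NaN, rec(-1.61), TRUE, cfg)
    expect_identical(nan$status, "nan_p")
    expect_true(nan$responsive)
    ns <- classifyGene(0.5, rec(0.9), TRUE, cfg)
    expect_identical(ns$status, "not_significant")
    expect_false(ns$responsive)
    expect_true(classifyGene(0.5, rec(0.9), TRUE,
        ScreenConfig(gateOnP = FALSE))$responsive)
    # undefined d is a hit only when allowed
    expect_false(classifyGene(NaN, rec(NaN), TRUE, cfg)$responsive)
    expect_true(classifyGene(NaN, rec(NaN), TRUE,
        ScreenConfig(undefinedIsHit = TRUE))$responsive)
    miss <- classifyGene(NA, rec(0.9), FALSE, cfg)
    expect_identical(miss$status, "missing")
    expect_false(miss$responsive)
})

test_that("screenPanel partitions the panel and recovers planted effects", {
    nResp <- 10L; nNull <- 200L
    genes <- sprintf("GENE%05d", seq_len(nResp + nNull))
    cfg <- SimConfig(seed = 202L, nGenes = nResp + nNull,
                     plantedEffects = data.frame(
                         gene = genes[seq_len(nResp)],
                         condition = "acute_aerobic", d = 1.2))
    sim <- genExpression(cfg)
    res <- screenPanel(genes, sim$summary)
    expect_identical(sum(screenCounts(res)), length(genes))
    hits <- responsiveGenes(res)
    expect_gte(length(intersect(hits, genes[seq_len(nResp)])) / nResp,
               0.95)
    # false-positive rate among nulls is bounded by the p gate
    fp <- length(intersect(hits, genes[-seq_len(nResp)])) / nNull
    expect_lte(fp, 0.05 + 2 * sqrt(0.05 * 0.95 / nNull))
    # absent genes are counted missing
    res2 <- screenPanel(c(genes[1:5], "NOT_THERE"), sim$summary)
    expect_identical(unname(screenCounts(res2)["missing"]), 1L)
    expect_error(screenPanel(c("A", "A"), sim$summary), "duplicate")
})

test_that("summary-based effects equal raw-sample recomputation", {
    cfg <- SimConfig(seed = 7L, nGenes = 20L)
    sim <- genExpression(cfg)
    es <- effectSizes(sim$summary)
    for (i in sample(nrow(es), 25)) {
        g <- es$gene[i]; m <- es$modality[i]
        a <- sim$values[g, sim$sampleConditions == m]
        b <- sim$values[g, sim$sampleConditions == "inactivity"]
        expect_equal(es$d[i], oracleD(mean(a), sd(a), mean(b), sd(b)),
                     tolerance = 1e-12)
    }
})
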