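test_that("per-SNV bias is the absolute allelic-depth difference in percent", {
    expect_equal(perSnvBias(15, 5, 20), 50)
    expect_equal(perSnvBias(10, 10, 20), 0)
    expect_equal(perSnvBias(0, 30, 30), 100)
    # unsigned: invariant under swapping the alleles
    set.seed(6)
    a <- sample(0:30, 50, replace = TRUE)
    b <- sample(0:30, 50, replace = TRUE)
    rd <- a + b + sample(0:3, 50, replace = TRUE)
    rd[rd == 0] <- 1L
    expect_equal(perSnvBias(a, b, rd), perSnvBias(b, a, rd))
    expect_error(perSnvBias(0, 0, 0), "rd")
})

test_that("gene bias is the mean per-SNV bias, bounded by its extremes", {
    expect_equal(geneBias(c(40, 60)), 50)
    v1 <- makeVariants(100, adRef = 15, adAlt = 5)
    expect_equal(geneBias(v1), perSnvBias(v1))
    expect_identical(geneBias(makeVariants(integer(0), integer(0),
                                           integer(0))), NA_real_)
    set.seed(7)
    for (i in 1:20) {
        n <- sample(2:6, 1)
        rd <- sample(5:40, n, replace = TRUE)
        aR <- rbinom(n, rd, 0.5)
        v <- makeVariants(seq_len(n) * 10, adRef = aR, adAlt = rd - aR)
        b <- perSnvBias(v)
        expect_gte(geneBias(v), min(b))
        expect_lte(geneBias(v), max(b))
    }
})

test_that("simulated per-SNV bias matches exact binomial enumeration", {
    # estimator oracle across depths and allelic fractions
    set.seed(17)
    for (rd in c(4L, 8L, 12L)) {
        for (p in c(0.5, 0.7, 0.9)) {
            ad <- sampleAllelicDepths(p, rep(rd, 4000L))
            simMean <- mean(perSnvBias(ad[, 1], ad[, 2], rowSums(ad)))
            exact <- enumPerSnvBias(rd, p)
            mcSd <- sd(perSnvBias(ad[, 1], ad[, 2], rowSums(ad))) /
                sqrt(4000)
            expect_lt(abs(simMean - exact), 5 * mcSd + 1e-9)
        }
    }
    # expected bias grows with distance from balance at fixed depth
    for (rd in c(5L, 20L)) {
        ps <- seq(0.5, 1, by = 0.05)
        expect_true(all(diff(vapply(ps, function(p)
            enumPerSnvBias(rd, p), numeric(1))) >= -1e-12))
    }
})

test_that("concordance compares directions only above the threshold", {
    # same direction
    v <- makeVariants(c(10, 20), adRef = c(36, 35), adAlt = c(4, 5),
                      source = "cDNA")
    expect_true(concordanceCheck(v))
    # opposite strong directions
    v <- makeVariants(c(10, 20), adRef = c(36, 6), adAlt = c(4, 34),
                      source = "cDNA")
    expect_false(concordanceCheck(v))
    # a weak opposite variant (bias below 20) does not break concordance
    v <- makeVariants(c(10, 20), adRef = c(36, 18), adAlt = c(4, 22),
                      source = "cDNA")
    expect_true(concordanceCheck(v, directionThreshold = 20))
    # single SNV is vacuously concordant
    expect_true(concordanceCheck(makeVariants(10, 2, 38)))
})

test_that("classification follows the printed inequalities", {
    expect_identical(classifyGenes(10, 15), "BAE")
    expect_identical(classifyGenes(10, 61), "MAE")
    expect_identical(classifyGenes(25, 90), "EXCLUDED_AFB")
    expect_identical(classifyGenes(10, 30, concordant = FALSE),
                     "DISCORDANT")
    expect_identical(classifyGenes(NA_real_, NA_real_), "NO_SNV")
    expect_error(classifyGenes(150, 10), "percentages")
})

test_that("quantification covers every annotated gene exactly once", {
    sim <- simulateASEData(SimConfig(nGenes = 120L, seed = 19L),
                           withr::local_tempdir())
    res <- suppressMessages(runASEAnalysis(
        sim$paths$gdnaVcf, sim$paths$cdnaVcf, sim$models))
    tab <- res$table
    expect_s4_class(tab, "GeneBiasTable")
    expect_identical(tab$geneId, sort(geneIds(sim$models)))
    # categories partition the gene universe
    expect_equal(sum(categorySummary(tab)$count), 120L)
    expect_equal(sum(categorySummary(tab)$pct), 100)
    # afb/aeb present exactly when the gene has usable SNVs on both sides
    both <- tab$nGdnaSnvs > 0 & tab$nCdnaSnvs > 0
    expect_true(all(!is.na(tab$afb[tab$nGdnaSnvs > 0])))
    expect_true(all(tab$category[!both] == "NO_SNV"))
    # zero-SNV genes in the simulation are NO_SNV in the table
    zero <- sim$truth$gene_id[sim$truth$n_snvs == 0]
    expect_true(all(tab$category[tab$geneId %in% zero] == "NO_SNV"))
})

test_that("a fully balanced deep simulation yields no MAE calls", {
    cfg <- SimConfig(nGenes = 80L, cnvFraction = 0,
        classMixture = c(balanced = 1, moderate = 0, monoallelic = 0),
        snvsPerGene = list(pZero = 0, min = 2L, lambda = 2),
        gdnaDepth = function(n) rep(120L, n),
        cdnaDepth = function(n) rep(120L, n), seed = 23L)
    sim <- simulateASEData(cfg, withr::local_tempdir())
    res <- suppressMessages(runASEAnalysis(
        sim$paths$gdnaVcf, sim$paths$cdnaVcf, sim$models))
    expect_equal(sum(res$table$category == "MAE"), 0L)
})

test_that("genomic bias above threshold vanishes as gDNA depth grows", {
    afbExcess <- vapply(c(100L, 400L), function(d) {
        cfg <- SimConfig(nGenes = 100L, cnvFraction = 0,
            snvsPerGene = list(pZero = 0, min = 1L, lambda = 1),
            gdnaDepth = function(n) rep(d, n),
            cdnaDepth = function(n) rep(50L, n), seed = 29L)
        sim <- simulateASEData(cfg, withr::local_tempdir())
        res <- suppressMessages(runASEAnalysis(
            sim$paths$gdnaVcf, sim$paths$cdnaVcf, sim$models))
        mean(res$table$afb > 20, na.rm = TRUE)
    }, numeric(1))
    expect_lte(afbExcess[2], afbExcess[1])
    expect_lt(afbExcess[2], 0.02)
})

test_that("an external exclusion list removes genes from the universe", {
    sim <- simulateASEData(SimConfig(nGenes = 40L, seed = 31L),
                           withr::local_tempdir())
    drop <- sim$truth$gene_id[1:5]
    res <- suppressMessages(runASEAnalysis(
        sim$paths$gdnaVcf, sim$paths$cdnaVcf, sim$models,
        excludeGenes = drop))
    expect_equal(nrow(res$table), 35L)
    expect_false(any(res$table$geneId %in% drop))
})
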