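test_that("sampleAllelicDepths follows the binomial model", {
    # degenerate fractions are deterministic
    expect_equal(unname(sampleAllelicDepths(1, 30)), c(30L, 0L),
                 ignore_attr = TRUE)
    expect_equal(unname(sampleAllelicDepths(0, 12)), c(0L, 12L),
                 ignore_attr = TRUE)
    # depths always sum to the total
    set.seed(5)
    ad <- sampleAllelicDepths(runif(500), sample(0:50, 500, replace = TRUE))
    expect_true(all(rowSums(ad) == ad[, "ad1"] + ad[, "ad2"]))
    # law of large numbers at p = 0.5
    set.seed(1)
    big <- sampleAllelicDepths(0.5, 1e5)
    expect_lt(abs(big[, "ad1"] / 1e5 - 0.5), 0.005)
    # input validation
    expect_error(sampleAllelicDepths(1.2, 10), "p")
    expect_error(sampleAllelicDepths(0.5, -1), "depth")
})

test_that("truth table is exact and consistent with the thresholds", {
    cfg <- SimConfig(nGenes = 200L, seed = 42L)
    sim <- simulateASEData(cfg, withr::local_tempdir())
    tr <- sim$truth
    expect_equal(tr$expected_AEB, 100 * abs(2 * tr$true_p - 1))
    expect_equal(tr$expected_AFB, 100 * abs(2 * tr$true_gdna_p - 1))
    # exact allocation of the zero-SNV fraction
    expect_equal(sum(tr$n_snvs == 0), 80L)
    expect_equal(sum(tr$cnv), 52L)  # round(0.26 * 200)
    # category consistency at the printed inequalities
    recat <- ifelse(tr$n_snvs == 0, "NO_SNV",
             ifelse(tr$expected_AFB > 20, "EXCLUDED_AFB",
             ifelse(tr$expected_AEB <= 20, "BAE",
             ifelse(tr$expected_AEB <= 60, "ASE", "MAE"))))
    expect_identical(tr$true_category, recat)
    # CNV genes sit at a >= 2:1 genomic ratio, expected AFB >= 100/3
    expect_true(all(tr$expected_AFB[tr$cnv] >= 100 / 3 - 1e-9))
})

test_that("all-balanced and all-monoallelic configurations label as expected", {
    balanced <- SimConfig(nGenes = 60L, cnvFraction = 0,
        classMixture = c(balanced = 1, moderate = 0, monoallelic = 0),
        snvsPerGene = list(pZero = 0, min = 2L, lambda = 1), seed = 3L)
    tr <- simulateASEData(balanced, withr::local_tempdir())$truth
    expect_true(all(tr$expected_AEB == 0))
    expect_true(all(tr$true_category == "BAE"))

    mono <- SimConfig(nGenes = 60L, cnvFraction = 0,
        classMixture = c(balanced = 0, moderate = 0, monoallelic = 1),
        snvsPerGene = list(pZero = 0, min = 2L, lambda = 1), seed = 3L)
    tr <- simulateASEData(mono, withr::local_tempdir())$truth
    expect_true(all(tr$expected_AEB > 60))
    expect_true(all(tr$true_category == "MAE"))
})

test_that("identical seeds reproduce byte-identical output files", {
    cfg <- SimConfig(nGenes = 50L, intergenicSnvs = 10L, seed = 7L)
    d1 <- withr::local_tempdir()
    d2 <- withr::local_tempdir()
    s1 <- simulateASEData(cfg, d1)
    s2 <- simulateASEData(cfg, d2)
    for (f in names(s1$paths))
        expect_identical(readLines(s1$paths[[f]]),
                         readLines(s2$paths[[f]]),
                         label = paste("file", f))
    # and a different seed changes the data
    s3 <- simulateASEData(cfg, withr::local_tempdir(), seed = 8L)
    expect_false(identical(readLines(s1$paths$gdnaVcf),
                           readLines(s3$paths$gdnaVcf)))
})

test_that("simulated VCFs round-trip exactly through the reader", {
    cfg <- SimConfig(nGenes = 40L, seed = 9L)
    sim <- simulateASEData(cfg, withr::local_tempdir())
    v <- readAllelicVariants(sim$paths$gdnaVcf, "gDNA")
    expect_s4_class(v, "AllelicVariants")
    expect_equal(length(v), sum(sim$truth$n_snvs))
    expect_true(all(mcols(v)$genotype == "0/1"))
    expect_true(all(mcols(v)$adRef + mcols(v)$adAlt == mcols(v)$rd))
    # per-gene counts match the truth table
    byGene <- assignVariantsToGenes(v, sim$models)
    expect_equal(unname(lengths(byGene)[sim$truth$gene_id]),
                 sim$truth$n_snvs)
    # cDNA sample holds the same loci
    vc <- readAllelicVariants(sim$paths$cdnaVcf, "cDNA")
    expect_identical(start(vc), start(v))
    expect_identical(mcols(vc)$ref, mcols(v)$ref)
})

test_that("gene placement fails gracefully when chromosomes are too short", {
    expect_error(simulateGeneModels(100, 1, 1e4), "not placeable")
})

test_that("gene models survive a GFF3 round trip", {
    sim <- simulateASEData(SimConfig(nGenes = 30L, seed = 2L),
                           withr::local_tempdir())
    gm <- readGeneModels(sim$paths$annotation)
    expect_identical(geneIds(gm), geneIds(sim$models))
    expect_equal(unname(start(geneSpans(gm))),
                 unname(start(geneSpans(sim$models))))
    expect_equal(unname(start(unlist(cdsRanges(gm)))),
                 unname(start(unlist(cdsRanges(sim$models)))))
})

test_that("peak placement respects the enrichment odds", {
    gm <- simulateGeneModels(100, 2, 1e6)
    cats <- setNames(rep(c("MAE", "BAE"), c(20, 80)), geneIds(gm))
    maeGenes <- geneSpans(gm)[cats == "MAE"]
    baeGenes <- geneSpans(gm)[cats == "BAE"]

    # infinite odds: every peak overlaps an MAE gene, and with ample
    # peaks every MAE gene is covered
    set.seed(21)
    pk <- simulatePeakSet(gm, cats, "MAE", enrichmentBias = Inf,
                          nPeaks = 200L, peakWidth = 1000L)
    expect_true(all(countOverlaps(pk, maeGenes) > 0))
    expect_equal(percentOverlap(maeGenes, pk), 100)

    # uniform odds: per-category overlap within 3 SD of the permutation
    # null from the package's own randomization
    set.seed(22)
    pk1 <- simulatePeakSet(gm, cats, "MAE", enrichmentBias = 1,
                           nPeaks = 60L, peakWidth = 1000L)
    os <- overlapSignificance(list(MAE = maeGenes, BAE = baeGenes), pk1,
                              flank = 0L, nIter = 200L)
    expect_true(all(abs(os$observedPct - os$randomMeanPct) <
                    3 * os$randomSdPct))

    # unknown target category
    expect_error(simulatePeakSet(gm, cats, "XXX", enrichmentBias = 2),
                 "category")
})

test_that("peak sets survive a BED round trip", {
    gm <- simulateGeneModels(20, 2, 1e5)
    cats <- setNames(rep("BAE", 20), geneIds(gm))
    set.seed(4)
    pk <- simulatePeakSet(gm, cats, enrichmentBias = 1, nPeaks = 15L,
                          peakWidth = 500L, markName = "H3K27me3")
    path <- withr::local_tempfile(fileext = ".bed")
    writePeakSet(pk, path)
    back <- readPeakSet(path, markName = "H3K27me3",
                        chromLengths = seqlengths(pk))
    expect_equal(unname(start(back)), unname(start(pk)))
    expect_equal(unname(width(back)), unname(width(pk)))
    expect_identical(markName(back), "H3K27me3")
})
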