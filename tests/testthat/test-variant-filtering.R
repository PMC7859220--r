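test_that("the reader keeps biallelic SNVs and drops the rest", {
    path <- withr::local_tempfile(fileext = ".vcf")
    writeTinyVcf(c(
        vcfLine("chr1", 300, "A", "G", "0/1", c(12, 8), 20),
        vcfLine("chr1", 400, "C", "T", "0/1", c(5, 15), 20),
        vcfLine("chr1", 500, "G", "GA", "0/1", c(9, 9), 18),     # indel
        vcfLine("chr1", 600, "T", "A,C", "0/1", c(4, 4, 4), 12), # triallelic
        vcfLine("chr1", 700, "T", "C", "0/1", c(10, 10), 20)
    ), path)
    v <- suppressMessages(readAllelicVariants(path, "gDNA"))
    expect_equal(length(v), 3L)
    expect_equal(start(v), c(300L, 400L, 700L))
    expect_equal(unname(metadata(v)$dropped[c("multiallelic", "indel")]),
                 c(1L, 1L))
    expect_equal(mcols(v)$adRef, c(12L, 5L, 10L))
})

test_that("a header-only VCF yields an empty variant set without error", {
    path <- writeTinyVcf(character(), withr::local_tempfile(fileext = ".vcf"))
    v <- readAllelicVariants(path, "cDNA")
    expect_equal(length(v), 0L)
})

test_that("records with adRef + adAlt above DP are kept but flagged", {
    expect_warning(
        v <- makeVariants(100, adRef = 12, adAlt = 10, rd = 20),
        "flagged")
    expect_true(mcols(v)$depthFlagged)
})

test_that("depth threshold detection finds the first histogram peak", {
    # delta function at d returns d for any qualifying prominence
    for (d in c(2L, 5L, 40L))
        expect_equal(detectDepthThreshold(rep(d, 500)), d)
    # monotonically decreasing histogram falls back to the default
    decreasing <- rep(1:30, times = 30:1)
    expect_equal(detectDepthThreshold(decreasing, default = 5L), 5L)
    expect_equal(detectDepthThreshold(decreasing, default = 20L), 20L)
    # bimodal histogram: first peak wins, matching the brute-force oracle
    set.seed(13)
    bimodal <- c(rpois(600, 8), rpois(600, 50))
    expect_equal(detectDepthThreshold(bimodal, default = 20L),
                 firstPeakOracle(bimodal))
    expect_lt(detectDepthThreshold(bimodal, default = 20L), 15L)
    # a bump below the prominence floor is skipped, falling back to the
    # default (the oracle likewise finds no qualifying peak)
    faint <- c(rep(3L, 4), rep(1:60, times = rep(20, 60)))
    expect_true(is.na(firstPeakOracle(faint, 0.05)))
    expect_equal(detectDepthThreshold(faint, default = 20L,
                                      minProminence = 0.05), 20L)
    expect_error(detectDepthThreshold(integer()), "non-empty")
})

test_that("filtering applies the three usability criteria inclusively", {
    gm <- twoGeneModels()
    v <- makeVariants(
        pos      = c(300, 400, 500, 150, 950, 1300),
        adRef    = c(10, 10, 60, 10, 10, 3),
        adAlt    = c(9, 9, 40, 10, 10, 2),
        genotype = c("0/1", "0/1", "1/1", "0/1", "0/1", "0|1"))
    # pos 300: het, coding, rd 19 < 20 -> depth-filtered at 20
    # pos 400: rd 19 -> kept at minDepth 19 (boundary inclusive)
    # pos 500: homozygous at high depth -> removed
    # pos 150: inside gene A span but outside CDS (intron/UTR) -> removed
    # pos 950: intergenic -> removed
    # pos 1300: het, coding, rd 5
    f5 <- filterVariants(v, gm, minDepth = 5L)
    expect_equal(start(f5), c(300L, 400L, 1300L))
    f19 <- filterVariants(v, gm, minDepth = 19L)
    expect_equal(start(f19), c(300L, 400L))
    f20b <- filterVariants(v, gm, minDepth = 20L)
    expect_equal(length(f20b), 0L)
    expect_equal(unname(metadata(f19)$removed["not_heterozygous"]), 1L)
    expect_equal(unname(metadata(f19)$removed["non_coding"]), 2L)
    # idempotence
    ff <- filterVariants(f19, gm, minDepth = 19L)
    expect_identical(start(ff), start(f19))
})

test_that("no variant survives below threshold; the boundary survives", {
    gm <- twoGeneModels()
    set.seed(8)
    rd <- sample(1:40, 60, replace = TRUE)
    v <- makeVariants(pos = sample(201:800, 60), adRef = rd, adAlt = 0L,
                      rd = rd)
    for (thr in c(1L, 10L, 20L)) {
        f <- filterVariants(v, gm, minDepth = thr)
        expect_true(all(mcols(f)$rd >= thr))
        expect_equal(length(f), sum(rd >= thr))
    }
})

test_that("cDNA usability is judged from the gDNA heterozygous call", {
    gm <- twoGeneModels()
    gdna <- makeVariants(pos = c(300, 400), adRef = c(10, 10),
                         adAlt = c(10, 10), source = "gDNA")
    # monoallelic expression makes the cDNA call look homozygous
    cdna <- makeVariants(pos = c(300, 400, 600), adRef = c(20, 0, 9),
                         adAlt = c(0, 20, 9),
                         genotype = c("0/0", "1/1", "0/1"),
                         source = "cDNA")
    own <- filterVariants(cdna, gm, minDepth = 5L)
    expect_equal(start(own), 600L)
    viaGdna <- filterVariants(cdna, gm, minDepth = 5L, hetFrom = gdna)
    expect_equal(start(viaGdna), c(300L, 400L))
})

test_that("variants are assigned to every containing gene's CDS", {
    gm <- twoGeneModels()
    v <- makeVariants(pos = c(250, 700, 1500, 950), adRef = 10, adAlt = 10)
    byGene <- assignVariantsToGenes(v, gm)
    expect_named(byGene, c("geneA", "geneB"))
    expect_equal(length(byGene$geneA), 2L)
    expect_equal(length(byGene$geneB), 1L)
    # variants on unknown chromosomes are reported and left unassigned
    v2 <- makeVariants(pos = 500, adRef = 5, adAlt = 5, chrom = "chrX")
    expect_message(byGene2 <- assignVariantsToGenes(v2, gm),
                   "absent from the annotation")
    expect_true(all(lengths(byGene2) == 0L))
})
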