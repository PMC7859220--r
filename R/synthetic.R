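## Synthetic-data generator: seeded VCF + GFF3 + BED + truth-table fixtures
## with the statistical structure the downstream inference assumes.

#' Sample allelic read depths at a heterozygous site
#'
#' Draws the read count of allele 1 from Binomial(`depth`, `p`); allele 2
#' receives the remainder. This is the generator's noise model for the
#' per-sample allelic depths (`AD`) of a called variant.
#'
#' @param p Fraction of reads carrying allele 1, in \[0, 1\]. May be a
#'   vector recycled against `depth`.
#' @param depth Total read depth (non-negative integer), vectorized.
#' @return A two-column integer matrix with columns `ad1` and `ad2`;
#'   rows sum to `depth`.
#' @examples
#' set.seed(1)
#' sampleAllelicDepths(0.5, c(20, 30))
#' @export
sampleAllelicDepths <- function(p, depth) {
    if (any(p < 0 | p > 1)) stop("'p' must be in [0, 1]")
    if (any(depth < 0)) stop("'depth' must be >= 0")
    n <- max(length(p), length(depth))
    ad1 <- rbinom(n, size = depth, prob = p)
    cbind(ad1 = as.integer(ad1), ad2 = as.integer(depth - ad1))
}

## exact integer allocation of proportions: counts sum to n, each within
## one of n * p
allocateCounts <- function(n, props) {
    setNames(as.integer(diff(c(0L, round(cumsum(props) * n)))),
             names(props))
}

#' Simulate non-overlapping single-CDS gene models
#'
#' Places `nGenes` genes round-robin across `nChromosomes` chromosomes of
#' length `chromLength`, each with one CDS inset by `cdsMargin` bp from the
#' gene span, separated by `gap` bp. Placement is deterministic given the
#' arguments.
#'
#' @param nGenes,nChromosomes,chromLength See [SimConfig].
#' @param geneLength,gap,cdsMargin Gene span, inter-gene gap and UTR margin
#'   in bp.
#' @return A [GeneModels] object.
#' @examples
#' simulateGeneModels(10, 2, 1e5)
#' @export
simulateGeneModels <- function(nGenes, nChromosomes, chromLength,
                               geneLength = 1500L, gap = 500L,
                               cdsMargin = 100L) {
    nGenes <- as.integer(nGenes)
    perChrom <- ceiling(nGenes / nChromosomes)
    if (perChrom * (geneLength + gap) > chromLength)
        stop("genes not placeable without overlap at the given ",
             "chromosome length")
    chromIdx <- rep(seq_len(nChromosomes), each = perChrom)[seq_len(nGenes)]
    within <- sequence(tabulate(chromIdx, nChromosomes))
    start <- 1L + (within - 1L) * (geneLength + gap)
    chroms <- paste0("chr", seq_len(nChromosomes))
    sl <- setNames(rep(as.integer(chromLength), nChromosomes), chroms)
    ids <- sprintf("g%05d", seq_len(nGenes))
    genes <- GRanges(chroms[chromIdx],
                     IRanges(start, width = geneLength),
                     strand = rep_len(c("+", "-"), nGenes),
                     seqlengths = sl)
    names(genes) <- ids
    cds <- GRanges(chroms[chromIdx],
                   IRanges(start + cdsMargin,
                           start + geneLength - 1L - cdsMargin),
                   seqlengths = sl)
    cdsList <- split(cds, factor(ids, levels = ids))
    GeneModels(genes, cdsList)
}

## deterministic, timestamp-free VCFv4.2 emitter for the simulated records
writeSimVcf <- function(chrom, pos, ref, alt, ad1, ad2, path, chromLengths,
                        sampleName = "sim") {
    o <- order(match(chrom, names(chromLengths)), pos)
    header <- c(
        "##fileformat=VCFv4.2",
        sprintf("##contig=<ID=%s,length=%d>", names(chromLengths),
                as.integer(chromLengths)),
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,Description=",
               "\"Allelic depths for the ref and alt alleles in the order",
               " listed\">"),
        paste0("##FORMAT=<ID=DP,Number=1,Type=Integer,Description=",
               "\"Approximate read depth\">"),
        paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
              "FORMAT", sampleName, sep = "\t"))
    records <- paste(chrom[o], pos[o], ".", ref[o], alt[o], ".", ".", ".",
                     "GT:AD:DP",
                     sprintf("0/1:%d,%d:%d", ad1[o], ad2[o],
                             ad1[o] + ad2[o]),
                     sep = "\t")
    writeLines(c(header, records), path)
}

#' Simulate a complete allele-specific-expression dataset
#'
#' Generates gene models, assigns every gene an expression class and a true
#' allelic fraction, samples heterozygous coding SNVs with binomial allelic
#' depths in a gDNA and a cDNA sample (same loci in both), and writes four
#' files to `outdir`: `gdna.vcf`, `cdna.vcf` (VCFv4.2, one sample, genotype
#' `0/1`, `GT:AD:DP` fields, contigs declared, no timestamps), `genes.gff3`
#' and `truth.tsv`. Re-running with the same configuration and seed
#' reproduces byte-identical files.
#'
#' The truth table has one row per gene: `gene_id`, `class`, `cnv`,
#' `n_snvs`, `true_p` (fraction of cDNA reads from the reference-haplotype
#' allele), `true_gdna_p`, `expected_AEB` = \eqn{100 |2p - 1|},
#' `expected_AFB`, and `true_category` — the label implied by the expected
#' values at `thresholds` (genes without SNVs are `NO_SNV`).
#'
#' @param config A [SimConfig].
#' @param outdir Output directory (created if needed).
#' @param seed Integer seed; defaults to the configuration's seed.
#' @param thresholds [CategoryThresholds] used to derive `true_category`.
#' @return Invisibly, a list with file `paths`, the `truth` data.frame, the
#'   [GeneModels] and the chromosome lengths.
#' @examples
#' sim <- simulateASEData(SimConfig(nGenes = 50L, seed = 3L), tempfile())
#' head(sim$truth)
#' @export
simulateASEData <- function(config, outdir, seed = config@seed,
                            thresholds = CategoryThresholds()) {
    validObject(config)
    set.seed(seed)
    n <- config@nGenes
    models <- simulateGeneModels(n, config@nChromosomes, config@chromLength)
    ids <- geneIds(models)
    chromLengths <- seqlengths(geneSpans(models))

    ## SNV counts: exact zero-SNV allocation, Poisson tail elsewhere
    s <- config@snvsPerGene
    nZero <- round(s$pZero * n)
    nSnvs <- as.integer(s$min) + rpois(n, s$lambda)
    nSnvs[sample.int(n, nZero)] <- 0L
    cdsW <- sum(width(cdsRanges(models)))
    nSnvs <- pmin(nSnvs, as.integer(cdsW))

    ## expression class: exact mixture counts over all genes
    classCounts <- allocateCounts(n, config@classMixture)
    class <- sample(rep(names(classCounts), classCounts))

    ## CNV genes drawn among SNV-bearing genes
    withSnv <- which(nSnvs > 0L)
    nCnv <- round(config@cnvFraction * n)
    if (nCnv > length(withSnv))
        stop("'cnvFraction' exceeds the fraction of SNV-bearing genes")
    cnv <- logical(n)
    cnv[sample(withSnv, nCnv)] <- TRUE

    ## true allelic fractions; p is the fraction of reads carrying the
    ## reference-haplotype allele, so multi-SNV genes are sign-concordant
    mag <- numeric(n)
    mag[class == "balanced"] <- 0.5
    mag[class == "moderate"] <- runif(sum(class == "moderate"), 0.60, 0.80)
    mag[class == "monoallelic"] <- runif(sum(class == "monoallelic"), 0.95, 1)
    side <- sample(c(TRUE, FALSE), n, replace = TRUE)
    trueP <- ifelse(side, mag, 1 - mag)
    trueGdnaP <- rep(0.5, n)
    if (any(cnv)) {
        ratio <- runif(sum(cnv), 2, 3)
        gp <- ratio / (ratio + 1)
        gSide <- sample(c(TRUE, FALSE), sum(cnv), replace = TRUE)
        trueGdnaP[cnv] <- ifelse(gSide, gp, 1 - gp)
        trueP[cnv] <- trueGdnaP[cnv]  # dosage-driven expression
    }

    expectedAEB <- 100 * abs(2 * trueP - 1)
    expectedAFB <- 100 * abs(2 * trueGdnaP - 1)
    trueCategory <- ifelse(nSnvs == 0L, "NO_SNV",
        ifelse(expectedAFB > thresholds@afbMax, "EXCLUDED_AFB",
        ifelse(expectedAEB <= thresholds@aebBaeMax, "BAE",
        ifelse(expectedAEB <= thresholds@aebAseMax, "ASE", "MAE"))))

    ## SNV loci within each gene's CDS
    geneOf <- rep(seq_len(n), nSnvs)
    cdsFlat <- unlist(cdsRanges(models), use.names = FALSE)
    pos <- unlist(lapply(which(nSnvs > 0L), function(i) {
        sort(sample(seq(start(cdsFlat)[i], end(cdsFlat)[i]), nSnvs[i]))
    }))
    chrom <- as.character(seqnames(geneSpans(models)))[geneOf]

    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, length(pos), replace = TRUE)
    shift <- sample.int(3L, length(pos), replace = TRUE)
    alt <- bases[(match(ref, bases) - 1L + shift) %% 4L + 1L]

    dG <- config@gdnaDepth(length(pos))
    dC <- config@cdnaDepth(length(pos))
    if (any(dG < 0) || any(dC < 0) || any(dG != floor(dG)) ||
        any(dC != floor(dC)))
        stop("depth samplers must return non-negative integers")
    adG <- sampleAllelicDepths(trueGdnaP[geneOf], dG)
    adC <- sampleAllelicDepths(trueP[geneOf], dC)

    ## optional intergenic SNVs in the gaps between genes (balanced)
    if (config@intergenicSnvs > 0L) {
        spans <- geneSpans(models)
        gaps <- GenomicRanges::gaps(spans)
        gaps <- gaps[strand(gaps) == "*" & width(gaps) > 2L]
        gi <- sample(length(gaps), config@intergenicSnvs, replace = TRUE)
        gpos <- start(gaps)[gi] +
            floor(runif(config@intergenicSnvs) * width(gaps)[gi])
        gchrom <- as.character(seqnames(gaps))[gi]
        gref <- sample(bases, config@intergenicSnvs, replace = TRUE)
        gshift <- sample.int(3L, config@intergenicSnvs, replace = TRUE)
        galt <- bases[(match(gref, bases) - 1L + gshift) %% 4L + 1L]
        gdG <- config@gdnaDepth(config@intergenicSnvs)
        gdC <- config@cdnaDepth(config@intergenicSnvs)
        gadG <- sampleAllelicDepths(0.5, gdG)
        gadC <- sampleAllelicDepths(0.5, gdC)
        chrom <- c(chrom, gchrom); pos <- c(pos, gpos)
        ref <- c(ref, gref); alt <- c(alt, galt)
        adG <- rbind(adG, gadG); adC <- rbind(adC, gadC)
    }

    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(gdnaVcf = file.path(outdir, "gdna.vcf"),
                  cdnaVcf = file.path(outdir, "cdna.vcf"),
                  annotation = file.path(outdir, "genes.gff3"),
                  truth = file.path(outdir, "truth.tsv"))
    writeSimVcf(chrom, pos, ref, alt, adG[, 1], adG[, 2], paths$gdnaVcf,
                chromLengths)
    writeSimVcf(chrom, pos, ref, alt, adC[, 1], adC[, 2], paths$cdnaVcf,
                chromLengths)
    writeGeneModelsGff3(models, paths$annotation)

    truth <- data.frame(gene_id = ids, class = class, cnv = cnv,
                        n_snvs = nSnvs, true_p = trueP,
                        true_gdna_p = trueGdnaP,
                        expected_AEB = expectedAEB,
                        expected_AFB = expectedAFB,
                        true_category = trueCategory,
                        stringsAsFactors = FALSE)
    write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(list(paths = paths, truth = truth, models = models,
                   chromLengths = chromLengths))
}

## GFF3 writer for two-level gene/CDS models (via rtracklayer)
writeGeneModelsGff3 <- function(models, path) {
    spans <- geneSpans(models)
    cdsFlat <- unlist(cdsRanges(models), use.names = FALSE)
    geneOf <- rep(geneIds(models), lengths(cdsRanges(models)))
    g <- spans
    mcols(g) <- DataFrame(source = "aasekit", type = "gene",
                          ID = geneIds(models))
    k <- cdsFlat
    strand(k) <- strand(spans)[match(geneOf, geneIds(models))]
    mcols(k) <- DataFrame(source = "aasekit", type = "CDS",
                          ID = paste0(geneOf, ".cds"), Parent = geneOf,
                          phase = 0L)
    all <- suppressWarnings(c(g, k))
    names(all) <- NULL
    all <- all[order(as.integer(seqnames(all)), start(all),
                     mcols(all)$type != "gene")]
    rtracklayer::export(all, path, format = "gff3")
    invisible(path)
}

#' Simulate a histone-mark peak set over gene categories
#'
#' Places `nPeaks` peaks of width `peakWidth` on the chromosomes of
#' `genes`, preferentially over genes of `targetCategory` with the given
#' odds: a uniformly drawn candidate peak overlapping a target-category
#' gene is always kept, while other candidates are kept with probability
#' `1/enrichmentBias` (for bias >= 1; for bias < 1 the roles reverse).
#' `enrichmentBias = 1` therefore yields uniform placement and
#' `enrichmentBias = Inf` places peaks only over target genes.
#'
#' @param genes A [GeneModels] (or `GRanges` of gene spans with seqlengths).
#' @param categories Named character vector, gene id to category label.
#' @param targetCategory The preferred category; must appear in
#'   `categories` (unless `enrichmentBias` is 1).
#' @param enrichmentBias Placement odds, >= 0.
#' @param nPeaks,peakWidth Number and width (bp) of peaks.
#' @param markName Mark name carried by the returned [PeakSet].
#' @return A [PeakSet].
#' @examples
#' gm <- simulateGeneModels(20, 2, 1e5)
#' cat20 <- setNames(rep(c("BAE", "MAE"), 10), geneIds(gm))
#' set.seed(1)
#' simulatePeakSet(gm, cat20, "MAE", enrichmentBias = Inf, nPeaks = 10)
#' @export
simulatePeakSet <- function(genes, categories, targetCategory = "MAE",
                            enrichmentBias = 1, nPeaks = 100L,
                            peakWidth = 1000L, markName = "H3K9me2") {
    if (is(genes, "GeneModels")) genes <- geneSpans(genes)
    if (enrichmentBias < 0) stop("'enrichmentBias' must be >= 0")
    if (enrichmentBias != 1 &&
        !targetCategory %in% categories)
        stop("unknown category label '", targetCategory, "'")
    sl <- seqlengths(genes)
    if (any(is.na(sl))) stop("gene spans must carry seqlengths")
    target <- genes[names(genes) %in%
                    names(categories)[categories == targetCategory]]
    keepProb <- function(onTarget) {
        if (enrichmentBias >= 1)
            ifelse(onTarget, 1, 1 / enrichmentBias)
        else ifelse(onTarget, enrichmentBias, 1)
    }
    out <- GRanges(seqlengths = sl)
    while (length(out) < nPeaks) {
        m <- max(2L * nPeaks, 64L)
        chr <- sample(names(sl), m, replace = TRUE)
        start <- 1L + floor(runif(m) * (sl[chr] - peakWidth + 1))
        cand <- GRanges(chr, IRanges(start, width = peakWidth),
                        seqlengths = sl)
        onTarget <- countOverlaps(cand, target) > 0L
        keep <- runif(m) < keepProb(onTarget)
        out <- c(out, cand[keep])
    }
    PeakSet(out[seq_len(nPeaks)], markName = markName)
}

#' Write a peak set to a BED file
#'
#' @param peaks A [PeakSet] (or `GRanges`).
#' @param path Output BED path.
#' @return The path, invisibly.
#' @export
writePeakSet <- function(peaks, path) {
    rtracklayer::export(granges(peaks), path, format = "bed")
    invisible(path)
}

#' Read a peak set from a BED file
#'
#' @param path BED3+ file of peak intervals.
#' @param markName Mark name (defaults to the file stem).
#' @param chromLengths Named vector of chromosome lengths (required for
#'   randomization).
#' @return A [PeakSet].
#' @export
readPeakSet <- function(path, markName = NULL, chromLengths = NULL) {
    if (is.null(markName))
        markName <- sub("\\.[^.]*$", "", basename(path))
    gr <- rtracklayer::import(path, format = "bed")
    PeakSet(gr, markName = markName, chromLengths = chromLengths)
}
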