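# Independent oracles and small fixture builders, kept free of the code
# paths they check.

suppressPackageStartupMessages(library(GenomicRanges))

# exact expectation of the per-SNV percent bias at read depth rd and
# allele-1 fraction p, by direct binomial enumeration
enumPerSnvBias <- function(rd, p) {
    k <- 0:rd
    sum(abs(2 * k - rd) / rd * 100 * dbinom(k, rd, p))
}

# one-sided Fisher p for over-representation by direct summation over
# binomial coefficients (no phyper/dhyper)
hypergeomTailOracle <- function(k, n, K, N) {
    j <- k:min(n, K)
    sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# first qualifying interior maximum of a window-3 smoothed depth
# histogram, by brute-force scan (plateaus resolved by raw count)
firstPeakOracle <- function(depths, minProminence = 0.01) {
    maxd <- max(depths)
    counts <- tabulate(depths, nbins = maxd)
    padded <- c(counts[1], counts, 0)
    smooth <- vapply(seq_len(maxd),
                     function(d) mean(padded[d:(d + 2)]), numeric(1))
    minCount <- minProminence * length(depths)
    for (d in 2:maxd) {
        lo <- d
        hi <- d
        while (hi < maxd && smooth[hi + 1] == smooth[d]) hi <- hi + 1
        left <- smooth[d - 1]
        right <- if (hi < maxd) smooth[hi + 1] else 0
        if (smooth[d] >= left && smooth[d] >= right &&
            smooth[d] > min(left, right) && smooth[d] >= minCount) {
            plateau <- lo:hi
            return(plateau[which.max(counts[plateau])])
        }
    }
    NA_integer_
}

# minimal VCF writer for hand-crafted records (header + given body lines)
writeTinyVcf <- function(lines, path,
                         contigs = c(chr1 = 1000000L)) {
    header <- c(
        "##fileformat=VCFv4.2",
        sprintf("##contig=<ID=%s,length=%d>", names(contigs), contigs),
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
        "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
        paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
              "INFO", "FORMAT", "s1", sep = "\t"))
    writeLines(c(header, lines), path)
    path
}

vcfLine <- function(chrom, pos, ref, alt, gt, ad, dp) {
    paste(chrom, pos, ".", ref, alt, ".", ".", ".", "GT:AD:DP",
          paste0(gt, ":", paste(ad, collapse = ","), ":", dp), sep = "\t")
}

# simple two-gene annotation on chr1: gene A CDS 201-800 (span 101-900),
# gene B CDS 1201-1800 (span 1101-1900)
twoGeneModels <- function() {
    sl <- c(chr1 = 1000000L)
    genes <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(c(101, 1101), c(900, 1900)), seqlengths = sl)
    names(genes) <- c("geneA", "geneB")
    cds <- GenomicRanges::GRangesList(
        geneA = GenomicRanges::GRanges("chr1",
            IRanges::IRanges(201, 800), seqlengths = sl),
        geneB = GenomicRanges::GRanges("chr1",
            IRanges::IRanges(1201, 1800), seqlengths = sl))
    GeneModels(genes, cds)
}

# sample one value from an integer range, robust to length-1 ranges
sampleOne <- function(rng) if (length(rng) == 1L) rng else sample(rng, 1L)

makeVariants <- function(pos, adRef, adAlt, rd = adRef + adAlt,
                         genotype = "0/1", source = "gDNA",
                         chrom = "chr1") {
    AllelicVariants(rep_len(chrom, length(pos)), pos,
                    ref = rep_len("A", length(pos)),
                    alt = rep_len("G", length(pos)), adRef = adRef,
                    adAlt = adAlt, rd = rd, genotype = genotype,
                    source = source)
}
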