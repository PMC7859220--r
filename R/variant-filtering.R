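## Reading variant calls and applying the three usability filters:
## heterozygous call, coding position, minimum read depth.

#' Read biallelic SNVs with allelic depths from a VCF
#'
#' Parses a VCF (via [VariantAnnotation::readVcf]) into an
#' [AllelicVariants] object, keeping one record per biallelic SNV.
#' Indels, multi-allelic records and records missing the per-sample `AD`
#' or `DP` fields are dropped; the counts of dropped records are reported
#' in a message and kept in `metadata()` under `dropped`.
#'
#' @param path VCF file (v4.2; one sample, or `sample` named).
#' @param source `"gDNA"` or `"cDNA"` — which template the calls come from.
#' @param sample Sample column to use; defaults to the first.
#' @return An [AllelicVariants] object.
#' @examples
#' sim <- simulateASEData(SimConfig(nGenes = 20L, seed = 1L), tempfile())
#' readAllelicVariants(sim$paths$gdnaVcf, "gDNA")
#' @export
readAllelicVariants <- function(path, source = c("gDNA", "cDNA"),
                                sample = 1L) {
    source <- match.arg(source)
    vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
    if (ncol(vcf) < 1L)
        stop("VCF has no sample column: ", path)
    rr <- SummarizedExperiment::rowRanges(vcf)
    refA <- as.character(VariantAnnotation::ref(vcf))
    altL <- VariantAnnotation::alt(vcf)
    nAlt <- lengths(altL)

    multi <- nAlt != 1L
    altA <- rep(NA_character_, length(vcf))
    altA[!multi] <- as.character(unlist(altL[!multi]))
    indel <- nchar(refA) != 1L | (!multi & nchar(altA) != 1L) |
        (!multi & !altA %in% c("A", "C", "G", "T"))
    indel[multi] <- FALSE

    gt <- VariantAnnotation::geno(vcf)$GT[, sample]
    adRaw <- VariantAnnotation::geno(vcf)$AD[, sample]
    dp <- VariantAnnotation::geno(vcf)$DP[, sample]
    adLen <- lengths(adRaw)
    noDepth <- !multi & !indel &
        (adLen < 2L | is.na(dp) |
         vapply(adRaw, function(x) any(is.na(x[1:2])), logical(1)))

    keep <- !multi & !indel & !noDepth
    dropped <- c(multiallelic = sum(multi), indel = sum(indel),
                 missing_depth = sum(noDepth))
    if (sum(dropped) > 0L)
        message("readAllelicVariants: dropped ", sum(dropped),
                " record(s) [", paste(names(dropped), dropped, sep = "=",
                collapse = ", "), "]")

    adMat <- if (any(keep))
        matrix(unlist(lapply(adRaw[keep], `[`, 1:2)), ncol = 2L,
               byrow = TRUE)
    else matrix(integer(), ncol = 2L)
    out <- AllelicVariants(
        chrom = as.character(seqnames(rr))[keep],
        pos = start(rr)[keep],
        ref = refA[keep], alt = altA[keep],
        adRef = adMat[, 1L], adAlt = adMat[, 2L],
        rd = as.integer(dp[keep]),
        genotype = unname(gt[keep]), source = source)
    sl <- seqlengths(rr)
    if (!all(is.na(sl)))
        seqlengths(out) <- sl[seqlevels(out)]
    metadata(out)$dropped <- dropped
    out
}

#' Detect a depth threshold from the read-depth frequency distribution
#'
#' Returns the depth at the first interior local maximum of the integer
#' read-depth histogram, after moving-average smoothing (window 3),
#' scanning upward from depth 1. A maximum qualifies only if its smoothed
#' count is at least `minProminence` of the total variant count. Within a
#' tied (plateau) maximum the depth with the highest raw count is
#' returned. If no interior maximum qualifies (e.g. a monotonically
#' decreasing histogram), `default` is returned — 20 for gDNA and 5 for
#' cDNA are the conventional fixed cutoffs, set at the first peak of the
#' respective depth distributions.
#'
#' @param depths Integer read depths of all variants in a sample.
#' @param default Fallback threshold when no qualifying peak exists.
#' @param minProminence Minimum smoothed count at the peak, as a fraction
#'   of the number of variants.
#' @return A single integer depth.
#' @examples
#' detectDepthThreshold(rep(40L, 1000L), default = 20L)
#' @export
detectDepthThreshold <- function(depths, default = 20L,
                                 minProminence = 0.01) {
    if (length(depths) == 0L) stop("'depths' must be non-empty")
    depths <- as.integer(depths)
    maxd <- max(depths, 1L)
    counts <- tabulate(depths, nbins = maxd)  # counts[d] = #variants at d
    ## replicate the left boundary so a decreasing histogram does not gain
    ## a spurious rise at depth 2 from zero-padding
    padded <- c(counts[1L], counts, 0)
    smooth <- (padded[seq_len(maxd)] + padded[seq_len(maxd) + 1L] +
               padded[seq_len(maxd) + 2L]) / 3
    minCount <- minProminence * length(depths)
    d <- 2L
    while (d <= maxd) {
        left <- smooth[d - 1L]
        if (smooth[d] >= left && smooth[d] >= minCount) {
            ## extend across the plateau of equal smoothed counts
            hi <- d
            while (hi < maxd && smooth[hi + 1L] == smooth[d]) hi <- hi + 1L
            after <- if (hi < maxd) smooth[hi + 1L] else 0
            if (after <= smooth[d] && smooth[d] > min(left, after)) {
                plateau <- d:hi
                return(plateau[which.max(counts[plateau])])
            }
            d <- hi + 1L
        } else d <- d + 1L
    }
    as.integer(default)
}

## het sites usable for allelic quantification, as chrom:pos keys
hetSiteKeys <- function(variants) {
    het <- mcols(variants)$genotype %in% HET_GENOTYPES
    paste0(as.character(seqnames(variants))[het], ":",
           start(variants)[het])
}

#' Filter variants to heterozygous coding SNVs with sufficient depth
#'
#' Keeps exactly those variants that are (i) heterozygous, (ii) inside
#' some gene's CDS, and (iii) of read depth `rd >= minDepth` (the boundary
#' is inclusive). Order is preserved and the operation is idempotent.
#' Removal counts per criterion (applied independently) are stored in
#' `metadata()` under `removed`.
#'
#' Heterozygosity is judged from the variant's own genotype call unless
#' `hetFrom` supplies a gDNA call set: then a variant is usable when its
#' locus is called heterozygous in gDNA, regardless of its own genotype
#' string. This is how cDNA calls must be treated — a monoallelically
#' expressed gene yields cDNA reads from one allele only, so its cDNA
#' genotype can look homozygous at a genuinely heterozygous locus.
#'
#' @param variants An [AllelicVariants] object.
#' @param genes A [GeneModels] object.
#' @param minDepth Minimum read depth (inclusive); conventionally 20 for
#'   gDNA and 5 for cDNA.
#' @param hetFrom Optional gDNA [AllelicVariants] defining heterozygous
#'   loci (recommended when `variants` are cDNA calls).
#' @return The filtered [AllelicVariants].
#' @examples
#' sim <- simulateASEData(SimConfig(nGenes = 20L, seed = 1L), tempfile())
#' v <- readAllelicVariants(sim$paths$gdnaVcf, "gDNA")
#' filterVariants(v, sim$models, minDepth = 20L)
#' @export
filterVariants <- function(variants, genes, minDepth = 20L,
                           hetFrom = NULL) {
    if (minDepth < 0L) stop("'minDepth' must be >= 0")
    if (is.null(hetFrom)) {
        het <- mcols(variants)$genotype %in% HET_GENOTYPES
    } else {
        keys <- paste0(as.character(seqnames(variants)), ":",
                       start(variants))
        het <- keys %in% hetSiteKeys(hetFrom)
    }
    cdsFlat <- unlist(cdsRanges(genes), use.names = FALSE)
    coding <- suppressWarnings(
        countOverlaps(variants, cdsFlat, ignore.strand = TRUE)) > 0L
    deep <- mcols(variants)$rd >= minDepth
    keep <- het & coding & deep
    out <- variants[keep]
    metadata(out)$removed <- c(
        not_heterozygous = sum(!het), non_coding = sum(!coding),
        low_depth = sum(!deep), total_removed = sum(!keep))
    out
}

#' Assign variants to the genes whose CDS contains them
#'
#' Every variant is attached to each gene whose CDS intervals contain its
#' position (a variant inside two overlapping genes is counted for both,
#' with a warning). Genes without any assigned variant appear with empty
#' elements — they feed the NO_SNV category. Variants on chromosomes
#' absent from the annotation are left unassigned and counted in a
#' message.
#'
#' @param variants A filtered [AllelicVariants] object.
#' @param genes A [GeneModels] object.
#' @return A named list (one element per gene, in `geneIds` order) of
#'   [AllelicVariants].
#' @export
assignVariantsToGenes <- function(variants, genes) {
    cdsFlat <- unlist(cdsRanges(genes), use.names = FALSE)
    geneOfCds <- rep(seq_along(geneIds(genes)), lengths(cdsRanges(genes)))
    offAnno <- !as.character(seqnames(variants)) %in%
        seqlevels(geneSpans(genes))
    if (any(offAnno))
        message("assignVariantsToGenes: ", sum(offAnno),
                " variant(s) on chromosomes absent from the annotation")
    hits <- suppressWarnings(
        findOverlaps(variants, cdsFlat, ignore.strand = TRUE))
    geneHit <- geneOfCds[subjectHits(hits)]
    if (anyDuplicated(queryHits(hits)))
        warning("some variants fall in more than one gene; ",
                "they are assigned to every containing gene")
    idx <- split(queryHits(hits),
                 factor(geneHit, levels = seq_along(geneIds(genes))))
    out <- lapply(idx, function(i) variants[i])
    names(out) <- geneIds(genes)
    out
}
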