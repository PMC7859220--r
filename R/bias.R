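## The core statistic: per-SNV allelic bias, per-gene averages (AFB/AEB),
## multi-SNV concordance, and category classification.

#' Percent allelic bias of a single variant
#'
#' The unsigned per-variant statistic
#' \deqn{\left| \frac{AD(ref)}{RD} - \frac{AD(alt)}{RD} \right| \times 100,}
#' a percent in \[0, 100\] that is 0 for perfectly balanced allelic depths
#' and 100 for a fully monoallelic site. Invariant under swapping the two
#' alleles.
#'
#' @param x An [AllelicVariants] object, or a numeric vector of
#'   reference-allele depths.
#' @param adAlt,rd Alternate-allele depths and total read depths (ignored
#'   when `x` is an [AllelicVariants]).
#' @return Numeric vector of percent biases.
#' @examples
#' perSnvBias(15, 5, 20)  # 50
#' @export
perSnvBias <- function(x, adAlt = NULL, rd = NULL) {
    if (is(x, "AllelicVariants")) {
        m <- mcols(x)
        adRef <- m$adRef; adAlt <- m$adAlt; rd <- m$rd
    } else adRef <- x
    if (any(rd == 0))
        stop("per-SNV bias is undefined at rd == 0")
    abs(adRef / rd - adAlt / rd) * 100
}

#' Average percent allelic bias of a gene
#'
#' The arithmetic mean of [perSnvBias()] over the N heterozygous variants
#' mapped on a gene — the AFB when the variants are gDNA calls, the AEB
#' when they are cDNA calls. An empty variant set signals the NO_SNV state
#' and returns `NA` rather than a number.
#'
#' Note the statistic's noise floor: even at a truly balanced locus the
#' expected per-SNV bias is positive (37.5 at depth 5, about 17.6 at depth
#' 20, shrinking as \eqn{\sqrt{2/(\pi\,rd)}\times 100}), so low-depth
#' variants inflate apparent bias.
#'
#' @param variants An [AllelicVariants] object holding one gene's variants
#'   (all from the same source), or a numeric vector of per-SNV biases.
#' @return The mean percent bias, or `NA_real_` for an empty input.
#' @examples
#' geneBias(c(40, 60))  # 50
#' @export
geneBias <- function(variants) {
    if (is(variants, "AllelicVariants")) {
        if (length(variants) == 0L) return(NA_real_)
        src <- unique(mcols(variants)$source)
        if (length(src) > 1L)
            stop("a gene's variants must come from a single source")
        mean(perSnvBias(variants))
    } else {
        if (length(variants) == 0L) return(NA_real_)
        mean(variants)
    }
}

#' Check directional concordance of a gene's expression bias
#'
#' A gene's multi-SNV evidence is concordant when all variants whose
#' per-SNV bias exceeds `directionThreshold` agree on which allele is
#' over-represented (the sign of `adAlt - adRef`). Variants below the
#' threshold carry no reliable direction and are ignored; single-SNV genes
#' are vacuously concordant. Because reads are mapped against one
#' reference haplotype, the ref/alt sign is haplotype-consistent across a
#' gene's SNVs.
#'
#' @param variants An [AllelicVariants] object (one gene, cDNA calls).
#' @param directionThreshold Percent bias below which a variant's
#'   direction is disregarded.
#' @return `TRUE` if concordant.
#' @examples
#' v <- AllelicVariants("chr1", c(10, 20), ref = "A", alt = "G",
#'     adRef = c(2, 30), adAlt = c(38, 6), rd = c(40, 36), source = "cDNA")
#' concordanceCheck(v)  # FALSE: biases point to opposite alleles
#' @export
concordanceCheck <- function(variants, directionThreshold = 20) {
    if (length(variants) == 0L)
        stop("'variants' must contain at least one variant")
    if (length(variants) == 1L) return(TRUE)
    m <- mcols(variants)
    strong <- perSnvBias(variants) > directionThreshold
    s <- sign(m$adAlt[strong] - m$adRef[strong])
    length(unique(s[s != 0])) <= 1L
}

#' Classify genes from AFB, AEB and concordance
#'
#' Vectorized classification at the printed inequalities: genes with
#' `afb > afbMax` are `EXCLUDED_AFB` (genomic copy-number imbalance
#' masquerades as expression bias); discordant genes are `DISCORDANT`;
#' otherwise `aeb <= aebBaeMax` is `BAE`, `aeb <= aebAseMax` is `ASE`, and
#' above that `MAE`. A missing (`NA`) AFB or AEB yields `NO_SNV`.
#'
#' @param afb,aeb Percent biases in \[0, 100\] (`NA` allowed).
#' @param concordant Logical vector.
#' @param thresholds A [CategoryThresholds].
#' @return A character vector of category labels.
#' @examples
#' classifyGenes(c(10, 10, 25), c(15, 61, 90), TRUE)
#' @export
classifyGenes <- function(afb, aeb, concordant = TRUE,
                          thresholds = CategoryThresholds()) {
    n <- max(length(afb), length(aeb), length(concordant))
    afb <- rep_len(afb, n); aeb <- rep_len(aeb, n)
    concordant <- rep_len(concordant, n)
    ok <- !is.na(afb) & !is.na(aeb)
    if (any(c(afb[ok], aeb[ok]) < 0 | c(afb[ok], aeb[ok]) > 100))
        stop("'afb' and 'aeb' must be percentages in [0, 100]")
    out <- rep("NO_SNV", n)
    out[ok & afb > thresholds@afbMax] <- "EXCLUDED_AFB"
    rest <- ok & afb <= thresholds@afbMax
    out[rest & !concordant] <- "DISCORDANT"
    rest <- rest & concordant
    out[rest & aeb <= thresholds@aebBaeMax] <- "BAE"
    out[rest & aeb > thresholds@aebBaeMax &
        aeb <= thresholds@aebAseMax] <- "ASE"
    out[rest & aeb > thresholds@aebAseMax] <- "MAE"
    out
}

#' Quantify and classify allelic bias for every annotated gene
#'
#' Computes AFB from each gene's usable gDNA variants and AEB from its
#' usable cDNA variants, checks multi-SNV concordance of the cDNA
#' evidence, and classifies every annotated gene. The classification
#' needs both statistics, so a gene must have at least one usable SNV in
#' each sample; genes lacking either are `NO_SNV` (sites present in gDNA
#' but absent from the cDNA call set are not imputed as zero expression —
#' absence of a call is ambiguous). The gDNA and cDNA variant sets need
#' not be identical at a gene; both counts are reported.
#'
#' @param gdnaByGene,cdnaByGene Named lists of [AllelicVariants] as
#'   produced by [assignVariantsToGenes()] from depth-filtered gDNA and
#'   cDNA calls.
#' @param genes A [GeneModels] object (the annotated gene universe).
#' @param thresholds A [CategoryThresholds].
#' @param directionThreshold Passed to [concordanceCheck()].
#' @param totalGenes Denominator for category percentages; defaults to the
#'   number of annotated genes.
#' @return A [GeneBiasTable], one row per gene, sorted by gene id.
#' @seealso [runASEAnalysis()] for the one-call pipeline.
#' @export
quantifyAllelicBias <- function(gdnaByGene, cdnaByGene, genes,
                                thresholds = CategoryThresholds(),
                                directionThreshold = 20,
                                totalGenes = length(genes)) {
    ids <- sort(geneIds(genes))
    chrom <- as.character(seqnames(geneSpans(genes)))[match(
        ids, geneIds(genes))]
    g <- gdnaByGene[ids]
    c_ <- cdnaByGene[ids]
    nG <- vapply(g, function(v) if (is.null(v)) 0L else length(v),
                 integer(1))
    nC <- vapply(c_, function(v) if (is.null(v)) 0L else length(v),
                 integer(1))
    afb <- ifelse(nG > 0L,
                  vapply(g, function(v) if (length(v)) geneBias(v)
                         else NA_real_, numeric(1)), NA_real_)
    aeb <- ifelse(nC > 0L,
                  vapply(c_, function(v) if (length(v)) geneBias(v)
                         else NA_real_, numeric(1)), NA_real_)
    conc <- vapply(c_, function(v) {
        if (is.null(v) || length(v) == 0L) TRUE
        else concordanceCheck(v, directionThreshold)
    }, logical(1))
    category <- classifyGenes(afb, aeb, conc, thresholds)
    lost <- sum(nG > 0L & nC == 0L)
    if (lost > 0L)
        message("quantifyAllelicBias: ", lost, " gene(s) with gDNA SNVs ",
                "but no usable cDNA SNV -> NO_SNV")
    new("GeneBiasTable",
        DataFrame(geneId = ids, chrom = chrom, nGdnaSnvs = unname(nG),
                  nCdnaSnvs = unname(nC), afb = unname(afb),
                  aeb = unname(aeb), concordant = unname(conc),
                  category = category),
        thresholds = thresholds, totalGenes = as.integer(totalGenes))
}

#' Summarise category counts and percentages
#'
#' @param x A [GeneBiasTable].
#' @return A data.frame with `category`, `count` and `pct` — the
#'   percentage of the total annotated genes.
#' @export
categorySummary <- function(x) {
    stopifnot(is(x, "GeneBiasTable"))
    counts <- table(factor(x$category, levels = ASE_CATEGORIES))
    data.frame(category = names(counts), count = as.integer(counts),
               pct = 100 * as.integer(counts) / x@totalGenes,
               row.names = NULL, stringsAsFactors = FALSE)
}
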