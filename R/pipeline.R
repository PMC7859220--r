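## One-call pipeline: VCFs + annotation in, classified gene table out.

#' Run the allele-specific-expression pipeline
#'
#' Reads gDNA and cDNA variant calls and a gene annotation, applies the
#' usability filters (heterozygous by the gDNA call, inside a CDS, read
#' depth at or above the per-sample cutoff), computes per-gene AFB and
#' AEB and classifies every annotated gene.
#'
#' With `autoDepth = TRUE` the depth cutoffs are taken from the first
#' peak of each sample's read-depth frequency distribution
#' ([detectDepthThreshold()]), falling back to `minGdnaDepth` /
#' `minCdnaDepth` when no peak qualifies; otherwise the fixed cutoffs are
#' used directly.
#'
#' @param gdnaVcf,cdnaVcf VCF paths with per-sample `AD` and `DP` fields.
#' @param annotation GFF3 or BED12 gene-model path, or a [GeneModels].
#' @param minGdnaDepth,minCdnaDepth Depth cutoffs (inclusive).
#' @param autoDepth Detect cutoffs from the depth histograms.
#' @param thresholds A [CategoryThresholds].
#' @param directionThreshold Concordance direction threshold, percent.
#' @param excludeGenes Optional character vector of gene ids to drop from
#'   the universe before analysis (e.g. an external copy-number-variant
#'   gene list).
#' @return A list with the [GeneBiasTable] (`table`), the
#'   [categorySummary()] data.frame (`summary`) and the depth cutoffs
#'   used (`depths`).
#' @examples
#' sim <- simulateASEData(SimConfig(nGenes = 50L, seed = 2L), tempfile())
#' res <- runASEAnalysis(sim$paths$gdnaVcf, sim$paths$cdnaVcf, sim$models)
#' res$summary
#' @export
runASEAnalysis <- function(gdnaVcf, cdnaVcf, annotation,
                           minGdnaDepth = 20L, minCdnaDepth = 5L,
                           autoDepth = FALSE,
                           thresholds = CategoryThresholds(),
                           directionThreshold = 20,
                           excludeGenes = NULL) {
    genes <- if (is(annotation, "GeneModels")) annotation
             else readGeneModels(annotation)
    if (!is.null(excludeGenes)) {
        keep <- !geneIds(genes) %in% excludeGenes
        genes <- GeneModels(geneSpans(genes)[keep],
                            cdsRanges(genes)[keep])
    }
    gdna <- readAllelicVariants(gdnaVcf, "gDNA")
    cdna <- readAllelicVariants(cdnaVcf, "cDNA")
    dG <- if (autoDepth)
        detectDepthThreshold(mcols(gdna)$rd, default = minGdnaDepth)
    else as.integer(minGdnaDepth)
    dC <- if (autoDepth)
        detectDepthThreshold(mcols(cdna)$rd, default = minCdnaDepth)
    else as.integer(minCdnaDepth)
    gdnaF <- filterVariants(gdna, genes, minDepth = dG)
    cdnaF <- filterVariants(cdna, genes, minDepth = dC, hetFrom = gdna)
    tab <- quantifyAllelicBias(
        assignVariantsToGenes(gdnaF, genes),
        assignVariantsToGenes(cdnaF, genes),
        genes, thresholds = thresholds,
        directionThreshold = directionThreshold)
    list(table = tab, summary = categorySummary(tab),
         depths = c(gDNA = dG, cDNA = dC))
}
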