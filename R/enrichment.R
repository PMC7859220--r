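## GO-term over-representation of a gene category against the annotated
## background (one-sided Fisher exact test on the 2x2 table).

#' Fisher exact GO-term enrichment of a gene category
#'
#' For every term annotating at least one category gene, tests
#' over-representation of the term in the category against the background
#' with the one-sided Fisher exact test on the 2x2 table
#' \eqn{[[k, n-k], [K-k, (N-n)-(K-k)]]} — computed as the hypergeometric
#' upper tail \eqn{P(X \ge k)}. No multiple-testing correction is applied
#' by default: rows with raw `p < alpha` are flagged `enriched`
#' (Benjamini-Hochberg adjusted p-values are added with
#' `adjust = "BH"`, and `enriched` then uses the adjusted values).
#'
#' @param categoryGenes Character vector of gene ids (must be a subset of
#'   `backgroundGenes`).
#' @param backgroundGenes Character vector: the annotated gene universe.
#' @param annotations Data.frame with columns `gene_id`, `term_id` and
#'   optionally `namespace` (see [readGoAnnotations()]).
#' @param alpha Significance level on the (possibly adjusted) p-value.
#' @param adjust `"none"` (raw Fisher p, the default) or `"BH"`.
#' @return A data.frame sorted by p-value with columns `term_id`,
#'   `namespace`, `kStudy`, `nStudy`, `KPop`, `NPop`, `pFisher`,
#'   (`pAdjusted`,) `enriched`.
#' @examples
#' anno <- data.frame(gene_id = c("g1", "g2", "g3"),
#'                    term_id = c("GO:1", "GO:1", "GO:2"))
#' fisherEnrichment(c("g1", "g2"), paste0("g", 1:10), anno)
#' @export
fisherEnrichment <- function(categoryGenes, backgroundGenes, annotations,
                             alpha = 0.05, adjust = c("none", "BH")) {
    adjust <- match.arg(adjust)
    categoryGenes <- unique(categoryGenes)
    backgroundGenes <- unique(backgroundGenes)
    stray <- setdiff(categoryGenes, backgroundGenes)
    if (length(stray))
        stop("category genes absent from the background: ",
             paste(head(stray, 5L), collapse = ", "),
             if (length(stray) > 5L) ", ...")
    if (length(backgroundGenes) == 0L)
        stop("'backgroundGenes' must be non-empty")
    anno <- annotations[annotations$gene_id %in% backgroundGenes, ,
                        drop = FALSE]
    anno <- anno[!duplicated(anno[c("gene_id", "term_id")]), , drop = FALSE]
    if (nrow(anno) == 0L || length(categoryGenes) == 0L)
        return(emptyEnrichment(adjust))
    N <- length(backgroundGenes)
    n <- length(categoryGenes)
    inCat <- anno$gene_id %in% categoryGenes
    kTab <- table(anno$term_id[inCat])
    if (length(kTab) == 0L) return(emptyEnrichment(adjust))
    KTab <- table(anno$term_id)[names(kTab)]
    k <- as.integer(kTab); K <- as.integer(KTab)
    p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    ns <- if ("namespace" %in% names(anno))
        vapply(names(kTab), function(t)
            anno$namespace[match(t, anno$term_id)], character(1))
    else NA_character_
    out <- data.frame(term_id = names(kTab), namespace = unname(ns),
                      kStudy = k, nStudy = n, KPop = K, NPop = N,
                      pFisher = p, stringsAsFactors = FALSE,
                      row.names = NULL)
    if (adjust == "BH") {
        out$pAdjusted <- p.adjust(out$pFisher, method = "BH")
        out$enriched <- out$pAdjusted < alpha
    } else out$enriched <- out$pFisher < alpha
    out[order(out$pFisher, out$term_id), , drop = FALSE]
}

emptyEnrichment <- function(adjust) {
    out <- data.frame(term_id = character(), namespace = character(),
                      kStudy = integer(), nStudy = integer(),
                      KPop = integer(), NPop = integer(),
                      pFisher = numeric(), stringsAsFactors = FALSE)
    if (adjust == "BH") out$pAdjusted <- numeric()
    out$enriched <- logical()
    out
}
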