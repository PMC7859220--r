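## Annotation and table readers (GFF3 / BED12 gene models, GO TSV,
## chromosome-length TSV).

#' Read gene models from GFF3 or BED12
#'
#' For GFF3, `gene` features give the spans and `CDS` features the coding
#' intervals; CDS `Parent` attributes pointing at an intermediate `mRNA`
#' level are resolved to the gene. For BED12, block structures are taken
#' as CDS intervals and the whole record as the gene span.
#'
#' @param path A GFF3 (`.gff`/`.gff3`) or BED12 (`.bed`) file.
#' @return A [GeneModels] object.
#' @examples
#' sim <- simulateASEData(SimConfig(nGenes = 10L, seed = 1L), tempfile())
#' readGeneModels(sim$paths$annotation)
#' @export
readGeneModels <- function(path) {
    fmt <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
    gr <- rtracklayer::import(path, format = fmt)
    if (fmt == "bed") {
        ids <- mcols(gr)$name
        if (is.null(ids)) stop("BED12 gene models need a name column")
        names(gr) <- ids
        cds <- rtracklayer::blocks(gr)
        return(GeneModels(granges(gr), cds))
    }
    type <- as.character(mcols(gr)$type)
    genes <- gr[type == "gene"]
    ids <- mcols(genes)$ID
    if (is.null(ids) || anyNA(ids))
        stop("GFF3 gene features must carry ID attributes")
    names(genes) <- ids
    cds <- gr[type == "CDS"]
    parent <- as.character(unlist(mcols(cds)$Parent))
    ## resolve CDS -> mRNA -> gene if an mRNA layer is present
    mrna <- gr[type %in% c("mRNA", "transcript")]
    if (length(mrna)) {
        m <- match(parent, mcols(mrna)$ID)
        up <- as.character(unlist(mcols(mrna)$Parent))[m[!is.na(m)]]
        parent[!is.na(m)] <- up
    }
    if (!all(parent %in% ids))
        stop("CDS features with Parent outside the gene set")
    cdsList <- split(granges(sort(cds)),
                     factor(parent[order(cds)], levels = ids))
    GeneModels(granges(genes), cdsList)
}

#' Read gene-to-GO-term annotations from a two-column TSV
#'
#' @param path TSV with columns `gene_id` and `term_id` (header optional;
#'   a third `namespace` column is kept when present). Duplicate
#'   (gene, term) pairs are dropped.
#' @return A data.frame with columns `gene_id`, `term_id` and (optionally)
#'   `namespace`.
#' @export
readGoAnnotations <- function(path) {
    first <- strsplit(readLines(path, n = 1L), "\t")[[1]]
    hasHeader <- identical(tolower(first[1]), "gene_id")
    df <- read.delim(path, header = hasHeader, stringsAsFactors = FALSE)
    if (!hasHeader)
        names(df)[1:2] <- c("gene_id", "term_id")
    if (ncol(df) >= 3L && !"namespace" %in% names(df))
        names(df)[3] <- "namespace"
    df[!duplicated(df[c("gene_id", "term_id")]),
       intersect(c("gene_id", "term_id", "namespace"), names(df)),
       drop = FALSE]
}

#' Read chromosome lengths from a two-column TSV
#'
#' @param path TSV with chromosome name and length (no header).
#' @return A named integer vector of lengths.
#' @export
readChromLengths <- function(path) {
    df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    setNames(as.integer(df[[2]]), df[[1]])
}
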