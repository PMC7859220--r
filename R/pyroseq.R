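## Pyrosequencing validation arithmetic: observed allele bias from allele
## frequencies, population-vs-genomic comparisons, subclone consistency.

#' Observed allelic bias from pyrosequencing allele frequencies
#'
#' \eqn{100 \times |f_1 - f_2|} for allele frequencies given as fractions
#' in \[0, 1\] (so the result lands on the same 0--100 percent scale as
#' AFB/AEB). Pyrosequencing instruments report percent-scale frequencies;
#' set `percentScale = TRUE` to divide inputs by 100 first. A warning is
#' issued when the two frequencies do not sum to 1 within `tol`
#' (instrument rounding tolerance).
#'
#' @param freqAllele1,freqAllele2 Allele frequencies (vectorized).
#' @param percentScale Inputs are percentages rather than fractions.
#' @param tol Allowed deviation of `freqAllele1 + freqAllele2` from 1.
#' @return Percent bias in \[0, 100\].
#' @examples
#' obsBias(0.925, 0.075)  # 85
#' @export
obsBias <- function(freqAllele1, freqAllele2, percentScale = FALSE,
                    tol = 0.02) {
    if (percentScale) {
        freqAllele1 <- freqAllele1 / 100
        freqAllele2 <- freqAllele2 / 100
    }
    if (any(freqAllele1 < 0 | freqAllele1 > 1 |
            freqAllele2 < 0 | freqAllele2 > 1))
        stop("allele frequencies must be in [0, 1]")
    off <- abs(freqAllele1 + freqAllele2 - 1) > tol
    if (any(off))
        warning(sum(off), " measurement(s) with frequencies summing ",
                "outside 1 +/- ", tol)
    100 * abs(freqAllele1 - freqAllele2)
}

#' Aggregate pyrosequencing measurements to one gene-level bias
#'
#' Averages technical replicates per SNV first, then averages the per-SNV
#' observed biases across the gene's SNVs — mirroring the per-gene
#' averaging of the in-silico statistic. Replicate sets whose bias
#' standard deviation exceeds `sdLimit` are flagged (warning) but still
#' averaged.
#'
#' @param measurements A data.frame for one gene and one template with
#'   columns `snv_id`, `freqAllele1`, `freqAllele2` and optionally
#'   `replicate_id`, `gene_id`, `template`.
#' @param sdLimit Flagging limit for the replicate SD (percent).
#' @param percentScale Passed to [obsBias()].
#' @return The gene-level percent bias, with the per-SNV table attached as
#'   attribute `perSnv`.
#' @export
aggregateGeneObs <- function(measurements, sdLimit = Inf,
                             percentScale = FALSE) {
    if (nrow(measurements) == 0L)
        stop("'measurements' must contain at least one row")
    if (!is.null(measurements$template) &&
        length(unique(measurements$template)) > 1L)
        stop("mixed templates (gDNA and cDNA) in one aggregation call")
    if (!is.null(measurements$gene_id) &&
        length(unique(measurements$gene_id)) > 1L)
        stop("'measurements' must describe a single gene")
    bias <- obsBias(measurements$freqAllele1, measurements$freqAllele2,
                    percentScale = percentScale)
    perSnv <- aggregate(list(bias = bias),
                        by = list(snv_id = measurements$snv_id),
                        FUN = function(x)
                            c(mean = mean(x), sd = sd(x), n = length(x)))
    perSnv <- data.frame(snv_id = perSnv$snv_id,
                         meanBias = perSnv$bias[, "mean"],
                         sdBias = perSnv$bias[, "sd"],
                         nReplicates = perSnv$bias[, "n"],
                         stringsAsFactors = FALSE)
    perSnv$flagged <- !is.na(perSnv$sdBias) & perSnv$sdBias > sdLimit
    if (any(perSnv$flagged))
        warning(sum(perSnv$flagged), " SNV(s) with replicate SD above ",
                sdLimit)
    structure(mean(perSnv$meanBias), perSnv = perSnv)
}

#' Compare two observed-bias distributions with a Student t-test
#'
#' Two-sided two-sample t-test, equal-variance by default (the classical
#' Student test); Welch via `equalVariance = FALSE`. Two groups with zero
#' variance and equal means (e.g. identical groups) return `t = 0`,
#' `p = 1`; zero variance with unequal means is a degenerate test and
#' errors.
#'
#' @param groupA,groupB Numeric vectors of percent biases, each of length
#'   >= 2.
#' @param equalVariance Pool the variances (Student) or not (Welch).
#' @return A list with `statistic`, `p.value`, `df` and `method`.
#' @examples
#' compareObsDistributions(c(10, 20, 15), c(80, 85, 90))
#' @export
compareObsDistributions <- function(groupA, groupB, equalVariance = TRUE) {
    if (length(groupA) < 2L || length(groupB) < 2L)
        stop("each group needs at least 2 values")
    if (var(groupA) == 0 && var(groupB) == 0) {
        if (mean(groupA) == mean(groupB))
            return(list(statistic = 0, p.value = 1,
                        df = length(groupA) + length(groupB) - 2L,
                        method = "Two Sample t-test (degenerate: zero variance, equal means)"))
        stop("degenerate test: zero variance in both groups with ",
             "unequal means")
    }
    tt <- t.test(groupA, groupB, var.equal = equalVariance)
    list(statistic = unname(tt$statistic), p.value = tt$p.value,
         df = unname(tt$parameter), method = tt$method)
}

#' Subclone consistency of a monoallelically expressed gene
#'
#' Summarises pyrosequencing of one gene across subclones: per clone and
#' SNV, the mean allele-1 frequency across technical replicates, their
#' standard deviation (`NA`, not 0, for a single replicate) and the
#' deviation from the population-level reference frequency. The gene is
#' flagged `consistent` when every clone's observed bias falls on the
#' same side of the MAE threshold as the population-level bias —
#' monoallelic expression that is mitotically stable stays above the
#' threshold in every subclone.
#'
#' @param measurements A data.frame for one gene (cDNA template) with
#'   columns `clone_id`, `snv_id`, `freqAllele1` and optionally
#'   `replicate_id`; at least two clones.
#' @param populationReference Population-level allele-1 frequency, percent
#'   (the red-line value the clones are compared against).
#' @param maeThreshold MAE bias threshold, percent.
#' @return A list with `perClone` (data.frame), the per-clone biases
#'   `cloneBias`, the `populationBias`, and the logical `consistent`.
#' @export
subcloneConsistency <- function(measurements, populationReference,
                                maeThreshold = 60) {
    clones <- unique(measurements$clone_id)
    if (length(clones) < 2L)
        stop("subclone consistency needs measurements from >= 2 clones")
    key <- interaction(measurements$clone_id, measurements$snv_id,
                       drop = TRUE)
    perClone <- do.call(rbind, lapply(split(measurements, key), function(d) {
        data.frame(clone_id = d$clone_id[1], snv_id = d$snv_id[1],
                   freqAllele1 = mean(d$freqAllele1),
                   sdFreq = if (nrow(d) >= 2L) sd(d$freqAllele1)
                            else NA_real_,
                   nReplicates = nrow(d),
                   deviation = mean(d$freqAllele1) * 100 -
                       populationReference,
                   stringsAsFactors = FALSE)
    }))
    row.names(perClone) <- NULL
    cloneFreq <- vapply(split(perClone$freqAllele1, perClone$clone_id),
                        mean, numeric(1))
    cloneBias <- 100 * abs(2 * cloneFreq - 1)
    populationBias <- abs(2 * populationReference / 100 - 1) * 100
    consistent <- all((cloneBias > maeThreshold) ==
                      (populationBias > maeThreshold))
    list(perClone = perClone, cloneBias = cloneBias,
         populationBias = populationBias, consistent = consistent)
}
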