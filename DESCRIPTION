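Package: aasekit
Title: Allele-Specific Expression Analysis from Allelic Read Depths
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies autosomal allele-specific expression (aASE) in
    diploid genomes from heterozygous coding single-nucleotide variants.
    Computes per-gene allele frequency bias (AFB, from genomic DNA) and
    allele expression bias (AEB, from cDNA/RNA-seq) as the mean absolute
    allelic-depth difference per variant, classifies genes into biallelic
    (BAE), allele-specific (ASE) and monoallelic (MAE) expression
    categories with copy-number guarding, validates calls with
    pyrosequencing-style observed-bias arithmetic, tests gene categories
    for GO-term over-representation with one-sided Fisher exact tests, and
    measures chromatin-mark peak overlap against a within-chromosome peak
    randomization null. Includes a seeded synthetic-data generator (VCF,
    GFF3, BED, truth tables) with known per-gene allelic fractions for
    end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
biocViews: Transcriptomics, GeneExpression, SNP, Epigenetics, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
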