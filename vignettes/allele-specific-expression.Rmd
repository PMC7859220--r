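---
title: "Quantifying allele-specific expression from allelic read depths"
author: "aasekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying allele-specific expression from allelic read depths}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages(library(aasekit))
```

## The problem and the model

In a heterozygous diploid organism the two alleles of a gene are usually
transcribed at similar levels; when they are not, the gene shows
allele-specific expression (ASE), and in the extreme monoallelic
expression (MAE). In clonal, asexually propagating organisms such as the
diatom *Phaeodactylum tricornutum* this imbalance cannot be genomic
imprinting, so detecting it genome-wide is a question of comparing the
two alleles' read support at heterozygous coding single-nucleotide
variants (SNVs) in RNA-seq (cDNA) against the same loci in genomic DNA
(gDNA).

For a single variant with reference-allele depth $AD_{ref}$,
alternate-allele depth $AD_{alt}$ and approximate total depth $RD$, the
per-SNV percent bias is

$$b = \left|\frac{AD_{ref}}{RD} - \frac{AD_{alt}}{RD}\right| \times 100 ,$$

and a gene's statistic is the arithmetic mean of $b$ over its $N$
usable heterozygous SNVs. Computed on gDNA this is the allele frequency
bias (AFB), a proxy for the copy balance of the two alleles; on cDNA it
is the allele expression bias (AEB). Genes are then classified:

* `EXCLUDED_AFB` — AFB > 20. A duplicated polymorphism at a 2:1
  genomic ratio already gives AFB > 30, so genomic bias above 20
  means apparent expression bias could be copy-number driven, and the
  gene is excluded from interpretation.
* `BAE` — AEB ≤ 20 (biallelic expression).
* `ASE` — 20 < AEB ≤ 60 (moderate allele-specific expression).
* `MAE` — AEB > 60 (near-monoallelic expression).

Boundary values resolve exactly by these printed inequalities
(`classifyGenes()`); the thresholds live in a `CategoryThresholds`
object and are tunable, with the above defaults.

Two more labels complete the partition of the annotated gene universe:
`NO_SNV` for genes without at least one usable SNV in *each* sample,
and `DISCORDANT` for genes whose multiple cDNA SNVs disagree on which
allele is overexpressed.

## Variant usability

Three filters precede quantification (`filterVariants()`):

1. **Heterozygous** — judged from the gDNA genotype call. A cDNA record
   at a locus called heterozygous in gDNA is usable even when its own
   genotype string looks homozygous: monoallelic expression removes one
   allele's reads from the cDNA, so requiring a heterozygous cDNA call
   would make MAE genes systematically un-callable. This is why
   `runASEAnalysis()` passes the gDNA call set as `hetFrom` when
   filtering cDNA variants.
2. **Coding** — the position lies inside a CDS interval of the
   annotation. Containment is position-only; strand is ignored because
   the bias statistic is strand-agnostic. VCF positions are 1-based;
   interval containment is tested on 1-based closed intervals as stored
   in `GRanges`.
3. **Depth** — $RD \geq$ 20 (gDNA) or 5 (cDNA), boundaries inclusive.
   These cutoffs correspond to the first peak of each sample's
   read-depth frequency distribution; `detectDepthThreshold()`
   operationalises that rule as the first interior local maximum (depth
   ≥ 2) of the window-3 moving-average-smoothed integer depth
   histogram, requiring the peak to carry at least `minProminence`
   (default 1%) of the variants. Tied plateaus resolve to the depth
   with the highest raw count; if no peak qualifies the caller-supplied
   default (20/5) is used. The left histogram boundary is padded with
   its own value so a monotonically decreasing histogram does not gain
   a spurious peak at depth 2.

Sites present in gDNA but absent from the cDNA call set are **not**
imputed as zero expression: absence of a call is ambiguous (no coverage
versus no variant), so such genes simply lack cDNA evidence and fall
into `NO_SNV` when nothing else remains. Multi-allelic records are
dropped rather than decomposed — the two-allele bias formula is
undefined for three alleles. The gDNA and cDNA SNV sets of a gene need
not be identical: AFB uses the SNVs passing the gDNA depth filter and
AEB those passing the cDNA filter, maximising usable genes; both counts
are reported per gene.

## Concordance

When a gene carries several cDNA SNVs they should agree on which
haplotype is overexpressed. Because reads are mapped against one
reference haplotype, the sign of $AD_{alt} - AD_{ref}$ is comparable
across a gene's SNVs. `concordanceCheck()` calls a gene concordant when
at most one sign occurs among SNVs whose per-SNV bias exceeds a
direction threshold (default 20%); weaker SNVs carry no reliable
direction and are ignored, and single-SNV genes are vacuously
concordant. The qualitative requirement ("multiple SNVs should show
concordant bias") does not prescribe an algorithm; this
sign-above-threshold rule is this package's operationalisation, and the
threshold is configurable. Discordant genes are labelled rather than
silently dropped, for auditability.

## The noise floor of the bias statistic

$b$ is the absolute value of a noisy difference, so its expectation is
positive even at a perfectly balanced locus. With
$AD_{ref} \sim \mathrm{Binomial}(RD, 1/2)$,

$$\mathbb{E}[b] = \frac{100}{RD}\,\mathbb{E}\,|2K - RD|
  \approx 100\sqrt{\frac{2}{\pi\,RD}} .$$

Exact enumeration gives $\mathbb{E}[b] = 37.5$ at $RD = 5$ and
$\approx 17.62$ at $RD = 20$ — the latter sits just below the BAE/ASE
cutoff, which is one reason the depth filters matter: shallower
variants would push truly biallelic genes over the boundary. The test
suite verifies the simulated estimator against this enumeration, and
`geneBias()`'s documentation carries the warning.

```{r noise-floor}
enum <- function(rd) sum(abs(2 * (0:rd) - rd) / rd * 100 *
                         dbinom(0:rd, rd, 0.5))
c(depth5 = enum(5), depth20 = enum(20), depth100 = enum(100))
```

## The synthetic-data generator

`simulateASEData()` writes a gDNA VCF, a cDNA VCF (same loci,
single-sample `GT:AD:DP`, genotype `0/1`, contigs declared, no
timestamps — identical seeds give byte-identical files), a GFF3
annotation of non-overlapping single-CDS genes, and a truth table. The
generative model per gene:

* an expression class — **balanced** ($p = 0.5$), **moderate**
  ($p \sim U[0.60, 0.80]$, so expected AEB spans (20, 60]) or
  **monoallelic** ($p \sim U[0.95, 1]$), where $p$ is the fraction of
  cDNA reads carrying the reference-haplotype allele (the biased side
  is randomised per gene);
* optionally a copy-number skew: the gDNA allelic ratio is drawn
  uniformly between 2:1 and 3:1 (expected AFB 33–50) and the cDNA
  fraction follows the genomic one (dosage-driven expression) — these
  genes are the targets of the AFB guard;
* a SNV count (zero-inflated Poisson) and, per SNV, allelic depths
  drawn as $\mathrm{Binomial}(RD, p)$ at depths from configurable
  samplers.

Class, zero-SNV and CNV proportions are allocated as exact rounded
counts, so stated fractions are exact by construction. The default
configuration mirrors the composition reported for *P. tricornutum*
Pt18.6 — about 40% of genes without usable SNVs, roughly a quarter
removed by the AFB guard, and classified genes split about 33/64/3
between balanced, moderate and monoallelic — with read depths peaked
near 40× (gDNA) and 15× (cDNA) with low-depth tails so the depth
filters act.

What the generator does *not* emulate: sequencing error, mapping/
reference bias, overdispersion beyond binomial sampling, linked or
overlapping genes, multi-exon structure, and allelic phase switching.
Passing tests therefore demonstrate that the inference machinery
recovers the truth *under its own statistical assumptions*, not that
those assumptions hold in any particular real data set.

### The deep benchmark and its error analysis

`benchmarkConfig()` is the parameter-recovery condition: 1,000 genes,
every gene with 3 + Poisson(5) SNVs, depths uniform on {100, …, 200}
in both samples, 5% CNV genes. The depth choice is an a-priori design
decision, not a tuning: at depth $d$ the per-SNV bias has standard
deviation $\approx 200\sqrt{p(1-p)/d}$ (≈ 7.5% at $d = 150$,
$p = 0.7$), so a gene averaging $m \approx 8$ SNVs measures its AEB
with an error of ~2.7%. Since moderate genes' expected AEB is uniform
over a 40-point interval, the expected boundary misclassification rate
is roughly $2 \times 0.4 \times \sigma_g / 40 \approx 5\%$ *of the
moderate class*, i.e. ~3% of all genes — comfortably inside the ≥95%
recovery the benchmark asserts, whereas at depths near 50 the margin
would shrink to nearly nothing. CNV genes sit ≥ 13 AFB points above
the exclusion threshold at these depths, about five standard errors,
so all of them must be excluded.

## Pyrosequencing validation arithmetic

Experimental validation reports per-SNV allele frequencies. The
observed bias is $100 \times |f_1 - f_2|$ with frequencies as
*fractions*: the printed form of this formula multiplies percentages
by 100, which would leave the 0–100 scale; interpreting inputs as
fractions lands the output on the same percent scale as AFB/AEB (an
MAE gene at 92.5%/7.5% gives 85, matching the scale of reported MAE
medians). `obsBias(percentScale = TRUE)` divides by 100 first for
instrument-style input. Technical replicates are averaged per SNV
before SNVs are averaged per gene (`aggregateGeneObs()`), mirroring
the in-silico aggregation; replicate sets with large spread are
flagged, not dropped.

Distribution comparisons use the classical equal-variance Student
t-test (`compareObsDistributions()`, Welch by option). The degenerate
case — both groups constant — returns $t = 0$, $p = 1$ when the means
agree and errors otherwise, since the test statistic is undefined.
Subclone stability (`subcloneConsistency()`) summarises per-clone
allele-1 frequencies (SD of technical replicates reported as missing,
never zero, for single replicates) and flags a gene consistent when
every clone's bias falls on the same side of the MAE threshold as the
population-level value; a quantitative consistency rule is again this
package's construction.

## Chromatin-mark overlap and its null

`overlapSignificance()` measures, per gene category, the percentage of
genes whose annotated span intersects at least one peak, after
extending peaks by ±500 bp to capture promoter and regulatory
marking — the extension applies to peaks, never to genes. The overlap
unit is the gene (hit or not hit); a bp-resolution variant
(`unit = "bp"`) is available since percentage overlap could be read
either way. The null distribution repositions each extended peak
uniformly within its chromosome (width and chromosome conserved,
overlaps between randomized peaks allowed), 100 iterations by default.
One randomization per iteration serves all categories. Empirical
p-values use the add-one estimator
$p = (1 + \#\{\text{random} \ge \text{observed}\})/(n_{iter} + 1)$, so
$p$ is never 0 and the smallest attainable value at 100 iterations is
$1/101$; enrichment and depletion tails are both reported. Because the
overlap statistic is discrete, ties make the estimator slightly
conservative; the calibration test (200 synthetic data sets, 250 genes,
80 peaks) checks that null p-values are indistinguishable from uniform
by a Kolmogorov–Smirnov test.

## GO enrichment

`fisherEnrichment()` tests each GO term annotating at least one
category gene for over-representation against the annotated background
with the one-sided Fisher exact test — computed as the hypergeometric
upper tail, which is exact for a 2×2 table. **No multiple-testing
correction is applied by default**: the classification pipeline this
package implements keeps terms at raw Fisher $p < 0.05$, and the
default reproduces that behaviour; pass `adjust = "BH"` for
Benjamini–Hochberg control. GO-graph (true-path) propagation is not
performed — annotations are used as supplied.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use: 2×10⁴ simulated SNVs
for the estimator-enumeration comparison; the 1,000-gene benchmark for
recovery; 200 synthetic data sets × 100 randomizations for null
calibration; and exhaustive enumeration of all 2×2 tables with
background size ≤ 200 (about 2×10⁸ cells) for the Fisher oracle, where
the implementation and an explicit binomial-coefficient summation agree
to < 10⁻¹². Ties at classification boundaries follow the printed
inequalities exactly; empty variant sets propagate `NA` (never 0) into
the bias columns; and all randomness flows through R's RNG so a single
seed reproduces every file and statistic.

## Known limitations

* Fixed thresholds, not per-gene statistical tests: no binomial or
  beta-binomial test of allelic imbalance is performed, so shallow
  genes near a boundary are classified by a noisy point estimate (the
  depth filters and the concordance guard are the mitigations).
* The unsigned average ignores phase: two SNVs biased toward opposite
  haplotypes average their magnitudes; the concordance check is the
  guard, not a fix.
* Real allelic data carry mapping bias toward the reference allele and
  overdispersion; neither is modelled by the generator, so real-data
  AFB/AEB distributions will be wider than simulated ones.
* The genome-wide category proportions of any particular organism are
  not a target of the synthetic defaults — they only shape realistic
  test conditions.
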