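---
title: "Discovering cancer predisposition genes from somatic second hits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering cancer predisposition genes from somatic second hits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alfredr)
```

## The model

Knudson's two-hit hypothesis holds that recessive cancer predisposition
acts through two events: an inherited damaging variant in one allele of a
gene (the first hit) and somatic loss of the remaining wild-type allele
(the second hit), typically by loss of heterozygosity (LOH). `alfredr`
turns this into a genome-wide statistical screen over paired tumor–normal
exome cohorts, without needing healthy-control sequencing for discovery.

The screen has three ingredients:

1. **Allelic imbalance (AI) as an LOH proxy.** For every gene and tumor,
   all heterozygous germline variants in the gene (extended to a 100 kb
   window for shorter genes, to decouple statistical power from gene
   length) are compared between tumor and normal reads. A variant is
   informative only if its tumor variant allele frequency (VAF) shows a
   real effect — above 0.7 or below 0.3 — and each informative variant is
   tested with a two-tailed Fisher exact test on its tumor vs normal
   alt/ref read counts. Per-variant P-values are pooled with Fisher's
   method and the gene is called AI in that sample when the pooled P is at
   most 0.05. Samples with heterozygous sites but no directional shift are
   evaluable non-AI samples; samples with no informative site are missing
   and never enter any denominator.

2. **Rare damaging germline variants (RDGVs).** A germline variant
   qualifies when its reference-database allele frequency is below 0.1%
   both globally and in every subpopulation, its consequence is
   protein-truncating (nonsense, frameshift, splice) or
   predicted-deleterious missense, it is present in and passes the QC of
   the reference database, is not a multi-nucleotide substitution, and is
   not recurrent at one position in more than 1% of cohort samples. A
   PTV-only mode drops the missense class.

3. **Two tests per gene, combined conservatively.**
   *Test 1* asks whether RDGV carriers are enriched among AI samples: the
   statistic is the carrier frequency in AI samples minus that in non-AI
   samples, and its null is generated by permuting the AI labels *within
   population strata*, yielding an add-one-smoothed empirical P-value
   $(b+1)/(N+1)$. *Test 2* asks whether AI removes the wild-type allele
   rather than the variant: a carrier sample is a putative two-hit sample
   when the RDGV's tumor VAF exceeds its normal VAF by at least 10
   percentage points, and the count of two-hit events among RDGV-carrying
   AI samples is tested one-tailed against a binomial baseline estimated
   from the RDGV-carrying non-AI samples. The gene's final P-value is the
   *less* significant of the two, so a gene must pass both to score;
   Benjamini–Hochberg FDR is applied across tested genes.

Genes enter the test only if they have at least 5 RDGV-carrier samples, at
least one carrier with a ≥10% VAF increase, and an AI frequency of at
least 10% among evaluable samples; per-cancer runs additionally require
strictly more than a per-type number of carriers in both the AI and non-AI
groups (`perCancerCarrierMinima()`), which keeps the per-type P-value
distributions uninflated at smaller sample sizes.

## Population structure

Carrier frequencies differ across ancestries, so labels are never permuted
across populations. Strata are estimated from common variants (reference
MAF ≥ 5%): the genotype dosage matrix is mean-centered (no per-variant
scaling; scaling is exposed nowhere because rare columns are already
excluded), the first 4 principal components are taken with a fixed sign
convention (largest-magnitude loading positive) for determinism, and
samples are partitioned with a trimmed k-means (default k = 10, 5%
trimmed, 20 seeded restarts). Trimmed samples (stratum 0) are excluded
from every test. Trimmed k-means stands in for heteroscedastic
ellipsoidal trimmed clustering; since the strata only serve as permutation
blocks, cluster shape details are immaterial, and k, the trim fraction and
restarts are all configurable.

Which samples feed the clustering follows the analysis's own sample
universe: the gene test clusters the tumor cohort, the case–control
burden analyses cluster cases and controls together (`runPipeline()` does
the latter whenever controls are present).

## The permutation engine

For a binary carrier indicator, a within-stratum permutation of binary
labels affects the statistic only through the number of carriers assigned
to the label-1 group in each stratum, and that count is exactly
hypergeometric with the stratum's carrier count and group size as margins.
The engine therefore samples the null with `rhyper` per stratum and sums —
mathematically identical to literally shuffling labels, at a small
fraction of the cost; `stratifiedPermutation()` performs the literal
shuffle and the test suite checks the two routes against each other, and
checks the single-stratum empirical P against the exact hypergeometric
tail. Effect sizes are reported as observed statistic minus null median,
with a 95% interval from the 2.5th/97.5th null percentiles subtracted
from the observed value.

Every randomized quantity draws its seed from the master seed and a string
key (`substreamSeed()`), one substream per gene, so results are invariant
to gene evaluation order and to how work is partitioned.

## Burden analyses and contribution to risk

The same randomization machinery runs three burden designs — cases vs
controls, one cancer type vs the rest, and the type-vs-rest comparison
restricted to AI samples — plus a leave-one-comparator-out variant of the
tissue-specificity test. Gene sets are treated as one concatenated gene
(carrier = carrier in any member). The contribution-to-risk curve adds
genes in order of their gene-test P-values and reports the cumulative
case-vs-control carrier excess per prefix; all prefixes share one
permutation stream (common random numbers), which keeps the curve smooth
and makes the one-gene prefix coincide exactly with the single-gene
burden test. The maximum over prefixes is reported together with the full
curve, because a maximum over correlated estimates is upward-biased and
should be auditable rather than silently corrected.

## The synthetic cohort generator

`simulateCohort()` produces cohorts with known truth so that every stage
is testable without any external data: population strata with
stratum-specific common-variant allele frequencies (disjoint ranges, so
PCA separates them), per-gene heterozygous window variants at normal VAF
0.5, per-carrier RDGVs at distinct positions, AI events at a baseline
rate (or an elevated rate in carriers of planted genes), and binomial
read counts at negative-binomial depths. Under AI, window variants shift
to the LOH VAF in a random direction, while a planted carrier's RDGV
rises deterministically — the wild-type allele is lost, encoding the
method's core biological assumption; incidental AI shifts the RDGV in a
random direction. Control samples carry germline genotypes (common,
window and RDGV sites) but no tumor signal. Named substreams per
component mean that zeroing the planted effects (`nullCohort()`) leaves
the common-variant block bit-identical.

Defaults were fixed once as the calibration conditions: 3 strata at
50/30/20%, 200 common variants, RDGV carrier rate 3% per gene, baseline
AI rate 12%, LOH VAF 0.85, depth mean 80 with negative-binomial size 10,
and 4 heterozygous window variants per gene. What the generator does
*not* model: linkage disequilibrium and haplotype structure (window
variants shift independently under AI rather than as a haplotype), tumor
purity and subclonality (AI is all-or-none per gene), coverage biases, and
annotation error. Passing tests on simulated cohorts therefore validate
the statistical machinery, not robustness to those real-data features.

## Numerical choices

- The two-tailed Fisher exact P sums hypergeometric probabilities of all
  tables no more probable than the observed one, counting ties within
  relative tolerance 1e-9; the suite verifies exact agreement with full
  enumeration for all tables with margins up to 15.
- Fisher's-method pooling uses only effect-filter-passing variants; with
  none passing, the pooled P is missing and the sample is non-AI (it was
  evaluable). An empty P-value set is missing evidence, never P = 1.
- Indel QC uses exact binomial goodness-of-fit tests against VAF 0.5 and
  VAF 1.0 (any reference read rejects 1.0) rather than an asymptotic
  chi-square, because the rule operates at depths near its 10-read floor;
  a call is discarded only when both genotypes are rejected at 0.05.
- In test 2, a zero or undefined binomial baseline (no RDGV-carrying
  non-AI samples, or none with a two-hit event while AI carriers have
  some) would force P = 0 for any success; instead the test returns
  missing with an audit flag and the combined P falls back to test 1.
- The empirical P floor is $1/(N+1)$; production runs use 500,000
  iterations (floor 2×10⁻⁶), the test suite and bundled examples use
  10,000 to keep runtimes in minutes.
- Short genes are extended symmetrically around their midpoint to exactly
  100 kb, clipped at position 1 without compensation on the other side.
- Sample-rank ties in the low-variant-count filter break by sample id, so
  QC is deterministic.

## Calibration behavior and known limitations

The carrier-count statistic is an integer; with realistic carrier counts
(tens of carriers per gene) its permutation null is visibly discrete, and
because the empirical P counts ties as "greater or equal", null P-values
are conservatively shifted upward. On simulated null cohorts the fraction
of genes passing any threshold stays below that threshold (the screen
does not over-discover), but the genomic-inflation lambda computed from
test-1 P-values sits well below 1 and a Kolmogorov–Smirnov uniformity
check fails in the conservative direction — deflation, not inflation.
This is an inherent property of discrete permutation P-values at these
carrier counts, and it grows milder as cohorts grow. The max-P
combination of the two tests adds a second conservative layer.

Other limitations: AI does not distinguish deletion LOH from copy-neutral
LOH or amplification; the naive relative risk `relativeRisk()` is a
descriptive ratio of conditional AI frequencies, not an adjusted risk
estimate; and the per-variant Fisher tests pooled within a gene are
treated as independent, ignoring linkage between nearby variants.

## Problem sizes used by the test suite

The bundled checks run at desk scale, chosen to finish in minutes on one
core: exact-test oracles enumerate all 2×2 tables with margins ≤ 15;
permutation oracles use 20 cohorts of ≤ 30 samples at 100,000 iterations;
null calibration uses 1,000 samples × 500 testable genes × 10,000
iterations; planted-gene recovery uses 2,000 samples × 100 genes (5
planted) across 3 seeds; burden recovery uses 20 replicates of 2,000
cases vs 2,000 controls with a planted 5-percentage-point carrier excess.

## A worked example

```{r example, eval = FALSE}
planted <- data.frame(gene_id = "gene0004", carrier_rate = 0.05,
                      ai_rate_given_carrier = 0.5, case_excess = 0.03)
cfg <- simulationConfig(nSamples = 500, nControlSamples = 250,
                        nGenes = 30, seed = 42, plantedGenes = planted)
sim <- simulateCohort(cfg)
flags <- classifyRDGV(sim$variants)
ai <- callCohortAI(sim$variants, sim$genes)
cohort <- buildCohortMatrices(sim$variants, ai, flags, sim$genes,
                              sampleMeta = sim$samples)
gm <- buildGenotypeMatrix(sim$variants, sampleIds = sim$samples$sample_id)
strata <- clusterStrata(runPCA(gm), k = 3, trimFraction = 0.02, seed = 1)
cases <- sim$samples$sample_id[sim$samples$group == "case"]
res <- alfredTest(cohort[, cases], strata, nIter = 10000, seed = 42)
head(as.data.frame(res)[order(res$p_alfred), ])
```

The same analysis runs end to end from a single YAML configuration via
`runPipeline()` or the bundled `inst/scripts/alfred-pipeline.R` script.
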