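# Allelic-imbalance (putative LOH) calling from paired tumor/normal allele
# depths of heterozygous germline variants.

#' Variant allele frequency
#'
#' @param altReads,refReads Non-negative read counts; their sum must be
#'   positive (zero-depth sites must be filtered by the caller).
#' @return \code{altReads / (altReads + refReads)}, vectorized.
#' @export
#' @examples
#' computeVaf(30, 70)  # 0.3
computeVaf <- function(altReads, refReads) {
  tot <- altReads + refReads
  if (any(tot <= 0)) stop("zero total depth; filter such sites first",
                          call. = FALSE)
  if (any(altReads < 0 | refReads < 0)) stop("negative read counts")
  altReads / tot
}

#' Two-tailed Fisher exact test on paired tumor/normal allele depths
#'
#' Tests whether the alt/ref read-count split differs between tumor and
#' normal for one variant. The two-tailed P is the sum of hypergeometric
#' probabilities of all tables with the observed margins whose probability
#' does not exceed that of the observed table (ties included within
#' relative tolerance 1e-9). Vectorized over variants.
#'
#' @param tumorAlt,tumorRef,normalAlt,normalRef Read counts; both the tumor
#'   and the normal row totals must be positive.
#' @return Numeric vector of two-tailed P-values.
#' @export
#' @examples
#' variantFisherTest(90, 10, 50, 50)
variantFisherTest <- function(tumorAlt, tumorRef, normalAlt, normalRef) {
  n <- length(tumorAlt)
  stopifnot(length(tumorRef) == n, length(normalAlt) == n,
            length(normalRef) == n)
  if (any(c(tumorAlt, tumorRef, normalAlt, normalRef) < 0)) {
    stop("negative counts", call. = FALSE)
  }
  if (any(tumorAlt + tumorRef <= 0) || any(normalAlt + normalRef <= 0)) {
    stop("both row totals must be positive", call. = FALSE)
  }
  p <- numeric(n)
  for (i in seq_len(n)) {
    p[i] <- .fisher2x2(tumorAlt[i], tumorRef[i], normalAlt[i], normalRef[i])
  }
  p
}

# exact two-tailed P for one 2x2 table; rows (tumor, normal), cols (alt, ref)
.fisher2x2 <- function(a, b, c, d) {
  N <- a + b + c + d
  row1 <- a + b
  col1 <- a + c
  lo <- max(0L, col1 - (N - row1))
  hi <- min(row1, col1)
  if (lo == hi) return(1)
  dens <- stats::dhyper(lo:hi, col1, N - col1, row1)
  dobs <- dens[a - lo + 1L]
  min(1, sum(dens[dens <= dobs * (1 + 1e-9)]))
}

#' Collect the heterozygous variants informing AI for one gene
#'
#' Genes at least \code{minSpan} long contribute only their in-gene
#' variants; shorter genes are extended symmetrically around their midpoint
#' so the examined region spans exactly \code{minSpan} (clipped at position
#' 1 at the chromosome start, without compensation). Only variants with a
#' heterozygous normal genotype are returned; homozygous germline variants
#' carry no allelic-imbalance information.
#'
#' @param gene A length-1 \code{GRanges} (or list with \code{chrom},
#'   \code{start}, \code{end}).
#' @param variants Variant observation data.frame.
#' @param minSpan Minimum genomic span represented by the variants
#'   (default 100 kb).
#' @return The subset of \code{variants} in the gene's AI window.
#' @export
collectGeneVariants <- function(gene, variants, minSpan = 1e5) {
  if (is(gene, "GRanges")) {
    stopifnot(length(gene) == 1L)
    chrom <- as.character(GenomicRanges::seqnames(gene))
    gs <- GenomicRanges::start(gene); ge <- GenomicRanges::end(gene)
  } else {
    chrom <- gene$chrom; gs <- gene$start; ge <- gene$end
  }
  w <- .aiWindow(gs, ge, minSpan)
  keep <- variants$chrom == chrom & variants$pos >= w[1L] &
    variants$pos <= w[2L] & variants$normal_genotype == "het"
  variants[keep, , drop = FALSE]
}

# window [start, end] for AI collection; symmetric extension to minSpan
.aiWindow <- function(gs, ge, minSpan = 1e5) {
  len <- ge - gs + 1
  if (len >= minSpan) return(c(gs, ge))
  mid <- (gs + ge) / 2
  lo <- max(1, floor(mid - minSpan / 2))
  hi <- floor(mid + minSpan / 2)
  c(lo, hi)
}

#' Pool per-variant P-values with Fisher's method
#'
#' Returns \eqn{P(\chi^2_{2k} \ge -2 \sum \log p_i)}. An empty input
#' signals absence of evidence and yields NA rather than P = 1.
#'
#' @param pvalues Numeric vector of P-values in (0, 1].
#' @return Pooled P-value, or NA for empty input.
#' @export
#' @examples
#' combineFisher(c(0.1, 0.1))
combineFisher <- function(pvalues) {
  pvalues <- pvalues[!is.na(pvalues)]
  if (length(pvalues) == 0L) return(NA_real_)
  .assertProb(pvalues, "pvalues", openLeft = TRUE)
  stat <- -2 * sum(log(pvalues))
  stats::pchisq(stat, df = 2 * length(pvalues), lower.tail = FALSE)
}

#' Call allelic imbalance for one gene in one sample
#'
#' Applies the tumor-VAF effect filter (VAF above \code{highVaf} or below
#' \code{lowVaf}) to each informative variant, tests the passing variants
#' with the two-tailed Fisher exact test, pools their P-values with
#' Fisher's method, and calls AI when the pooled P is at most \code{alpha}.
#' Samples with informative variants but no variant passing the effect
#' filter are "no_AI" (they were evaluable, with no directional shift);
#' only samples with zero informative variants are "missing".
#'
#' @param geneVariants Variants for one gene window in one sample, as
#'   returned by [collectGeneVariants()] (zero-depth sites are dropped).
#' @param highVaf,lowVaf Tumor-VAF effect-size thresholds (defaults 0.7 and
#'   0.3, strict inequalities).
#' @param alpha Pooled-P call threshold (default 0.05).
#' @return A one-row data.frame: \code{n_variants_used}, \code{pooled_p},
#'   \code{ai_flag} in \{AI, no_AI, missing\}, plus the per-variant
#'   evidence in attribute \code{"evidence"}.
#' @export
callAI <- function(geneVariants, highVaf = 0.7, lowVaf = 0.3, alpha = 0.05) {
  v <- geneVariants
  tot_t <- v$tumor_alt_reads + v$tumor_ref_reads
  tot_n <- v$normal_alt_reads + v$normal_ref_reads
  v <- v[tot_t > 0 & tot_n > 0, , drop = FALSE]
  n <- nrow(v)
  if (n == 0L) {
    out <- data.frame(n_variants_used = 0L, pooled_p = NA_real_,
                      ai_flag = "missing", stringsAsFactors = FALSE)
    attr(out, "evidence") <- data.frame()
    return(out)
  }
  vafT <- computeVaf(v$tumor_alt_reads, v$tumor_ref_reads)
  vafN <- computeVaf(v$normal_alt_reads, v$normal_ref_reads)
  pass <- vafT > highVaf | vafT < lowVaf
  fp <- rep(NA_real_, n)
  if (any(pass)) {
    fp[pass] <- variantFisherTest(v$tumor_alt_reads[pass],
                                  v$tumor_ref_reads[pass],
                                  v$normal_alt_reads[pass],
                                  v$normal_ref_reads[pass])
  }
  pooled <- combineFisher(fp[pass])
  flag <- if (is.na(pooled)) "no_AI" else if (pooled <= alpha) "AI" else "no_AI"
  out <- data.frame(n_variants_used = n, pooled_p = pooled, ai_flag = flag,
                    stringsAsFactors = FALSE)
  attr(out, "evidence") <- data.frame(
    variant_id = v$variant_id, vaf_normal = vafN, vaf_tumor = vafT,
    passes_effect_filter = pass, fisher_p = fp, stringsAsFactors = FALSE)
  out
}

#' Call allelic imbalance for every gene x sample in a cohort
#'
#' Vectorized cohort-wide driver for [callAI()]: assigns heterozygous
#' variants to gene AI windows by overlap, applies the effect filter, runs
#' the per-variant Fisher tests and pools per (gene, sample). Gene-sample
#' pairs with no informative variant are absent from the output (they
#' become NA in [buildCohortMatrices()]).
#'
#' @param variants Variant observation data.frame for the whole cohort.
#' @param genes \code{GRanges} of gene bodies, named by gene id.
#' @param highVaf,lowVaf,alpha As in [callAI()].
#' @param minSpan Minimum AI window span (default 100 kb).
#' @return data.frame with columns \code{sample_id}, \code{gene_id},
#'   \code{n_variants_used}, \code{pooled_p}, \code{ai_flag}.
#' @export
callCohortAI <- function(variants, genes, highVaf = 0.7, lowVaf = 0.3,
                         alpha = 0.05, minSpan = 1e5) {
  stopifnot(!is.null(names(genes)))
  v <- variants[variants$normal_genotype == "het", , drop = FALSE]
  v <- v[(v$tumor_alt_reads + v$tumor_ref_reads) > 0 &
           (v$normal_alt_reads + v$normal_ref_reads) > 0, , drop = FALSE]
  if (nrow(v) == 0L) {
    return(data.frame(sample_id = character(0), gene_id = character(0),
                      n_variants_used = integer(0), pooled_p = numeric(0),
                      ai_flag = character(0), stringsAsFactors = FALSE))
  }
  win <- t(mapply(.aiWindow, GenomicRanges::start(genes),
                  GenomicRanges::end(genes), MoreArgs = list(minSpan = minSpan)))
  wgr <- GenomicRanges::GRanges(GenomicRanges::seqnames(genes),
                                IRanges::IRanges(win[, 1L], win[, 2L]))
  names(wgr) <- names(genes)
  vgr <- GenomicRanges::GRanges(v$chrom, IRanges::IRanges(v$pos, width = 1L))
  hits <- GenomicRanges::findOverlaps(vgr, wgr, ignore.strand = TRUE)
  if (length(hits) == 0L) {
    return(data.frame(sample_id = character(0), gene_id = character(0),
                      n_variants_used = integer(0), pooled_p = numeric(0),
                      ai_flag = character(0), stringsAsFactors = FALSE))
  }
  qi <- S4Vectors::queryHits(hits)
  dt <- data.table::data.table(
    sample_id = v$sample_id[qi],
    gene_id = names(wgr)[S4Vectors::subjectHits(hits)],
    ta = v$tumor_alt_reads[qi], tr = v$tumor_ref_reads[qi],
    na_ = v$normal_alt_reads[qi], nr = v$normal_ref_reads[qi])
  dt[, vafT := ta / (ta + tr)]
  dt[, pass := vafT > highVaf | vafT < lowVaf]
  dt[, fp := NA_real_]
  if (any(dt$pass)) {
    dt[pass == TRUE, fp := variantFisherTest(ta, tr, na_, nr)]
  }
  lgl <- NULL # appease R CMD check for data.table NSE symbols
  res <- dt[, {
    pooled <- combineFisher(fp[pass])
    list(n_variants_used = .N,
         pooled_p = pooled,
         ai_flag = if (is.na(pooled)) "no_AI"
                   else if (pooled <= alpha) "AI" else "no_AI")
  }, by = c("sample_id", "gene_id")]
  as.data.frame(res)
}

#' Quality control for germline indel calls
#'
#' An indel is kept only when its normal-sample depth is at least
#' \code{minDepth} reads and its normal allele fraction is consistent with
#' either a heterozygous (50\%) or a homozygous (100\%) genotype: it is
#' discarded when an exact binomial goodness-of-fit test rejects both at
#' level \code{alpha}. The exact test (rather than an asymptotic
#' chi-square) keeps the rule meaningful at depths near 10; against VAF =
#' 1.0 any reference read is rejecting.
#'
#' @param normalAlt,normalRef Normal-sample read counts (vectorized).
#' @param minDepth Minimum normal depth (default 10).
#' @param alpha Rejection level (default 0.05).
#' @return Logical vector: keep the indel?
#' @export
indelQC <- function(normalAlt, normalRef, minDepth = 10, alpha = 0.05) {
  stopifnot(all(normalAlt >= 0), all(normalRef >= 0))
  n <- normalAlt + normalRef
  k <- pmin(normalAlt, normalRef)
  pHet <- ifelse(2 * normalAlt == n, 1, pmin(1, 2 * stats::pbinom(k, n, 0.5)))
  pHom <- ifelse(normalRef == 0, 1, 0)
  n >= minDepth & (pHet >= alpha | pHom >= alpha)
}

#' Null distribution of tumor-minus-normal VAF differences by shuffling
#'
#' For each shuffle, the tumor and normal VAF labels of every pair are
#' swapped independently with probability one half, emulating the null of
#' no systematic tumor/normal difference; the resulting distribution of
#' tumor-minus-normal differences calibrates the VAF-increase cutoff of the
#' direction test.
#'
#' @param vafNormal,vafTumor Paired VAF vectors.
#' @param nShuffles Number of shuffles (default 1e4).
#' @param seed Integer seed.
#' @return Numeric vector of length \code{nShuffles * length(vafNormal)}
#'   of shuffled tumor-minus-normal differences.
#' @export
vafShuffleNull <- function(vafNormal, vafTumor, nShuffles = 1e4, seed = 1L) {
  stopifnot(length(vafNormal) == length(vafTumor), nShuffles >= 1)
  n <- length(vafNormal)
  set.seed(substreamSeed(seed, "vaf_shuffle"))
  swap <- matrix(stats::runif(nShuffles * n) < 0.5, nShuffles, n)
  d <- vafTumor - vafNormal
  out <- matrix(rep(d, each = nShuffles), nShuffles, n)
  out[swap] <- -out[swap]
  as.numeric(out)
}
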