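# Fixture builders used across test files. Everything is generated in
# code; no data files.

# One variant observation with sensible defaults, overridable per field.
makeVariant <- function(sample_id = "S1", chrom = "chr1", pos = 100L,
                        ref = "A", alt = "G",
                        functional_class = "missense",
                        normal_ref = 50L, normal_alt = 50L,
                        tumor_ref = 50L, tumor_alt = 50L,
                        normal_genotype = "het",
                        maf_global = 1e-4, maf_subpop = 1e-4,
                        deleterious_call = "deleterious",
                        in_reference_db = TRUE, passes_db_qc = TRUE,
                        is_multinucleotide = FALSE) {
  df <- data.frame(
    sample_id = sample_id,
    variant_id = sprintf("%s:%d:%s:%s", chrom, pos, ref, alt),
    chrom = chrom, pos = as.integer(pos), ref_allele = ref,
    alt_allele = alt, functional_class = functional_class,
    normal_ref_reads = as.integer(normal_ref),
    normal_alt_reads = as.integer(normal_alt),
    tumor_ref_reads = as.integer(tumor_ref),
    tumor_alt_reads = as.integer(tumor_alt),
    normal_genotype = normal_genotype, maf_global = maf_global,
    deleterious_call = deleterious_call,
    in_reference_db = in_reference_db, passes_db_qc = passes_db_qc,
    is_multinucleotide = is_multinucleotide,
    stringsAsFactors = FALSE)
  for (s in c("afr", "amr", "eas", "fin", "nfe", "sas")) {
    df[[paste0("maf_", s)]] <- maf_subpop
  }
  df[, alfredr:::.VARIANT_COLUMNS]
}

makeVariants <- function(...) do.call(rbind, list(...))

# Build a TwoHitCohort directly from indicator matrices (genes x samples).
makeCohort <- function(carrier, ai, twohit = NULL, meta = NULL) {
  nG <- nrow(carrier); nS <- ncol(carrier)
  if (is.null(rownames(carrier))) {
    rownames(carrier) <- sprintf("g%03d", seq_len(nG))
  }
  if (is.null(colnames(carrier))) {
    colnames(carrier) <- sprintf("s%03d", seq_len(nS))
  }
  dimnames(ai) <- dimnames(carrier)
  if (is.null(twohit)) {
    twohit <- carrier & !is.na(ai) & ai == 1L
  }
  dimnames(twohit) <- dimnames(carrier)
  genes <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(seq_len(nG) * 1000L, width = 100L))
  names(genes) <- rownames(carrier)
  cd <- if (!is.null(meta)) {
    S4Vectors::DataFrame(meta, row.names = colnames(carrier))
  } else {
    S4Vectors::DataFrame(sample_id = colnames(carrier),
                         row.names = colnames(carrier))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(rdgvCarrier = carrier, aiStatus = ai,
                  twoHitEvent = twohit),
    rowRanges = genes, colData = cd)
  methods::new("TwoHitCohort", se)
}

# Independent brute-force two-tailed Fisher oracle: enumerate every table
# with the observed margins and sum the probabilities (from factorials) of
# tables no more probable than the observed one.
fisherOracle <- function(a, b, c, d) {
  N <- a + b + c + d
  row1 <- a + b
  col1 <- a + c
  tabProb <- function(x) {
    # P(table with top-left x) by the factorial formula
    exp(lfactorial(row1) + lfactorial(N - row1) + lfactorial(col1) +
          lfactorial(N - col1) - lfactorial(N) - lfactorial(x) -
          lfactorial(row1 - x) - lfactorial(col1 - x) -
          lfactorial(N - row1 - col1 + x))
  }
  xs <- max(0, col1 - (N - row1)):min(row1, col1)
  probs <- vapply(xs, tabProb, numeric(1))
  pObs <- probs[xs == a]
  sum(probs[probs <= pObs * (1 + 1e-9)])
}

# Exact one-sided hypergeometric tail P(X >= k) for the single-stratum
# permutation null: carriers K among N samples, m samples labeled 1.
hyperTail <- function(k, N, K, m) {
  min(1, sum(stats::dhyper(k:min(K, m), K, N - K, m)))
}
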