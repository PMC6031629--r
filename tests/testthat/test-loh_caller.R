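test_that("VAF is alt over total and zero depth is an error", {
  expect_equal(computeVaf(30, 70), 0.3)
  expect_equal(computeVaf(0, 50), 0)
  expect_equal(computeVaf(50, 0), 1)
  expect_equal(computeVaf(c(1, 3), c(1, 1)), c(0.5, 0.75))
  expect_error(computeVaf(0, 0), "zero total depth")
})

test_that("Fisher exact test matches the enumeration oracle on all small tables", {
  # every 2x2 table with row sums <= 8 and positive rows
  for (r1 in 1:8) for (r2 in 1:8) for (a in 0:r1) for (c in 0:r2) {
    p <- variantFisherTest(a, r1 - a, c, r2 - c)
    expect_equal(p, fisherOracle(a, r1 - a, c, r2 - c), tolerance = 1e-12,
                 label = sprintf("table (%d,%d,%d,%d)", a, r1 - a, c, r2 - c))
  }
})

test_that("Fisher exact test agrees with stats::fisher.test away from ties", {
  set.seed(42)
  for (i in 1:50) {
    x <- rpois(4, 20) + 1L
    ours <- variantFisherTest(x[1], x[2], x[3], x[4])
    ref <- stats::fisher.test(matrix(x, 2, byrow = TRUE))$p.value
    expect_equal(ours, ref, tolerance = 1e-6)
  }
})

test_that("Fisher test handles the documented edge cases", {
  expect_equal(variantFisherTest(5, 5, 5, 5), 1)
  expect_equal(variantFisherTest(0, 100, 0, 100), 1)
  expect_equal(variantFisherTest(10, 0, 5, 5), fisherOracle(10, 0, 5, 5))
  expect_lt(abs(variantFisherTest(10, 0, 5, 5) - 0.0325), 3e-4)
  # symmetric under simultaneous row and column swap
  expect_equal(variantFisherTest(7, 3, 2, 9),
               variantFisherTest(9, 2, 3, 7))
  expect_error(variantFisherTest(-1, 5, 5, 5), "negative")
  expect_error(variantFisherTest(0, 0, 5, 5), "positive")
})

test_that("Fisher's method pooling follows the closed form and is monotone", {
  expect_equal(combineFisher(c(1, 1)), 1)
  expect_equal(combineFisher(0.05), 0.05)
  x <- -2 * (log(0.1) + log(0.1))
  expect_equal(combineFisher(c(0.1, 0.1)), exp(-x / 2) * (1 + x / 2),
               tolerance = 1e-12)
  expect_lt(abs(combineFisher(c(0.1, 0.1)) - 0.05605), 5e-5)
  expect_true(is.na(combineFisher(numeric(0))))
  expect_error(combineFisher(c(0.5, 0)), "0,1")
  # decreasing any component never increases the pooled value
  set.seed(7)
  for (i in 1:20) {
    p <- runif(5)
    j <- sample(5, 1)
    q <- p; q[j] <- p[j] / 2
    expect_lte(combineFisher(q), combineFisher(p))
  }
})

test_that("gene windows extend short genes symmetrically to the span", {
  long <- list(chrom = "chr1", start = 1e6, end = 1e6 + 150000 - 1)
  v <- makeVariants(
    makeVariant(pos = 999000L),            # upstream of the long gene
    makeVariant(pos = 1050000L),           # inside
    makeVariant(pos = 1200000L))           # downstream
  got <- collectGeneVariants(long, v)
  expect_equal(got$pos, 1050000L)          # long gene: in-gene only
  # 40 kb gene centered at 1,000,000 -> window [950000, 1050000]
  short <- list(chrom = "chr1", start = 980001, end = 1020000)
  expect_equal(alfredr:::.aiWindow(short$start, short$end),
               c(950000, 1050000), tolerance = 1)
  v2 <- makeVariants(
    makeVariant(pos = 950100L), makeVariant(pos = 1049000L),
    makeVariant(pos = 949000L),
    makeVariant(pos = 960000L, normal_genotype = "hom_alt"))
  got2 <- collectGeneVariants(short, v2)
  # homozygous variants excluded; out-of-window excluded
  expect_setequal(got2$pos, c(950100L, 1049000L))
  # no heterozygous variants in window -> empty
  expect_equal(nrow(collectGeneVariants(short, v2[3:4, ])), 0L)
})

test_that("AI calls follow the effect filter and pooled-P rule", {
  # five balanced variants at depth 100: nothing passes the filter
  v <- do.call(rbind, lapply(1:5, function(i) {
    makeVariant(pos = 100L + i, tumor_ref = 50L, tumor_alt = 50L)
  }))
  got <- callAI(v)
  expect_equal(got$ai_flag, "no_AI")
  expect_true(is.na(got$pooled_p))
  expect_equal(got$n_variants_used, 5L)
  # three strongly shifted variants: every Fisher P tiny, pooled -> AI
  v2 <- do.call(rbind, lapply(1:3, function(i) {
    makeVariant(pos = 200L + i, tumor_ref = 10L, tumor_alt = 90L)
  }))
  got2 <- callAI(v2)
  expect_equal(got2$ai_flag, "AI")
  expect_lt(got2$pooled_p, 1e-8)
  ev <- attr(got2, "evidence")
  expect_true(all(ev$passes_effect_filter))
  expect_true(all(ev$fisher_p < 1e-7))
  # VAF 0.65 fails the effect filter regardless of depth
  v3 <- makeVariant(tumor_ref = 350L, tumor_alt = 650L)
  expect_equal(callAI(v3)$ai_flag, "no_AI")
  # no informative variants at all -> missing
  expect_equal(callAI(v3[0, ])$ai_flag, "missing")
})

test_that("cohort AI caller agrees with the per-gene caller", {
  sim <- simulateCohort(simulationConfig(nSamples = 40, nGenes = 6,
                                         seed = 5))
  cases <- sim$samples$sample_id[sim$samples$group == "case"]
  calls <- callCohortAI(sim$variants, sim$genes)
  # spot-check five (gene, sample) pairs against callAI()
  set.seed(2)
  for (i in sample(nrow(calls), 5)) {
    g <- calls$gene_id[i]; s <- calls$sample_id[i]
    gv <- collectGeneVariants(sim$genes[g],
                              sim$variants[sim$variants$sample_id == s, ])
    single <- callAI(gv)
    expect_equal(calls$ai_flag[i], single$ai_flag)
    expect_equal(calls$pooled_p[i], single$pooled_p, tolerance = 1e-12)
    expect_equal(calls$n_variants_used[i], single$n_variants_used)
  }
})

test_that("indel QC keeps only genotype-consistent calls at adequate depth", {
  expect_false(indelQC(4, 4))            # depth 8 < 10
  expect_true(indelQC(10, 10))           # consistent with het
  expect_true(indelQC(20, 0))            # consistent with hom (VAF 1)
  expect_false(indelQC(3, 17))           # rejects both 0.5 and 1.0
  # exact binomial oracle for the het side at depth 20
  pHet <- 2 * pbinom(3, 20, 0.5)
  expect_lt(pHet, 0.05)
  expect_equal(indelQC(c(4, 10, 3), c(4, 10, 17)), c(FALSE, TRUE, FALSE))
})

test_that("VAF shuffle null is symmetric and reproducible", {
  expect_true(all(vafShuffleNull(c(0.5, 0.4), c(0.5, 0.4), 100, seed = 1) == 0))
  a <- vafShuffleNull(c(0.5, 0.3), c(0.9, 0.6), 500, seed = 9)
  b <- vafShuffleNull(c(0.5, 0.3), c(0.9, 0.6), 500, seed = 9)
  expect_identical(a, b)
  d <- vafShuffleNull(0.5, 0.9, 20000, seed = 3)
  expect_setequal(unique(round(d, 10)), round(c(0.4, -0.4), 10))
  expect_lt(abs(mean(d > 0) - 0.5), 0.02)  # binomial SE ~ 0.0035
})
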