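test_that("gene inclusion applies carrier, two-hit and AI-frequency thresholds", {
  nS <- 60
  ai <- matrix(0L, 4, nS)
  ai[, 1:12] <- 1L                        # 20% AI frequency for all genes
  carrier <- matrix(FALSE, 4, nS)
  carrier[1, 1:5] <- TRUE                 # enough carriers
  carrier[2, 1:4] <- TRUE                 # only 4 carriers -> excluded
  carrier[3, 1:5] <- TRUE                 # carriers but no two-hit event
  carrier[4, 1:5] <- TRUE
  twohit <- carrier
  twohit[3, ] <- FALSE                    # no VAF-increase carrier
  ch <- makeCohort(carrier, ai, twohit)
  ai2 <- ai; ai2[4, ] <- 0L; ai2[4, 1:5] <- 1L  # ~8% AI -> excluded
  ch2 <- makeCohort(carrier, ai2, twohit)
  expect_setequal(selectTestableGenes(ch), c("g001", "g004"))
  expect_setequal(selectTestableGenes(ch2), "g001")
  # per-cancer mode: strictly more than the type minimum in each group
  expect_equal(selectTestableGenes(ch, cancerType = "THCA"), character(0))
})

test_that("test 1 empirical P matches the exact tail in a single stratum", {
  # 20 samples, 10 AI, 5 carriers all in the AI group
  carrier <- c(rep(TRUE, 5), rep(FALSE, 15))
  ai <- c(rep(1L, 10), rep(0L, 10))
  exact <- 252 / 15504                    # C(10,5)/C(20,5)
  r <- test1Enrichment(carrier, ai, rep(1L, 20), nIter = 100000, seed = 3)
  mcse <- sqrt(exact * (1 - exact) / 100000)
  expect_lt(abs(empiricalP(r) - exact), 3 * mcse + 1e-5)
  expect_equal(r@observed, 0.5)
})

test_that("test 1 handles degenerate labels per the error contract", {
  carrier <- rep(TRUE, 10)
  # all carriers: observed difference 0, P near 1
  r <- test1Enrichment(carrier, rep(c(1L, 0L), 5), rep(1L, 10),
                       nIter = 2000, seed = 1)
  expect_equal(r@observed, 0)
  expect_gt(empiricalP(r), 0.5)
  # empty label group: gene skipped
  expect_null(test1Enrichment(carrier, rep(1L, 10), rep(1L, 10), 100, 1))
  # a null gene's effect size is contained in its own CI
  set.seed(5)
  carrier2 <- rbinom(200, 1, 0.2) == 1
  ai2 <- rbinom(200, 1, 0.3)
  r2 <- test1Enrichment(carrier2, ai2, rep(1L, 200), nIter = 5000, seed = 2)
  expect_true(r2@ciLow <= r2@effectSize && r2@effectSize <= r2@ciHigh)
})

test_that("test 2 binomial tails match closed forms and degenerate rules", {
  # k = 0 -> P = 1
  carrier <- rep(TRUE, 20)
  ai <- rep(c(1L, 0L), 10)
  twohit <- rep(FALSE, 20)
  expect_equal(test2Direction(carrier, ai, twohit)$p, 1)
  # n = 10, k = 10, p0 = 0.5 -> 2^-10
  carrier <- rep(TRUE, 30)
  ai <- c(rep(1L, 10), rep(0L, 20))
  twohit <- c(rep(TRUE, 10), rep(TRUE, 10), rep(FALSE, 10))
  t2 <- test2Direction(carrier, ai, twohit)
  expect_equal(t2$p0, 0.5)
  expect_equal(t2$p, 2^-10, tolerance = 1e-12)
  # p0 = 0 with k >= 1: missing with a flag, not P = 0
  twohit0 <- c(rep(TRUE, 5), rep(FALSE, 25))
  t20 <- test2Direction(carrier, ai, twohit0)
  expect_true(is.na(t20$p))
  expect_equal(t20$flag, "degenerate_baseline")
  # no RDGV-carrying no-AI samples: baseline undefined
  t2n <- test2Direction(rep(c(TRUE, FALSE), 10), rep(1L, 20), rep(FALSE, 20))
  expect_equal(t2n$flag, "no_baseline_carriers")
})

test_that("max-P combination and BH FDR follow their definitions", {
  expect_equal(combineAlfred(1e-6, 0.04), 0.04)
  expect_equal(combineAlfred(0.5, 0.5), 0.5)
  fb <- combineAlfred(0.01, NA)
  expect_equal(as.numeric(fb), 0.01)
  expect_true(attr(fb, "fallback"))
  expect_equal(bhFDR(0.03), 0.03)
  expect_equal(bhFDR(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bhFDR(rep(1, 4)), rep(1, 4))
})

test_that("naive relative risk is the ratio of conditional AI frequencies", {
  # 42.2% of carriers vs 16.0% of non-carriers
  expect_equal(relativeRisk(422, 1000, 160, 1000), 2.6375)
  expect_equal(relativeRisk(5, 10, 50, 100), 1)
  expect_equal(relativeRisk(0, 10, 5, 100), 0)
  expect_true(is.na(relativeRisk(1, 0, 5, 100)))
})

test_that("the combined gene P is never smaller than either test", {
  sim <- simulateCohort(simulationConfig(
    nSamples = 250, nGenes = 15, seed = 41,
    plantedGenes = data.frame(gene_id = "gene0003", carrier_rate = 0.06,
                              ai_rate_given_carrier = 0.6, case_excess = 0)))
  flags <- classifyRDGV(sim$variants)
  ai <- callCohortAI(sim$variants, sim$genes)
  ch <- buildCohortMatrices(sim$variants, ai, flags, sim$genes,
                            sampleMeta = sim$samples)
  res <- alfredTest(ch, rep(1L, ncol(ch)), nIter = 2000, seed = 6)
  ok <- !is.na(res$p_alfred)
  expect_true(all(res$p_alfred[ok] >= res$p_test1[ok]))
  both <- ok & !is.na(res$p_test2)
  expect_true(all(res$p_alfred[both] >= res$p_test2[both]))
  # the planted gene is recovered at the top
  expect_equal(res$gene_id[which.min(res$p_alfred)], "gene0003")
})

test_that("gene test results are invariant to gene evaluation order", {
  carrier <- matrix(rbinom(8 * 120, 1, 0.15) == 1, 8, 120)
  ai <- matrix(rbinom(8 * 120, 1, 0.3), 8, 120)
  ch <- makeCohort(carrier, ai)
  st <- rep(1:2, 60)
  g <- selectTestableGenes(ch, geneInclusionRule(minRdgvCarriers = 1,
                                                 minVafIncCarriers = 0,
                                                 minAiFrequency = 0))
  r1 <- alfredTest(ch, st, nIter = 2000, seed = 11, genes = g)
  r2 <- alfredTest(ch, st, nIter = 2000, seed = 11, genes = rev(g))
  d1 <- as.data.frame(r1); d2 <- as.data.frame(r2)
  d2 <- d2[match(d1$gene_id, d2$gene_id), ]
  expect_equal(d1$p_test1, d2$p_test1)
  expect_equal(d1$effect_size, d2$effect_size)
  # fdr differs only through the set, which is identical
  expect_equal(sort(d1$fdr_q), sort(d2$fdr_q))
})

test_that("a singleton gene-set test reduces to test 1 on that gene", {
  carrier <- matrix(rbinom(5 * 100, 1, 0.2) == 1, 5, 100)
  ai <- matrix(rbinom(5 * 100, 1, 0.3), 5, 100)
  ch <- makeCohort(carrier, ai)
  st <- rep(1:2, 50)
  r1 <- geneSetTest(ch, "g002", st, nIter = 3000, seed = 13)
  r2 <- test1Enrichment(rdgvCarrier(ch)["g002", ], aiStatus(ch)["g002", ],
                        st, nIter = 3000, seed = 13)
  expect_equal(empiricalP(r1), empiricalP(r2))
  expect_equal(effectSize(r1), effectSize(r2))
  # a set of mutually exclusive null genes has effect near zero
  carrier2 <- matrix(FALSE, 4, 400)
  for (i in 1:4) carrier2[i, ((i - 1) * 100 + 1):(i * 100)] <-
      rbinom(100, 1, 0.2) == 1
  ai2 <- matrix(rbinom(4 * 400, 1, 0.3), 4, 400)
  ch2 <- makeCohort(carrier2, ai2)
  rs <- geneSetTest(ch2, rownames(ch2), rep(1L, 400), 3000, seed = 4)
  expect_lt(abs(effectSize(rs)), 0.1)
})

test_that("per-cancer runs subset correctly and skip small types", {
  set.seed(19)
  nS <- 160
  carrier <- matrix(rbinom(6 * nS, 1, 0.2) == 1, 6, nS)
  ai <- matrix(rbinom(6 * nS, 1, 0.3), 6, nS)
  meta <- data.frame(sample_id = sprintf("s%03d", 1:nS), group = "case",
                     cancer_type = rep(c("AA", "BB"), c(120, 40)),
                     stringsAsFactors = FALSE)
  ch <- makeCohort(carrier, ai, meta = meta)
  st <- rep(1L, nS)
  rule <- geneInclusionRule(minRdgvCarriers = 1, minVafIncCarriers = 0,
                            minAiFrequency = 0,
                            perCancerMinCarriers = c(AA = 0, BB = 0),
                            perCancerDefault = 0)
  out <- runPerCancer(ch, st, rule, nIter = 1000, seed = 2,
                      minSamples = 100)
  expect_equal(out$skipped, "BB")
  expect_true("AA" %in% names(out$perType))
  # a single-type cohort equals the pan-cancer run with the same seeds
  meta1 <- meta; meta1$cancer_type <- "AA"
  ch1 <- makeCohort(carrier, ai, meta = meta1)
  out1 <- runPerCancer(ch1, st, rule, nIter = 1000, seed = 2,
                       minSamples = 100)
  pan <- alfredTest(ch1, st, rule, nIter = 1000,
                    seed = substreamSeed(2, "type_AA"), cancerType = "AA")
  expect_equal(out1$perType$AA$p_test1, pan$p_test1)
  expect_true(!is.null(out$merged))
})
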