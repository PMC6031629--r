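test_that("simulation is deterministic and byte-identical on disk", {
  cfg <- simulationConfig(nSamples = 50, nControlSamples = 20, nGenes = 6,
                          seed = 101)
  a <- simulateCohort(cfg)
  b <- simulateCohort(cfg)
  expect_identical(a$variants, b$variants)
  expect_identical(a$truth, b$truth)
  d1 <- file.path(tempfile(), "run1"); d2 <- file.path(tempfile(), "run2")
  f1 <- writeCohort(a, d1); f2 <- writeCohort(b, d2)
  for (k in seq_along(f1)) {
    expect_identical(unname(tools::md5sum(f1[k])),
                     unname(tools::md5sum(f2[k])))
  }
})

test_that("config validation rejects inconsistent parameters", {
  expect_error(simulationConfig(nSamples = 100, strataProportions = c(.6, .6),
                                nStrata = 2), "sum to 1")
  expect_error(simulationConfig(baselineAiRate = 1.4), "rates")
  expect_error(simulationConfig(
    plantedGenes = data.frame(gene_id = "gene0001", carrier_rate = 2,
                              ai_rate_given_carrier = .5, case_excess = 0)),
    "planted")
})

test_that("truth-table carrier and AI frequencies converge to the config", {
  cfg <- simulationConfig(nSamples = 400, nGenes = 25, seed = 7,
                          rdgvCarrierRate = 0.05, baselineAiRate = 0.15)
  sim <- simulateCohort(cfg)
  ts <- sim$truth$geneSample
  carrierRate <- mean(ts$carrier)
  aiRate <- mean(ts$ai)
  # binomial 99.9% CI at n = 400 * 25 draws
  expect_lt(abs(carrierRate - 0.05), 3.3 * sqrt(0.05 * 0.95 / nrow(ts)))
  expect_lt(abs(aiRate - 0.15), 3.3 * sqrt(0.15 * 0.85 / nrow(ts)))
})

test_that("read simulation is binomial with fixed total depth", {
  set.seed(5)
  r <- simulateReads(rep(0.5, 10000), rep(100L, 10000))
  expect_true(all(r$alt + r$ref == 100L))
  expect_lt(abs(mean(r$alt) - 50), 1)
  expect_true(all(simulateReads(rep(0, 100), rep(30L, 100))$alt == 0))
})

test_that("two-hit tumor reads center on the LOH VAF", {
  cfg <- simulationConfig(nSamples = 300, nGenes = 10, seed = 3,
                          depthMean = 100, depthDispersion = 1e6,
                          plantedGenes = data.frame(
                            gene_id = "gene0001", carrier_rate = 0.2,
                            ai_rate_given_carrier = 0.9, case_excess = 0))
  sim <- simulateCohort(cfg)
  ts <- sim$truth$geneSample
  hot <- ts[ts$gene_id == "gene0001" & ts$twohit, ]
  v <- sim$variants
  rdgv <- v[v$functional_class %in% c("missense", "nonsense") &
              v$sample_id %in% hot$sample_id & v$chrom == "chr1", ]
  # keep only the planted gene's RDGVs (positions inside gene 1's body)
  rdgv <- rdgv[rdgv$pos <= 120000, ]
  vafT <- rdgv$tumor_alt_reads / (rdgv$tumor_alt_reads + rdgv$tumor_ref_reads)
  expect_gt(nrow(rdgv), 20)
  expect_lt(abs(mean(vafT) - 0.85), 0.02)
})

test_that("the null cohort removes planted effects but keeps the genotype block", {
  planted <- data.frame(gene_id = "gene0002", carrier_rate = 0.1,
                        ai_rate_given_carrier = 0.8, case_excess = 0.05)
  cfg <- simulationConfig(nSamples = 120, nControlSamples = 60, nGenes = 5,
                          seed = 13, plantedGenes = planted)
  full <- simulateCohort(cfg)
  null <- nullCohort(cfg)
  # same common-variant block (stream separation)
  fc <- full$variants[full$variants$chrom == "chr2", ]
  nc <- null$variants[null$variants$chrom == "chr2", ]
  expect_identical(fc, nc)
  # planted effects recorded as absent in the truth
  expect_equal(null$truth$genes$ai_rate_given_carrier,
               rep(cfg@baselineAiRate, 5))
  expect_true(all(null$truth$genes$case_excess == 0))
  # the planted run has a detectable AI excess in carriers; the null not
  tsF <- full$truth$geneSample
  tsN <- null$truth$geneSample
  g2F <- tsF[tsF$gene_id == "gene0002", ]
  g2N <- tsN[tsN$gene_id == "gene0002", ]
  expect_gt(mean(g2F$ai[g2F$carrier]), 0.5)
  expect_lt(mean(g2N$ai), 0.3)
})

test_that("PCA on simulated common variants separates the strata", {
  cfg <- simulationConfig(nSamples = 150, nGenes = 3, seed = 29)
  sim <- simulateCohort(cfg)
  gm <- buildGenotypeMatrix(sim$variants,
                            sampleIds = sim$samples$sample_id)
  sc <- runPCA(gm)
  true <- sim$samples$stratum_true[match(rownames(sc),
                                         sim$samples$sample_id)]
  st <- clusterStrata(sc, k = 3, trimFraction = 0, restarts = 10, seed = 1)
  # clustering recovers the true strata up to label permutation
  tab <- table(strataLabels(st), true)
  expect_equal(sum(apply(tab, 2, max)), 150)
})

test_that("paired VCF output round-trips through the VCF reader", {
  cfg <- simulationConfig(nSamples = 3, nGenes = 2, nCommonVariants = 10,
                          seed = 43)
  sim <- simulateCohort(cfg)
  dir <- tempfile()
  files <- suppressWarnings(writeCohort(sim, dir, vcf = TRUE))
  s1 <- sim$samples$sample_id[1]
  vcfPath <- file.path(files[["vcf_dir"]], paste0(s1, ".vcf"))
  expect_true(file.exists(vcfPath))
  back <- suppressWarnings(
    readVariantTable(vcfPath, "vcf_paired", sampleId = s1))
  orig <- sim$variants[sim$variants$sample_id == s1, ]
  orig <- orig[order(orig$chrom, orig$pos), ]
  back <- back[order(back$chrom, back$pos), ]
  expect_equal(nrow(back), nrow(orig))
  expect_equal(back$normal_alt_reads, orig$normal_alt_reads)
  expect_equal(back$tumor_alt_reads, orig$tumor_alt_reads)
  expect_equal(back$normal_genotype, orig$normal_genotype)
})
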