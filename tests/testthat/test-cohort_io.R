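test_that("TSV dialect round-trips all fields exactly", {
  v <- makeVariants(
    makeVariant(sample_id = "S1", pos = 100L, functional_class = "nonsense",
                deleterious_call = "unknown"),
    makeVariant(sample_id = "S2", pos = 250L, normal_genotype = "hom_alt",
                maf_global = 0.2, maf_subpop = 0.3,
                in_reference_db = FALSE))
  tf <- tempfile(fileext = ".tsv")
  writeVariantTable(v, tf)
  back <- readVariantTable(tf, dialect = "tsv")
  expect_equal(back, v, ignore_attr = TRUE)
})

test_that("empty variant file yields an empty observation table", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(character(0), tf)
  out <- readVariantTable(tf, "tsv")
  expect_equal(nrow(out), 0L)
  expect_true(all(alfredr:::.VARIANT_COLUMNS %in% names(out)))
})

test_that("paired VCF records map allele depths to observations", {
  tf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"AD\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tNORM\tTUM",
    "chr1\t123\t.\tA\tG\t.\tPASS\t.\tGT:AD\t0/1:50,50\t0/1:20,80",
    "chr1\t456\t.\tC\tG,T\t.\tPASS\t.\tGT:AD\t0/1:30,10,5\t0/1:25,15,8"),
    tf)
  obs <- readVariantTable(tf, dialect = "vcf_paired", sampleId = "P1")
  expect_equal(nrow(obs), 3L)  # multi-allelic record split per alt
  first <- obs[obs$pos == 123, ]
  expect_equal(first$normal_ref_reads, 50)
  expect_equal(first$normal_alt_reads, 50)
  expect_equal(first$tumor_ref_reads, 20)
  expect_equal(first$tumor_alt_reads, 80)
  expect_equal(first$sample_id, "P1")
  alts <- obs[obs$pos == 456, ]
  expect_setequal(alts$alt_allele, c("G", "T"))
  expect_equal(alts$normal_alt_reads[alts$alt_allele == "T"], 5)
})

test_that("VCF records without allele depths are skipped with a warning", {
  tf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"AD\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tNORM\tTUM",
    "chr1\t123\t.\tA\tG\t.\tPASS\t.\tGT\t0/1\t0/1",
    "chr1\t456\t.\tC\tT\t.\tPASS\t.\tGT:AD\t0/1:30,10\t0/1:25,15"),
    tf)
  expect_warning(obs <- readVariantTable(tf, "vcf_paired"), "skipped")
  expect_equal(nrow(obs), 1L)
  expect_equal(obs$pos, 456)
})

test_that("coverage masks retain only positions in the intersection", {
  v <- makeVariants(makeVariant(pos = 600L), makeVariant(pos = 1500L))
  m1 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1000))
  m2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(501, 2000))
  out <- applyCoverageMask(v, list(m1, m2))
  expect_equal(out$pos, 600L)
  # no masks -> identity
  expect_equal(applyCoverageMask(v, list()), v)
  # commutative and idempotent
  expect_equal(applyCoverageMask(v, list(m2, m1)), out)
  expect_equal(applyCoverageMask(out, list(m1, m2)), out,
               ignore_attr = TRUE)
  # empty intersection -> empty with warning
  m3 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5000, 6000))
  expect_warning(none <- applyCoverageMask(v, list(m1, m3)), "empty")
  expect_equal(nrow(none), 0L)
})

test_that("low-variant-count sample filter drops the configured fraction", {
  set.seed(1)
  ids <- sprintf("S%03d", 1:100)
  v <- do.call(rbind, lapply(seq_along(ids), function(i) {
    makeVariant(sample_id = ids[i], pos = 100L + i)
  }))
  # give two samples extra variants so they can never be dropped
  extra <- do.call(rbind, lapply(1:5, function(k) {
    makeVariant(sample_id = "S001", pos = 5000L + k)
  }))
  kept <- filterLowVariantSamples(rbind(v, extra), fraction = 0.02)
  expect_length(kept, 98L)
  expect_true("S001" %in% kept)
  # fraction 0 retains everyone
  expect_length(filterLowVariantSamples(v, fraction = 0), 100L)
  # all-equal counts: ties broken by id, lowest ids dropped
  kept2 <- filterLowVariantSamples(v, fraction = 0.02)
  expect_equal(setdiff(ids, kept2), c("S001", "S002"))
})

test_that("cohort matrices encode carrier, two-hit and missing AI", {
  genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(90L, 200L))
  names(genes) <- "gA"
  v <- makeVariants(
    # RDGV with VAF 0.50 -> 0.65: carrier and two-hit (0.15 >= 0.10)
    makeVariant(sample_id = "S1", pos = 100L, tumor_ref = 35L,
                tumor_alt = 65L),
    # RDGV with VAF 0.50 -> 0.55: carrier but no two-hit
    makeVariant(sample_id = "S2", pos = 120L, tumor_ref = 45L,
                tumor_alt = 55L))
  flags <- classifyRDGV(v, nSamples = 300)
  ai <- data.frame(sample_id = c("S1", "S2"), gene_id = "gA",
                   n_variants_used = 1L, pooled_p = c(0.01, NA),
                   ai_flag = c("AI", "no_AI"), stringsAsFactors = FALSE)
  meta <- data.frame(sample_id = c("S1", "S2", "S3"), group = "case",
                     stringsAsFactors = FALSE)
  ch <- buildCohortMatrices(v, ai, flags, genes, sampleMeta = meta)
  expect_true(rdgvCarrier(ch)["gA", "S1"])
  expect_true(twoHitEvent(ch)["gA", "S1"])
  expect_true(rdgvCarrier(ch)["gA", "S2"])
  expect_false(twoHitEvent(ch)["gA", "S2"])
  # sample without any variant in the window: missing AI status
  expect_true(is.na(aiStatus(ch)["gA", "S3"]))
  expect_equal(aiStatus(ch)["gA", "S1"], 1L)
  # two-hit implies carrier, enforced by class validity
  expect_true(methods::validObject(ch))
  # unknown gene in aiCalls is a hard error
  bad <- ai; bad$gene_id <- "nope"
  expect_error(buildCohortMatrices(v, bad, flags, genes), "absent")
})

test_that("two-hit events are always a subset of carriers on simulated data", {
  sim <- simulateCohort(simulationConfig(nSamples = 150, nGenes = 10,
                                         seed = 11))
  cases <- sim$samples$sample_id[sim$samples$group == "case"]
  flags <- classifyRDGV(sim$variants)
  ai <- callCohortAI(sim$variants, sim$genes)
  ch <- buildCohortMatrices(sim$variants, ai, flags, sim$genes,
                            sampleMeta = sim$samples)
  expect_false(any(twoHitEvent(ch) & !rdgvCarrier(ch)))
})
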