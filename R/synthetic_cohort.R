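# Synthetic paired tumor-normal cohort generator with known truth:
# population strata, common variants for PCA, RDGV carriers, allelic
# imbalance with directional VAF shifts, and binomial read counts. Every
# random decision is drawn from a named substream of the master seed, so
# (a) runs are byte-reproducible and (b) zeroing planted effects perturbs
# nothing else (the common-variant block is stream-separated from the AI
# and carrier draws).

#' Construct a simulation configuration
#'
#' See [SimulationConfig-class] for the meaning of every parameter.
#' Defaults describe the calibration conditions used throughout the test
#' suite: three strata (50/30/20\%) with disjoint common-variant allele
#' frequency ranges, 200 common variants, a 3\% per-gene RDGV carrier
#' rate, 12\% baseline AI, LOH shifting tumor VAF to 0.85, and
#' negative-binomial depth with mean 80 (size 10).
#'
#' @param nSamples,nControlSamples,nGenes,nStrata,strataProportions,nCommonVariants,commonMafRanges,rdgvCarrierRate,baselineAiRate,plantedGenes,vafLoh,depthMean,depthDispersion,variantsPerGeneWindow,nCancerTypes,seed
#'   See [SimulationConfig-class].
#' @return A validated [SimulationConfig-class].
#' @export
#' @examples
#' cfg <- simulationConfig(nSamples = 50, nGenes = 5, seed = 7)
simulationConfig <- function(nSamples = 1000, nControlSamples = 0,
                             nGenes = 100, nStrata = 3,
                             strataProportions = c(0.5, 0.3, 0.2),
                             nCommonVariants = 200,
                             commonMafRanges = NULL,
                             rdgvCarrierRate = 0.03,
                             baselineAiRate = 0.12,
                             plantedGenes = data.frame(),
                             vafLoh = 0.85,
                             depthMean = 80, depthDispersion = 10,
                             variantsPerGeneWindow = 4,
                             nCancerTypes = 1, seed = 1) {
  if (is.null(commonMafRanges)) {
    # evenly spaced disjoint ranges across [0.05, 0.95]
    centers <- seq(0.15, 0.85, length.out = nStrata)
    commonMafRanges <- lapply(centers, function(c) c(max(0.02, c - 0.1),
                                                     min(0.98, c + 0.1)))
  }
  methods::new("SimulationConfig",
    nSamples = as.integer(nSamples),
    nControlSamples = as.integer(nControlSamples),
    nGenes = as.integer(nGenes), nStrata = as.integer(nStrata),
    strataProportions = strataProportions,
    nCommonVariants = as.integer(nCommonVariants),
    commonMafRanges = commonMafRanges,
    rdgvCarrierRate = rdgvCarrierRate, baselineAiRate = baselineAiRate,
    plantedGenes = plantedGenes, vafLoh = vafLoh,
    depthMean = depthMean, depthDispersion = depthDispersion,
    variantsPerGeneWindow = as.integer(variantsPerGeneWindow),
    nCancerTypes = as.integer(nCancerTypes), seed = as.integer(seed))
}

#' Draw paired read counts at a site
#'
#' Alt reads are binomial(depth, vaf); alt + ref = depth always. Uses the
#' current RNG state.
#'
#' @param vaf Allele fraction(s) in \[0, 1\].
#' @param depth Total depth(s).
#' @return list with integer vectors \code{alt} and \code{ref}.
#' @export
simulateReads <- function(vaf, depth) {
  stopifnot(all(vaf >= 0 & vaf <= 1), all(depth >= 0))
  alt <- stats::rbinom(max(length(vaf), length(depth)), depth, vaf)
  list(alt = alt, ref = depth - alt)
}

# gene body layout on the synthetic chromosome: 20 kb genes every 300 kb,
# so the 100 kb AI windows of neighboring genes never overlap
.simGeneRanges <- function(nGenes) {
  start <- (seq_len(nGenes) - 1L) * 300000L + 100001L
  gr <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(start, start + 19999L))
  names(gr) <- sprintf("gene%04d", seq_len(nGenes))
  gr
}

#' Simulate a paired tumor-normal cohort with known truth
#'
#' Generates, per the configuration: sample strata and (for cases) cancer
#' types; common-variant genotypes with stratum-specific allele
#' frequencies (for PCA); per gene, heterozygous window variants at normal
#' VAF 0.5; RDGV carriers (each carrier gets its own rare variant at a
#' distinct position in the gene body); allelic imbalance per gene and
#' sample (baseline rate, or the planted rate for carriers of planted
#' genes); and binomial read counts at negative-binomial depths. Under AI
#' every window variant's tumor VAF shifts to \code{vafLoh} or
#' \code{1 - vafLoh} with random direction, while the RDGV allele of a
#' planted carrier rises deterministically to \code{vafLoh} (loss of the
#' wild-type allele — the two-hit assumption); incidental AI shifts the
#' RDGV in a random direction. Control samples contribute germline
#' genotypes and RDGV carrier status only (their tumor read columns
#' duplicate the normal counts as placeholders and carry no AI signal).
#'
#' @param config A [SimulationConfig-class].
#' @return list with \code{variants} (TSV-dialect data.frame),
#'   \code{samples} (metadata data.frame), \code{genes} (named
#'   \code{GRanges}), \code{truth} (list: \code{genes},
#'   \code{geneSample} with latent carrier/AI/two-hit indicators for case
#'   samples), and \code{config}.
#' @export
simulateCohort <- function(config) {
  methods::validObject(config)
  nS <- config@nSamples; nC <- config@nControlSamples
  nG <- config@nGenes; m <- config@variantsPerGeneWindow
  nAll <- nS + nC
  caseIds <- sprintf("S%05d", seq_len(nS))
  ctrlIds <- if (nC > 0) sprintf("C%05d", seq_len(nC)) else character(0)
  allIds <- c(caseIds, ctrlIds)
  genes <- .simGeneRanges(nG)
  geneIds <- names(genes)
  seed <- config@seed

  # planted-gene lookup
  pg <- config@plantedGenes
  plantedIdx <- if (nrow(pg)) match(pg$gene_id, geneIds) else integer(0)
  if (anyNA(plantedIdx)) stop("plantedGenes$gene_id not among simulated genes")
  carrierRate <- rep(config@rdgvCarrierRate, nG)
  aiRateCarrier <- rep(config@baselineAiRate, nG)
  caseExcess <- rep(0, nG)
  if (nrow(pg)) {
    carrierRate[plantedIdx] <- pg$carrier_rate
    aiRateCarrier[plantedIdx] <- pg$ai_rate_given_carrier
    caseExcess[plantedIdx] <- pg$case_excess
  }

  ## --- structure stream -------------------------------------------------
  set.seed(substreamSeed(seed, "structure"))
  strata <- sample.int(config@nStrata, nAll, replace = TRUE,
                       prob = config@strataProportions)
  ctype <- sample(sprintf("T%02d", seq_len(config@nCancerTypes)), nS,
                  replace = TRUE)

  ## --- genotypes stream: common variants for PCA ------------------------
  set.seed(substreamSeed(seed, "genotypes"))
  nCom <- config@nCommonVariants
  freqs <- vapply(config@commonMafRanges, function(r) {
    stats::runif(nCom, r[1L], r[2L])
  }, numeric(nCom))                     # nCom x nStrata
  freqs <- matrix(freqs, nrow = nCom)
  pMat <- t(freqs)[strata, , drop = FALSE]   # nAll x nCom
  gmat <- matrix(stats::rbinom(nAll * nCom, 2L, as.numeric(pMat)),
                 nAll, nCom)
  popFreq <- as.numeric(config@strataProportions %*% t(freqs))

  ## --- rdgv stream: carriers and variant classes ------------------------
  set.seed(substreamSeed(seed, "rdgv"))
  carrierU <- matrix(stats::runif(nG * nAll), nG, nAll)
  classU <- matrix(stats::runif(nG * nAll), nG, nAll)
  rateMat <- matrix(carrierRate, nG, nAll)
  if (nS > 0) {
    rateMat[, seq_len(nS)] <- rateMat[, seq_len(nS)] + caseExcess
  }
  carrier <- carrierU < pmin(1, rateMat)     # genes x all samples

  ## --- ai stream: AI indicators and shift directions --------------------
  set.seed(substreamSeed(seed, "ai"))
  aiU <- matrix(stats::runif(nG * nS), nG, nS)
  dirRdgvU <- matrix(stats::runif(nG * nS), nG, nS)
  dirWinU <- stats::runif(nG * nS * m)       # per window variant
  aiRateMat <- matrix(config@baselineAiRate, nG, nS)
  if (length(plantedIdx)) {
    for (j in seq_along(plantedIdx)) {
      gi <- plantedIdx[j]
      aiRateMat[gi, carrier[gi, seq_len(nS)]] <- pg$ai_rate_given_carrier[j]
    }
  }
  ai <- aiU < aiRateMat                      # genes x case samples
  plantedGene <- seq_len(nG) %in% plantedIdx
  # direction of the RDGV allele under AI: deterministic rise for planted
  # two-hit events, coin flip for incidental AI
  dirUp <- matrix(plantedGene, nG, nS) & carrier[, seq_len(nS), drop = FALSE]
  dirUp <- dirUp | (dirRdgvU < 0.5)

  ## --- reads stream ------------------------------------------------------
  set.seed(substreamSeed(seed, "reads"))
  vafLoh <- config@vafLoh
  rdepth <- function(n) {
    pmax(2L, stats::rnbinom(n, size = config@depthDispersion,
                            mu = config@depthMean))
  }

  # (1) common-variant block (cases + controls; no AI signal on chr2)
  carrierIdxCom <- which(gmat >= 1L)         # column-major over nAll x nCom
  csi <- ((carrierIdxCom - 1L) %% nAll) + 1L
  cvi <- ((carrierIdxCom - 1L) %/% nAll) + 1L
  vafCom <- ifelse(gmat[carrierIdxCom] == 2L, 1, 0.5)
  dN <- rdepth(length(csi)); dT <- rdepth(length(csi))
  altN <- stats::rbinom(length(csi), dN, vafCom)
  altT <- stats::rbinom(length(csi), dT, vafCom)
  comPos <- cvi * 1000L
  common <- data.table::data.table(
    sample_id = allIds[csi],
    variant_id = sprintf("chr2:%d:A:C", comPos),
    chrom = "chr2", pos = comPos,
    ref_allele = "A", alt_allele = "C",
    functional_class = "synonymous",
    normal_ref_reads = dN - altN, normal_alt_reads = altN,
    tumor_ref_reads = dT - altT, tumor_alt_reads = altT,
    normal_genotype = ifelse(gmat[carrierIdxCom] == 2L, "hom_alt", "het"),
    maf_global = popFreq[cvi],
    deleterious_call = "tolerated",
    in_reference_db = TRUE, passes_db_qc = TRUE,
    is_multinucleotide = FALSE)
  for (k in seq_along(.SUBPOPS)) {
    common[[paste0("maf_", .SUBPOPS[k])]] <-
      if (k <= config@nStrata) freqs[cvi, k] else popFreq[cvi]
  }

  # (2) heterozygous window variants (case samples only)
  wlo <- vapply(seq_len(nG), function(i) {
    .aiWindow(GenomicRanges::start(genes)[i],
              GenomicRanges::end(genes)[i])[1L]
  }, numeric(1))
  span <- 1e5
  # index order: gene fastest, then sample, then variant-in-window
  gi <- rep(rep(seq_len(nG), nS), m)
  si <- rep(rep(seq_len(nS), each = nG), m)
  vi <- rep(seq_len(m), each = nG * nS)
  wpos <- as.integer(floor(wlo[gi] + vi * span / (m + 1)))
  aiFlat <- ai[cbind(gi, si)]
  upWin <- dirWinU < 0.5
  vafWin <- ifelse(aiFlat, ifelse(upWin, vafLoh, 1 - vafLoh), 0.5)
  dNw <- rdepth(length(gi)); dTw <- rdepth(length(gi))
  altNw <- stats::rbinom(length(gi), dNw, 0.5)
  altTw <- stats::rbinom(length(gi), dTw, vafWin)
  windowV <- data.table::data.table(
    sample_id = caseIds[si],
    variant_id = sprintf("chr1:%d:A:G", wpos),
    chrom = "chr1", pos = wpos,
    ref_allele = "A", alt_allele = "G",
    functional_class = "synonymous",
    normal_ref_reads = dNw - altNw, normal_alt_reads = altNw,
    tumor_ref_reads = dTw - altTw, tumor_alt_reads = altTw,
    normal_genotype = "het",
    maf_global = 0.5,
    deleterious_call = "tolerated",
    in_reference_db = TRUE, passes_db_qc = TRUE,
    is_multinucleotide = FALSE)
  for (k in .SUBPOPS) {
    windowV[[paste0("maf_", k)]] <- rep(0.5, nrow(windowV))
  }

  # (3) RDGVs: one distinct rare variant per carrier, inside the gene body
  carrIdx <- which(carrier)                  # column-major over nG x nAll
  rgi <- ((carrIdx - 1L) %% nG) + 1L
  rsi <- ((carrIdx - 1L) %/% nG) + 1L
  rk <- stats::ave(rep(1L, length(rgi)), rgi, FUN = seq_along)
  rpos <- as.integer(GenomicRanges::start(genes)[rgi] + 9L + rk)
  isCase <- rsi <= nS
  aiR <- rep(FALSE, length(rgi))
  upR <- rep(FALSE, length(rgi))
  aiR[isCase] <- ai[cbind(rgi[isCase], rsi[isCase])]
  upR[isCase] <- dirUp[cbind(rgi[isCase], rsi[isCase])]
  vafR <- ifelse(aiR, ifelse(upR, vafLoh, 1 - vafLoh), 0.5)
  missenseR <- classU[cbind(rgi, rsi)] < 0.8
  dNr <- rdepth(length(rgi)); dTr <- rdepth(length(rgi))
  altNr <- stats::rbinom(length(rgi), dNr, 0.5)
  altTr <- stats::rbinom(length(rgi), dTr, vafR)
  # controls carry no tumor sample; duplicate the germline counts
  altTr[!isCase] <- altNr[!isCase]
  dTr[!isCase] <- dNr[!isCase]
  rdgvV <- data.table::data.table(
    sample_id = allIds[rsi],
    variant_id = sprintf("chr1:%d:C:T", rpos),
    chrom = "chr1", pos = rpos,
    ref_allele = "C", alt_allele = "T",
    functional_class = ifelse(missenseR, "missense", "nonsense"),
    normal_ref_reads = dNr - altNr, normal_alt_reads = altNr,
    tumor_ref_reads = dTr - altTr, tumor_alt_reads = altTr,
    normal_genotype = "het",
    maf_global = 1e-4,
    deleterious_call = ifelse(missenseR, "deleterious", "unknown"),
    in_reference_db = TRUE, passes_db_qc = TRUE,
    is_multinucleotide = FALSE)
  for (k in .SUBPOPS) {
    rdgvV[[paste0("maf_", k)]] <- rep(1e-4, nrow(rdgvV))
  }

  # (4) window variants of control samples: germline het sites only (the
  # tumor columns duplicate the germline counts; controls carry no AI
  # signal but must share the common variant sites with the cases, or the
  # genotype matrix would separate cases from controls instead of ancestry)
  ctrlWindowV <- NULL
  if (nC > 0) {
    gic <- rep(rep(seq_len(nG), nC), m)
    sic <- rep(rep(seq_len(nC), each = nG), m)
    vic <- rep(seq_len(m), each = nG * nC)
    wposc <- as.integer(floor(wlo[gic] + vic * span / (m + 1)))
    dNc <- rdepth(length(gic))
    altNc <- stats::rbinom(length(gic), dNc, 0.5)
    ctrlWindowV <- data.table::data.table(
      sample_id = ctrlIds[sic],
      variant_id = sprintf("chr1:%d:A:G", wposc),
      chrom = "chr1", pos = wposc,
      ref_allele = "A", alt_allele = "G",
      functional_class = "synonymous",
      normal_ref_reads = dNc - altNc, normal_alt_reads = altNc,
      tumor_ref_reads = dNc - altNc, tumor_alt_reads = altNc,
      normal_genotype = "het",
      maf_global = 0.5,
      deleterious_call = "tolerated",
      in_reference_db = TRUE, passes_db_qc = TRUE,
      is_multinucleotide = FALSE)
    for (k in .SUBPOPS) {
      ctrlWindowV[[paste0("maf_", k)]] <- rep(0.5, nrow(ctrlWindowV))
    }
  }

  blocks <- list(common, windowV, rdgvV)
  if (!is.null(ctrlWindowV)) blocks <- c(blocks, list(ctrlWindowV))
  variants <- as.data.frame(data.table::rbindlist(blocks, use.names = TRUE))
  variants <- variants[, .VARIANT_COLUMNS]

  samples <- data.frame(
    sample_id = allIds,
    group = c(rep("case", nS), rep("control", nC)),
    cancer_type = c(ctype, rep(NA_character_, nC)),
    batch = "SIM",
    stratum_true = strata,
    stringsAsFactors = FALSE)

  truthGenes <- data.frame(
    gene_id = geneIds, planted = plantedGene,
    carrier_rate = carrierRate, ai_rate_given_carrier = aiRateCarrier,
    case_excess = caseExcess, stringsAsFactors = FALSE)
  tg <- rep(seq_len(nG), nS)
  ts <- rep(seq_len(nS), each = nG)
  truthGS <- data.frame(
    gene_id = geneIds[tg], sample_id = caseIds[ts],
    carrier = carrier[cbind(tg, ts)],
    ai = ai[cbind(tg, ts)],
    twohit = carrier[cbind(tg, ts)] & ai[cbind(tg, ts)] &
      dirUp[cbind(tg, ts)],
    stringsAsFactors = FALSE)

  list(variants = variants, samples = samples, genes = genes,
       truth = list(genes = truthGenes, geneSample = truthGS),
       config = config)
}

#' Remove all planted effects from a configuration and simulate
#'
#' Identical generative process with every planted gene's AI rate reset to
#' the baseline and its case excess zeroed; because the simulator's
#' substreams are named, the common-variant block is identical to the
#' planted run at the same seed.
#'
#' @param config A [SimulationConfig-class].
#' @return As [simulateCohort()].
#' @export
nullCohort <- function(config) {
  pg <- config@plantedGenes
  if (nrow(pg)) {
    pg$ai_rate_given_carrier <- config@baselineAiRate
    pg$case_excess <- 0
    config@plantedGenes <- pg
  }
  simulateCohort(config)
}

#' Write a simulated cohort to disk
#'
#' Writes the TSV-dialect variant table, sample metadata, gene regions as
#' BED, and both truth tables; optionally also one paired-sample VCF per
#' case sample (plain-text VCF 4.2 with GT:AD genotype fields, readable by
#' \code{readVariantTable(dialect = "vcf_paired")}).
#'
#' @param cohort As returned by [simulateCohort()].
#' @param dir Output directory (created if needed).
#' @param vcf Also write per-sample paired VCFs (default FALSE).
#' @return Invisibly, the vector of files written.
#' @export
writeCohort <- function(cohort, dir, vcf = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(
    variants = file.path(dir, "variants.tsv"),
    samples = file.path(dir, "samples.tsv"),
    genes = file.path(dir, "genes.bed"),
    truth_genes = file.path(dir, "truth_genes.tsv"),
    truth_gene_sample = file.path(dir, "truth_gene_sample.tsv"))
  writeVariantTable(cohort$variants, files["variants"])
  data.table::fwrite(cohort$samples, files["samples"], sep = "\t", na = "NA",
                     quote = FALSE)
  genes <- cohort$genes
  genes$name <- names(genes)
  rtracklayer::export(genes, files[["genes"]], format = "BED")
  data.table::fwrite(cohort$truth$genes, files["truth_genes"], sep = "\t",
                     na = "NA", quote = FALSE)
  data.table::fwrite(cohort$truth$geneSample, files["truth_gene_sample"],
                     sep = "\t", na = "NA", quote = FALSE)
  if (vcf) {
    vdir <- file.path(dir, "vcf")
    dir.create(vdir, showWarnings = FALSE)
    cases <- cohort$samples$sample_id[cohort$samples$group == "case"]
    for (s in cases) {
      .writePairedVcf(cohort$variants[cohort$variants$sample_id == s, ],
                      file.path(vdir, paste0(s, ".vcf")), s)
    }
    files <- c(files, vcf_dir = vdir)
  }
  invisible(files)
}

# minimal paired-sample VCF writer for simulator output (GT:AD fields)
.writePairedVcf <- function(variants, path, sampleId) {
  v <- variants[order(variants$chrom, variants$pos), , drop = FALSE]
  gt <- ifelse(v$normal_genotype == "hom_alt", "1/1", "0/1")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
           "Description=\"Allelic depths (ref,alt)\">"),
    sprintf("##contig=<ID=%s>", unique(v$chrom)),
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", paste0(sampleId, "_N"), paste0(sampleId, "_T"),
          sep = "\t"),
    sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t.\tGT:AD\t%s:%d,%d\t%s:%d,%d",
            v$chrom, v$pos, v$variant_id, v$ref_allele, v$alt_allele,
            gt, v$normal_ref_reads, v$normal_alt_reads,
            gt, v$tumor_ref_reads, v$tumor_alt_reads))
  writeLines(lines, path)
  invisible(path)
}
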