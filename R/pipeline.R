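# End-to-end orchestration: simulate (or read) -> QC -> classify ->
# AI calling -> strata -> gene test -> burden/contribution, with a JSON
# run manifest. Reruns with the same configuration and seed are
# byte-identical (the manifest deliberately records no wall-clock times);
# stage timing is logged to stderr instead.

.pipelineDefaults <- function() {
  list(
    mafThreshold = 0.001, recurrenceMax = 0.01,
    highVaf = 0.7, lowVaf = 0.3, minSpan = 1e5, alpha = 0.05,
    vafIncrease = 0.10,
    minRdgvCarriers = 5, minVafIncCarriers = 1, minAiFrequency = 0.10,
    mafMin = 0.05, pcs = 4, k = 10, trim = 0.05, restarts = 20,
    sampleDropFraction = 0.02, indelMinDepth = 10, indelAlpha = 0.05,
    fdr = 0.2, minSamplesPerType = 300)
}

.configHash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tf)
  unname(tools::md5sum(tf))
}

.logStage <- function(name, t0) {
  message(sprintf("[alfredr] stage %-12s %.1fs", name,
                  as.numeric(Sys.time()) - t0))
}

#' Run the full discovery pipeline
#'
#' Orchestrates one end-to-end run from a single configuration: obtain the
#' cohort (from the bundled simulator or from files), apply sample- and
#' site-level QC (low-variant-count sample removal, indel QC, coverage-mask
#' intersection), classify qualifying rare damaging variants, call
#' per-gene allelic imbalance on the case samples, estimate population
#' strata from common variants, run the gene test (pan-cancer, and
#' per-cancer when configured), and — when control samples are present —
#' the case-control burden tests and contribution curve for the
#' FDR-significant genes. All stage outputs are tab-separated files under
#' \code{outDir} plus a JSON manifest recording parameters, seed, row
#' counts and output checksums.
#'
#' @param config A named list, or path to a YAML file, with elements:
#'   \code{seed}, \code{iters}, \code{mode} ("rdgv"/"ptv"), exactly one of
#'   \code{simulate} (parameters for [simulationConfig()]) or
#'   \code{inputs} (paths: \code{variants}, \code{genes}, \code{samples},
#'   optional \code{masks}), optional \code{params} overriding any
#'   pipeline default, and optional \code{perCancer} flag.
#' @param outDir Output directory.
#' @param force Recompute even when a manifest with the same configuration
#'   hash already exists (default FALSE; the skip makes completed runs
#'   no-ops).
#' @return list with the in-memory results (\code{results},
#'   \code{aiCalls}, \code{cohort}, \code{strata}, \code{burden},
#'   \code{contribution}, \code{perCancer}), the \code{manifest}, and
#'   \code{cached = TRUE} when a completed identical run was found.
#' @export
runPipeline <- function(config, outDir, force = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  seed <- as.integer(config$seed %||% 1L)
  nIter <- as.integer(config$iters %||% 10000L)
  mode <- config$mode %||% "rdgv"
  if (nIter < 1L) stop("iters must be >= 1", call. = FALSE)
  if (!mode %in% c("rdgv", "ptv")) stop("mode must be 'rdgv' or 'ptv'",
                                        call. = FALSE)
  if (is.null(config$simulate) == is.null(config$inputs)) {
    stop("exactly one of 'simulate' or 'inputs' must be given",
         call. = FALSE)
  }
  par <- utils::modifyList(.pipelineDefaults(), config$params %||% list())
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  hash <- .configHash(list(config = config, defaults = par))
  manifestPath <- file.path(outDir, "manifest.json")
  if (!force && file.exists(manifestPath)) {
    man <- jsonlite::read_json(manifestPath, simplifyVector = TRUE)
    if (identical(man$config_hash, unname(hash)) &&
        all(file.exists(file.path(outDir, names(man$checksums))))) {
      return(list(cached = TRUE, manifest = man))
    }
  }

  ## stage: cohort ---------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  if (!is.null(config$simulate)) {
    simArgs <- config$simulate
    simArgs$seed <- simArgs$seed %||% seed
    if (!is.null(simArgs$plantedGenes)) {
      simArgs$plantedGenes <- as.data.frame(simArgs$plantedGenes)
    }
    sim <- simulateCohort(do.call(simulationConfig, simArgs))
    variants <- sim$variants
    samples <- sim$samples
    genes <- sim$genes
  } else {
    inp <- config$inputs
    variants <- readVariantTable(inp$variants, dialect = "tsv")
    samples <- readSampleMeta(inp$samples)
    genes <- readGeneRegions(inp$genes)
    sim <- NULL
    if (!is.null(inp$masks)) {
      masks <- lapply(inp$masks, readBedMask)
      variants <- applyCoverageMask(variants, masks)
    }
  }
  .logStage("cohort", t0)

  ## stage: qc -------------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  isIndel <- variants$functional_class %in% c("frameshift_indel",
                                              "inframe_indel")
  if (any(isIndel)) {
    keep <- !isIndel
    keep[isIndel] <- indelQC(variants$normal_alt_reads[isIndel],
                             variants$normal_ref_reads[isIndel],
                             minDepth = par$indelMinDepth,
                             alpha = par$indelAlpha)
    variants <- variants[keep, , drop = FALSE]
  }
  keptSamples <- filterLowVariantSamples(variants,
                                         fraction = par$sampleDropFraction,
                                         sampleIds = samples$sample_id)
  samples <- samples[samples$sample_id %in% keptSamples, , drop = FALSE]
  variants <- variants[variants$sample_id %in% keptSamples, , drop = FALSE]
  .logStage("qc", t0)

  ## stage: classify --------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  flags <- classifyRDGV(variants, mode = mode,
                        mafThreshold = par$mafThreshold,
                        recurrenceMax = par$recurrenceMax,
                        nSamples = nrow(samples))
  .logStage("classify", t0)

  ## stage: AI calling (case samples only) ----------------------------------
  t0 <- as.numeric(Sys.time())
  caseIds <- samples$sample_id[samples$group == "case"]
  aiCalls <- callCohortAI(variants[variants$sample_id %in% caseIds, ],
                          genes, highVaf = par$highVaf, lowVaf = par$lowVaf,
                          alpha = par$alpha, minSpan = par$minSpan)
  .logStage("ai_calls", t0)

  ## stage: matrices ---------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  cohort <- buildCohortMatrices(variants, aiCalls, flags, genes,
                                sampleMeta = samples,
                                vafIncreaseThreshold = par$vafIncrease)
  .logStage("matrices", t0)

  ## stage: strata ------------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  gmatAll <- buildGenotypeMatrix(variants, mafMin = par$mafMin,
                                 sampleIds = samples$sample_id)
  scoresAll <- runPCA(gmatAll, nComponents = par$pcs)
  kUse <- min(par$k, nrow(scoresAll))
  strataAll <- clusterStrata(scoresAll, k = kUse, trimFraction = par$trim,
                             restarts = par$restarts,
                             seed = substreamSeed(seed, "strata"))
  stAll <- strataLabels(strataAll)
  .logStage("strata", t0)

  ## stage: gene test ----------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  caseCohort <- cohort[, colnames(cohort) %in% caseIds]
  stCases <- stAll[colnames(caseCohort)]
  rule <- geneInclusionRule(minRdgvCarriers = par$minRdgvCarriers,
                            minVafIncCarriers = par$minVafIncCarriers,
                            minAiFrequency = par$minAiFrequency)
  results <- alfredTest(caseCohort, stCases, rule = rule, nIter = nIter,
                        seed = seed)
  .logStage("gene_test", t0)

  perCancer <- NULL
  if (isTRUE(config$perCancer)) {
    t0 <- as.numeric(Sys.time())
    perCancer <- runPerCancer(caseCohort, stCases, rule = rule,
                              nIter = nIter, seed = seed,
                              minSamples = par$minSamplesPerType)
    .logStage("per_cancer", t0)
  }

  ## stage: burden -------------------------------------------------------------
  burden <- NULL
  contribution <- NULL
  hasControls <- any(samples$group == "control")
  sig <- character(0)
  if (nrow(results)) {
    ok <- !is.na(results$fdr_q) & results$fdr_q <= par$fdr
    sig <- results$gene_id[ok]
    sig <- sig[order(results$p_alfred[ok], sig)]
  }
  if (hasControls && length(sig)) {
    t0 <- as.numeric(Sys.time())
    grp1 <- SummarizedExperiment::colData(cohort)$group == "case"
    rc <- rdgvCarrier(cohort)
    rows <- lapply(sig, function(g) {
      r <- burdenTest(rc[g, ], grp1, stAll, nIter = nIter,
                      seed = substreamSeed(seed, paste0("burden_", g)),
                      design = "case_control")
      if (is.null(r)) return(NULL)
      data.frame(gene_id = g, excess = r@effectSize, ci_low = r@ciLow,
                 ci_high = r@ciHigh, empirical_p = r@empiricalP,
                 stringsAsFactors = FALSE)
    })
    burden <- do.call(rbind, rows)
    contribution <- contributionCurve(rc, sig, grp1, stAll, nIter = nIter,
                                      seed = substreamSeed(seed, "contrib"))
    .logStage("burden", t0)
  }

  ## stage: outputs --------------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  outputs <- list(
    "ai_calls.tsv" = aiCalls,
    "rdgv_flags.tsv" = flags,
    "strata.tsv" = data.frame(sample_id = names(stAll), stratum = stAll,
                              pcaScores(strataAll),
                              stringsAsFactors = FALSE),
    "results.tsv" = as.data.frame(results))
  if (!is.null(burden)) outputs[["burden.tsv"]] <- burden
  if (!is.null(contribution)) {
    outputs[["contribution.tsv"]] <- contribution$curve
  }
  if (!is.null(perCancer) && !is.null(perCancer$merged)) {
    outputs[["per_cancer.tsv"]] <- as.data.frame(perCancer$merged)
  }
  for (f in names(outputs)) {
    data.table::fwrite(outputs[[f]], file.path(outDir, f), sep = "\t",
                       na = "NA", quote = FALSE)
  }
  checksums <- vapply(names(outputs), function(f) {
    unname(tools::md5sum(file.path(outDir, f)))
  }, character(1))
  manifest <- list(
    package = "alfredr",
    version = as.character(utils::packageVersion("alfredr")),
    seed = seed, iterations = nIter, mode = mode,
    parameters = par, config_hash = unname(hash),
    n_samples = nrow(samples), n_case = length(caseIds),
    n_variants = nrow(variants), n_genes = length(genes),
    n_tested_genes = nrow(results),
    significant_genes = as.list(sig),
    checksums = as.list(checksums))
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  .logStage("outputs", t0)

  list(cached = FALSE, results = results, aiCalls = aiCalls,
       cohort = cohort, strata = strataAll, burden = burden,
       contribution = contribution, perCancer = perCancer,
       truth = if (!is.null(sim)) sim$truth else NULL,
       manifest = manifest)
}
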