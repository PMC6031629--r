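#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' TwoHitCohort: gene-by-sample indicator matrices for two-hit testing
#'
#' A \linkS4class{SummarizedExperiment} subclass holding the three gene x
#' sample matrices consumed by the gene tests:
#' \describe{
#'   \item{\code{rdgvCarrier}}{logical; sample carries at least one
#'     qualifying rare damaging germline variant (RDGV) inside the gene
#'     body.}
#'   \item{\code{aiStatus}}{integer; 1 = allelic imbalance (putative LOH)
#'     called in the gene window, 0 = evaluable but no AI, NA = no
#'     informative heterozygous variant in the window.}
#'   \item{\code{twoHitEvent}}{logical; at least one RDGV in the gene whose
#'     tumor VAF exceeds its normal VAF by the configured increase
#'     threshold (default 10 percentage points).}
#' }
#' Rows are genes (with their genomic ranges), columns are samples (with
#' case/control group, cancer type and batch in \code{colData}). Validity
#' enforces that every two-hit event is also an RDGV carrier.
#'
#' @seealso [buildCohortMatrices()] which constructs the object,
#'   [alfredTest()] which consumes it.
#' @export
setClass("TwoHitCohort", contains = "SummarizedExperiment")

setValidity("TwoHitCohort", function(object) {
  an <- SummarizedExperiment::assayNames(object)
  need <- c("rdgvCarrier", "aiStatus", "twoHitEvent")
  if (!all(need %in% an)) {
    return(paste("assays must include:", paste(need, collapse = ", ")))
  }
  rc <- SummarizedExperiment::assay(object, "rdgvCarrier")
  th <- SummarizedExperiment::assay(object, "twoHitEvent")
  ai <- SummarizedExperiment::assay(object, "aiStatus")
  if (!is.logical(rc) || !is.logical(th)) {
    return("rdgvCarrier and twoHitEvent must be logical matrices")
  }
  if (any(th & !rc, na.rm = TRUE)) {
    return("twoHitEvent implies rdgvCarrier; found two-hit non-carriers")
  }
  if (!all(ai %in% c(0L, 1L, NA))) {
    return("aiStatus entries must be 0, 1 or NA")
  }
  TRUE
})

#' StratumAssignment: population-structure strata for permutation tests
#'
#' Holds the per-sample stratum labels produced by trimmed clustering of
#' principal-component scores of the common-variant genotype matrix, plus
#' the scores themselves. Stratum 0 marks trimmed (outlying) samples, which
#' are excluded from every randomization test.
#'
#' @slot strata Named integer vector, one entry per sample; 0 = trimmed.
#' @slot scores Numeric matrix of PCA scores (samples x components).
#' @slot k Integer number of clusters requested.
#' @slot trimFraction Fraction of samples trimmed as outliers.
#' @seealso [clusterStrata()], [stratifiedPermutation()]
#' @export
setClass("StratumAssignment",
  slots = c(strata = "integer", scores = "matrix", k = "integer",
            trimFraction = "numeric"))

setValidity("StratumAssignment", function(object) {
  if (is.null(names(object@strata))) return("strata must be named by sample")
  if (nrow(object@scores) != length(object@strata)) {
    return("scores rows must match strata length")
  }
  if (any(object@strata < 0L | object@strata > object@k)) {
    return("stratum labels must lie in 0..k")
  }
  TRUE
})

#' RandomizationResult: outcome of a stratified randomization test
#'
#' Summarizes one stratified label-permutation test: the observed
#' carrier-frequency difference, the permutation null (median and 2.5/97.5
#' percentiles), the add-one-smoothed empirical P-value
#' \eqn{(b + 1)/(N + 1)} where \eqn{b} counts null statistics greater than
#' or equal to the observed one, the effect size (observed minus null
#' median) and its 95\% confidence bounds (observed minus the 97.5th and
#' 2.5th null percentiles).
#'
#' @slot observed Observed test statistic (difference of carrier
#'   frequencies between the two label groups).
#' @slot nullMedian,nullLower,nullUpper Median, 2.5th and 97.5th percentile
#'   of the permutation null.
#' @slot nIterations Number of randomizations.
#' @slot nGeObserved Count of null statistics >= observed.
#' @slot empiricalP Add-one-smoothed empirical P-value.
#' @slot effectSize Observed statistic minus null median.
#' @slot ciLow,ciHigh 95\% confidence bounds of the effect size.
#' @slot seed Integer seed used for the permutation stream.
#' @export
setClass("RandomizationResult",
  slots = c(observed = "numeric", nullMedian = "numeric",
            nullLower = "numeric", nullUpper = "numeric",
            nIterations = "integer", nGeObserved = "integer",
            empiricalP = "numeric", effectSize = "numeric",
            ciLow = "numeric", ciHigh = "numeric", seed = "integer"))

setValidity("RandomizationResult", function(object) {
  p <- object@empiricalP
  if (length(p) != 1L || is.na(p) || p <= 0 || p > 1) {
    return("empiricalP must be a single probability in (0,1]")
  }
  expect <- (object@nGeObserved + 1) / (object@nIterations + 1)
  if (abs(p - expect) > 1e-12) {
    return("empiricalP must equal (nGeObserved + 1)/(nIterations + 1)")
  }
  if (object@nullLower > object@nullUpper) {
    return("null percentiles out of order")
  }
  TRUE
})

#' SimulationConfig: parameters of the synthetic paired-cohort generator
#'
#' All knobs of [simulateCohort()]. Defaults encode the study conditions the
#' package is calibrated under: three population strata with disjoint
#' common-variant allele-frequency ranges (so PCA separates them), a 3\%
#' per-gene RDGV carrier rate, a 12\% baseline allelic-imbalance rate, loss
#' of heterozygosity shifting tumor VAF to 0.85, negative-binomial read
#' depth with mean 80, and four heterozygous variants per gene window.
#'
#' @slot nSamples,nControlSamples Number of case (tumor-normal pair) and
#'   control (germline-only) samples.
#' @slot nGenes Number of genes on the synthetic chromosome.
#' @slot nStrata,strataProportions Number of population strata and their
#'   mixing proportions (must sum to 1).
#' @slot nCommonVariants Number of common variants used for PCA.
#' @slot commonMafRanges List (one per stratum) of c(lo, hi) allele
#'   frequency ranges for the common variants.
#' @slot rdgvCarrierRate Per-gene probability that a sample carries an RDGV.
#' @slot baselineAiRate Per-gene probability of incidental allelic
#'   imbalance.
#' @slot plantedGenes data.frame with columns \code{gene_id},
#'   \code{carrier_rate}, \code{ai_rate_given_carrier}, \code{case_excess};
#'   genes listed here get elevated AI in carriers (two-hit signal) and/or
#'   a case-vs-control carrier-frequency excess.
#' @slot vafLoh Tumor VAF of the retained allele under LOH.
#' @slot depthMean,depthDispersion Mean and negative-binomial size of the
#'   per-site read depth.
#' @slot variantsPerGeneWindow Heterozygous informative variants per gene
#'   window.
#' @slot nCancerTypes Number of cancer-type labels assigned uniformly to
#'   case samples.
#' @slot seed Master seed; all simulator substreams derive from it.
#' @seealso [simulateCohort()], [nullCohort()]
#' @export
setClass("SimulationConfig",
  slots = c(nSamples = "integer", nControlSamples = "integer",
            nGenes = "integer", nStrata = "integer",
            strataProportions = "numeric", nCommonVariants = "integer",
            commonMafRanges = "list", rdgvCarrierRate = "numeric",
            baselineAiRate = "numeric", plantedGenes = "data.frame",
            vafLoh = "numeric", depthMean = "numeric",
            depthDispersion = "numeric", variantsPerGeneWindow = "integer",
            nCancerTypes = "integer", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  rates <- c(object@rdgvCarrierRate, object@baselineAiRate, object@vafLoh)
  if (any(rates < 0 | rates > 1)) return("rates must lie in [0,1]")
  if (abs(sum(object@strataProportions) - 1) > 1e-9) {
    return("strataProportions must sum to 1")
  }
  if (length(object@strataProportions) != object@nStrata) {
    return("strataProportions length must equal nStrata")
  }
  if (length(object@commonMafRanges) != object@nStrata) {
    return("commonMafRanges must have one c(lo, hi) range per stratum")
  }
  if (object@nSamples < 1L || object@nGenes < 1L) {
    return("nSamples and nGenes must be positive")
  }
  pg <- object@plantedGenes
  if (nrow(pg)) {
    need <- c("gene_id", "carrier_rate", "ai_rate_given_carrier",
              "case_excess")
    if (!all(need %in% names(pg))) {
      return(paste("plantedGenes needs columns:", paste(need, collapse = ", ")))
    }
    if (any(pg$carrier_rate < 0 | pg$carrier_rate > 1) ||
        any(pg$ai_rate_given_carrier < 0 | pg$ai_rate_given_carrier > 1)) {
      return("planted rates must lie in [0,1]")
    }
  }
  if (object@depthMean <= 0) return("depthMean must be positive")
  TRUE
})
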