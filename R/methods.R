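# Accessors and show() methods for the S4 classes.

#' @describeIn TwoHitCohort-accessors RDGV carrier indicator matrix.
#' @export
rdgvCarrier <- function(x) {
  stopifnot(is(x, "TwoHitCohort"))
  SummarizedExperiment::assay(x, "rdgvCarrier")
}

#' Accessors for TwoHitCohort assays
#'
#' @param x A [TwoHitCohort-class] object.
#' @return The corresponding gene x sample matrix.
#' @name TwoHitCohort-accessors
NULL

#' @describeIn TwoHitCohort-accessors Allelic-imbalance status matrix
#'   (1 = AI, 0 = no AI, NA = not evaluable).
#' @export
aiStatus <- function(x) {
  stopifnot(is(x, "TwoHitCohort"))
  SummarizedExperiment::assay(x, "aiStatus")
}

#' @describeIn TwoHitCohort-accessors Two-hit event indicator matrix.
#' @export
twoHitEvent <- function(x) {
  stopifnot(is(x, "TwoHitCohort"))
  SummarizedExperiment::assay(x, "twoHitEvent")
}

setMethod("show", "TwoHitCohort", function(object) {
  cat("TwoHitCohort with", nrow(object), "genes x", ncol(object), "samples\n")
  ai <- aiStatus(object)
  cat(sprintf("  AI calls: %.1f%% AI, %.1f%% evaluable\n",
              100 * mean(ai == 1L, na.rm = TRUE),
              100 * mean(!is.na(ai))))
  cat(sprintf("  RDGV carrier gene-samples: %d; two-hit events: %d\n",
              sum(rdgvCarrier(object), na.rm = TRUE),
              sum(twoHitEvent(object), na.rm = TRUE)))
  callNextMethod()
})

#' @describeIn StratumAssignment-accessors Named integer stratum labels
#'   (0 = trimmed outlier).
#' @export
strataLabels <- function(x) {
  stopifnot(is(x, "StratumAssignment"))
  x@strata
}

#' Accessors for StratumAssignment
#'
#' @param x A [StratumAssignment-class] object.
#' @name StratumAssignment-accessors
NULL

#' @describeIn StratumAssignment-accessors PCA score matrix
#'   (samples x components).
#' @export
pcaScores <- function(x) {
  stopifnot(is(x, "StratumAssignment"))
  x@scores
}

setMethod("show", "StratumAssignment", function(object) {
  tab <- table(factor(object@strata, levels = 0:object@k))
  cat("StratumAssignment:", length(object@strata), "samples in",
      object@k, "strata\n")
  cat("  trimmed (stratum 0):", tab["0"], "samples\n")
  cat("  stratum sizes:", paste(tab[-1], collapse = ", "), "\n")
})

#' @describeIn RandomizationResult-accessors Add-one-smoothed empirical
#'   P-value.
#' @export
empiricalP <- function(x) {
  stopifnot(is(x, "RandomizationResult"))
  x@empiricalP
}

#' Accessors for RandomizationResult
#'
#' @param x A [RandomizationResult-class] object.
#' @name RandomizationResult-accessors
NULL

#' @describeIn RandomizationResult-accessors Effect size (observed minus
#'   null median), a percentage-point carrier excess.
#' @export
effectSize <- function(x) {
  stopifnot(is(x, "RandomizationResult"))
  x@effectSize
}

#' @describeIn RandomizationResult-accessors 95\% confidence interval of
#'   the effect size, c(low, high).
#' @export
effectCI <- function(x) {
  stopifnot(is(x, "RandomizationResult"))
  c(x@ciLow, x@ciHigh)
}

setMethod("show", "RandomizationResult", function(object) {
  cat(sprintf(
    "RandomizationResult: observed %.4g, empirical P = %.3g (%d iterations)\n",
    object@observed, object@empiricalP, object@nIterations))
  cat(sprintf("  effect size %.4g [95%% CI %.4g, %.4g]\n",
              object@effectSize, object@ciLow, object@ciHigh))
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nSamples, "cases,",
      object@nControlSamples, "controls,", object@nGenes, "genes,",
      object@nStrata, "strata\n")
  cat(sprintf("  carrier rate %.3g, baseline AI %.3g, LOH VAF %.2f, depth %g\n",
              object@rdgvCarrierRate, object@baselineAiRate, object@vafLoh,
              object@depthMean))
  if (nrow(object@plantedGenes)) {
    cat("  planted genes:", paste(object@plantedGenes$gene_id, collapse = ", "),
        "\n")
  }
  cat("  seed:", object@seed, "\n")
})
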