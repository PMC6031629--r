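# RDGV-frequency (burden) designs: case-control, cancer-type-vs-rest,
# AI-restricted type-vs-rest, the leave-one-type-out variant, and the
# contribution-to-risk curves with maximum-excess reporting.

#' Stratified-randomization burden test for a carrier excess
#'
#' Tests for an excess of RDGV carriers in group 1 over group 0 (cases vs
#' controls, one cancer type vs the rest, or the AI-restricted variant —
#' for the latter the caller restricts the sample universe to AI samples
#' before calling). The statistic, null, empirical P, effect size and CI
#' follow the same stratified-permutation machinery as the gene test; the
#' effect size is interpretable as a percentage-point excess of carriers.
#'
#' @param carrier Logical carrier indicator over the design's sample
#'   universe (for a gene set, OR-reduced over member genes).
#' @param group1 Logical: sample belongs to group 1.
#' @param strata A [StratumAssignment-class] or integer stratum vector
#'   over the same samples (0 = trimmed, excluded).
#' @param nIter,seed As in [test1Enrichment()].
#' @param design Label recorded on the result: one of
#'   \code{"case_control"}, \code{"type_vs_rest"},
#'   \code{"type_vs_rest_ai_only"}, \code{"type_vs_rest_loo"}.
#' @return A [RandomizationResult-class] with a \code{"design"} attribute,
#'   or NULL when a group is empty.
#' @export
burdenTest <- function(carrier, group1, strata, nIter = 10000, seed = 1L,
                       design = c("case_control", "type_vs_rest",
                                  "type_vs_rest_ai_only",
                                  "type_vs_rest_loo")) {
  design <- match.arg(design)
  st <- if (is(strata, "StratumAssignment")) strataLabels(strata) else strata
  stopifnot(length(carrier) == length(group1), length(st) == length(group1))
  use <- !is.na(group1) & st != 0L
  res <- .randomizationTest(carrier[use], group1[use], st[use], nIter, seed)
  if (!is.null(res)) attr(res, "design") <- design
  res
}

#' Leave-one-type-out tissue-specificity tests
#'
#' For a focal cancer type, repeats the type-vs-rest burden test once per
#' comparator type, each time excluding that comparator's samples from the
#' "rest". With T types this yields T - 1 results; comparators whose
#' exclusion empties a group are skipped (NULL entry).
#'
#' @param carrier Logical carrier indicator over all samples.
#' @param cancerTypes Character cancer-type label per sample.
#' @param focalType The type of interest.
#' @param strata,nIter,seed As in [burdenTest()].
#' @return Named list (one entry per excluded comparator type) of
#'   [RandomizationResult-class] or NULL.
#' @export
looTypeSpecificity <- function(carrier, cancerTypes, focalType, strata,
                               nIter = 10000, seed = 1L) {
  st <- if (is(strata, "StratumAssignment")) strataLabels(strata) else strata
  types <- sort(unique(cancerTypes[!is.na(cancerTypes)]))
  stopifnot(focalType %in% types, length(types) >= 3L)
  others <- setdiff(types, focalType)
  out <- vector("list", length(others))
  names(out) <- others
  for (ex in others) {
    keep <- !is.na(cancerTypes) & cancerTypes != ex
    out[[ex]] <- burdenTest(carrier[keep], cancerTypes[keep] == focalType,
                            st[keep], nIter = nIter,
                            seed = substreamSeed(seed, paste0("loo_", ex)),
                            design = "type_vs_rest_loo")
  }
  out
}

#' Cumulative carrier-excess curve over an ordered gene list
#'
#' Adds genes sequentially (most significant first when the order comes
#' from gene-test P-values; ties broken by gene id by the caller), treats
#' each prefix as a pooled set (OR-reduction of the carrier indicators),
#' and runs the case-vs-control burden test per prefix. All prefixes share
#' one permutation stream seed (common random numbers keep the curve
#' smooth and make the single-gene prefix identical to [burdenTest()] on
#' that gene with the same seed). The maximum excess over prefixes is
#' reported with its CI; the full curve is returned so the maximum is
#' auditable (maximizing over prefixes inflates the estimate).
#'
#' @param carrierMatrix Logical genes x samples matrix (rownames = gene
#'   ids) over the combined case/control universe.
#' @param geneOrder Character vector ordering (a subset of) the rows.
#' @param group1 Logical: case sample.
#' @param strata,nIter,seed As in [burdenTest()].
#' @return list with \code{curve} (data.frame: prefix size, gene added,
#'   excess, ci_low, ci_high, empirical_p), \code{max_excess},
#'   \code{max_ci}, \code{argmax_prefix}.
#' @export
contributionCurve <- function(carrierMatrix, geneOrder, group1, strata,
                              nIter = 10000, seed = 1L) {
  stopifnot(all(geneOrder %in% rownames(carrierMatrix)))
  cum <- rep(FALSE, ncol(carrierMatrix))
  rows <- vector("list", length(geneOrder))
  for (i in seq_along(geneOrder)) {
    cum <- cum | carrierMatrix[geneOrder[i], ]
    r <- burdenTest(cum, group1, strata, nIter = nIter, seed = seed,
                    design = "case_control")
    rows[[i]] <- data.frame(
      prefix = i, gene_added = geneOrder[i],
      excess = if (is.null(r)) NA_real_ else r@effectSize,
      ci_low = if (is.null(r)) NA_real_ else r@ciLow,
      ci_high = if (is.null(r)) NA_real_ else r@ciHigh,
      empirical_p = if (is.null(r)) NA_real_ else r@empiricalP,
      stringsAsFactors = FALSE)
  }
  curve <- do.call(rbind, rows)
  amax <- which.max(curve$excess)
  list(curve = curve,
       max_excess = curve$excess[amax],
       max_ci = c(curve$ci_low[amax], curve$ci_high[amax]),
       argmax_prefix = curve$prefix[amax])
}

#' Seeded random gene sets for contribution-curve baselines
#'
#' Draws \code{nSets} random gene sets of a given size (without
#' replacement within each set) from a gene universe, for the random-order
#' baseline curves.
#'
#' @param geneUniverse Character vector to draw from.
#' @param size Genes per set.
#' @param nSets Number of sets (default 5).
#' @param seed Integer seed.
#' @return list of character vectors.
#' @export
randomGeneSets <- function(geneUniverse, size, nSets = 5, seed = 1L) {
  stopifnot(size <= length(geneUniverse))
  lapply(seq_len(nSets), function(i) {
    set.seed(substreamSeed(seed, paste0("random_set_", i)))
    sample(geneUniverse, size)
  })
}
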