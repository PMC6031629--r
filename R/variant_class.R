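# Classification of rare damaging germline variants (RDGVs) and rare
# protein-truncating variants (PTVs), with cohort-level recurrence and
# reference-database QC filters.

#' Is a variant rare?
#'
#' Rare means a reference-database minor allele frequency strictly below
#' \code{threshold} globally \emph{and} in every subpopulation. Missing
#' subpopulation frequencies are treated as 0 (absent = rare within that
#' subpopulation); a missing global frequency is treated as 0 for variants
#' present in the reference database (absence from the database is handled
#' by the separate presence filter, not here).
#'
#' @param variants Variant observation data.frame.
#' @param threshold MAF threshold (default 0.001, i.e. 0.1\%; strict
#'   inequality).
#' @return Logical vector.
#' @export
isRareVariant <- function(variants, threshold = 0.001) {
  mafs <- as.matrix(variants[, c("maf_global", paste0("maf_", .SUBPOPS)),
                             drop = FALSE])
  mafs[is.na(mafs)] <- 0
  rowSums(mafs >= threshold) == 0L
}

#' Is a variant damaging?
#'
#' Damaging classes are splice, frameshift indel, nonsense, and missense
#' predicted deleterious by the consensus predictor; everything else
#' (synonymous, in-frame indels, tolerated or unscored missense) is not.
#'
#' @param variants Variant observation data.frame.
#' @return Logical vector.
#' @export
isDamagingVariant <- function(variants) {
  cls <- variants$functional_class
  cls %in% c("splice", "frameshift_indel", "nonsense") |
    (cls %in% "missense" &
       variants$deleterious_call %in% "deleterious")
}

#' Is a variant protein-truncating?
#'
#' PTVs are splice, frameshift indel and nonsense variants; deleterious
#' missense is excluded, so PTV mode always selects a subset of RDGV mode.
#'
#' @param variants Variant observation data.frame.
#' @return Logical vector.
#' @export
isPTV <- function(variants) {
  variants$functional_class %in% c("splice", "frameshift_indel", "nonsense")
}

#' Classify qualifying rare damaging (or truncating) germline variants
#'
#' Applies, per observation: the rarity filter, the damaging (or, in PTV
#' mode, truncating) class filter, reference-database presence and QC
#' flags, the multi-nucleotide exclusion, and finally the cohort-level
#' recurrence filter: a genomic position fails when the fraction of cohort
#' samples carrying any candidate variant at that position exceeds
#' \code{recurrenceMax} (strictly; a position carried by exactly the
#' threshold fraction is retained). Position means (chrom, pos), ignoring
#' the alternate allele.
#'
#' @param variants Variant observation data.frame for the whole cohort.
#' @param mode \code{"rdgv"} (rare damaging, the default) or \code{"ptv"}
#'   (rare protein-truncating only).
#' @param mafThreshold Rarity threshold (default 0.001).
#' @param recurrenceMax Maximum carrier fraction per position
#'   (default 0.01).
#' @param nSamples Cohort size for the recurrence denominator; defaults to
#'   the number of distinct samples in \code{variants}.
#' @return data.frame with one row per observation: \code{sample_id},
#'   \code{variant_id}, \code{is_rare}, \code{is_damaging}, \code{is_ptv},
#'   \code{passes_recurrence} and the final \code{is_rdgv} flag
#'   (qualifying variant under the selected mode).
#' @export
classifyRDGV <- function(variants, mode = c("rdgv", "ptv"),
                         mafThreshold = 0.001, recurrenceMax = 0.01,
                         nSamples = NULL) {
  mode <- match.arg(mode)
  .checkVariantTable(variants)
  nSamples <- nSamples %||% length(unique(variants$sample_id))
  rare <- isRareVariant(variants, mafThreshold)
  damaging <- isDamagingVariant(variants)
  ptv <- isPTV(variants)
  classOk <- if (mode == "ptv") ptv else damaging
  dbOk <- variants$in_reference_db %in% TRUE &
    variants$passes_db_qc %in% TRUE &
    !(variants$is_multinucleotide %in% TRUE)
  candidate <- rare & classOk & dbOk

  posKey <- paste(variants$chrom, variants$pos, sep = ":")
  passRec <- rep(TRUE, nrow(variants))
  if (any(candidate)) {
    carriers <- tapply(variants$sample_id[candidate], posKey[candidate],
                       function(s) length(unique(s)))
    badPos <- names(carriers)[carriers / nSamples > recurrenceMax]
    passRec <- !(posKey %in% badPos)
  }
  data.frame(
    sample_id = variants$sample_id,
    variant_id = variants$variant_id,
    is_rare = rare,
    is_damaging = damaging,
    is_ptv = ptv,
    passes_recurrence = passRec,
    is_rdgv = candidate & passRec,
    stringsAsFactors = FALSE)
}
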