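# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a deterministic substream seed from a master seed and a key
#'
#' Randomized operations (per-gene permutation nulls, simulator streams,
#' clustering restarts) each draw their RNG seed from the master seed and a
#' string key, so results are independent of evaluation order and of how
#' work is split across genes.
#'
#' @param master Integer master seed.
#' @param key Character scalar naming the substream (e.g. a gene id).
#' @return An integer seed in \[0, 2^31 - 2\].
#' @export
#' @examples
#' substreamSeed(1L, "BRCA1")
substreamSeed <- function(master, key) {
  stopifnot(length(master) == 1L, is.finite(master), length(key) == 1L)
  h <- 0
  for (c in utf8ToInt(as.character(key))) {
    h <- (h * 31 + c) %% 2147483647
  }
  # mix in the master seed with a Lehmer-style multiplier; all intermediate
  # products stay below 2^53 so double arithmetic is exact
  as.integer((h * 48271 + (abs(master) %% 2147483647)) %% 2147483647)
}

.assertProb <- function(x, name = deparse(substitute(x)), openLeft = FALSE) {
  bad <- !is.na(x) & (x > 1 | (if (openLeft) x <= 0 else x < 0))
  if (any(bad)) {
    stop(sprintf("%s must lie in %s0,1]", name, if (openLeft) "(" else "["),
         call. = FALSE)
  }
  invisible(x)
}

# Required columns of the tab-separated variant dialect. The simulator
# writes exactly this header and readVariantTable() checks it, so the two
# sides are bit-compatible.
.SUBPOPS <- c("afr", "amr", "eas", "fin", "nfe", "sas")

.VARIANT_COLUMNS <- c(
  "sample_id", "variant_id", "chrom", "pos", "ref_allele", "alt_allele",
  "functional_class", "normal_ref_reads", "normal_alt_reads",
  "tumor_ref_reads", "tumor_alt_reads", "normal_genotype", "maf_global",
  paste0("maf_", .SUBPOPS),
  "deleterious_call", "in_reference_db", "passes_db_qc", "is_multinucleotide")

.FUNCTIONAL_CLASSES <- c("synonymous", "missense", "nonsense",
                         "frameshift_indel", "inframe_indel", "splice")

.checkVariantTable <- function(variants) {
  miss <- setdiff(.VARIANT_COLUMNS, names(variants))
  if (length(miss)) {
    stop("variant table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(variants$functional_class),
                 c(.FUNCTIONAL_CLASSES, NA))
  if (length(bad)) {
    stop("unknown functional_class value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(variants)
}
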