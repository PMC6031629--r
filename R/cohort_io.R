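# Cohort I/O: variant tables (TSV dialect and paired VCF), BED gene
# regions and coverage masks, sample metadata, and construction of the
# gene x sample indicator matrices.

#' Read a germline variant table
#'
#' Two dialects are supported. The \code{"tsv"} dialect is the package's
#' fixed-header tab-separated format (one row per sample x variant, columns
#' named after the variant-observation fields; the simulator writes exactly
#' this format, so write/read round-trips are exact). The
#' \code{"vcf_paired"} dialect is a VCF 4.x file with two genotype columns
#' (normal first, tumor second) carrying per-sample \code{AD} allele
#' depths; multi-allelic records are split into one observation per
#' alternate allele, and records without allele depths are skipped with a
#' warning. VCF input carries no annotations; merge them afterwards with
#' [annotateVariants()].
#'
#' @param path File to read.
#' @param dialect Either \code{"tsv"} or \code{"vcf_paired"}.
#' @param sampleId Sample identifier for VCF input; defaults to the name of
#'   the first (normal) genotype column.
#' @return A data.frame with one row per (sample, variant) observation and
#'   the columns listed in the TSV dialect.
#' @export
readVariantTable <- function(path, dialect = c("tsv", "vcf_paired"),
                             sampleId = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    if (file.exists(path) && file.size(path) == 0) {
      return(.emptyVariantTable())
    }
    dt <- data.table::fread(path, sep = "\t", header = TRUE,
                            colClasses = list(character = "chrom"))
    if (nrow(dt) == 0L && ncol(dt) == 0L) {
      return(.emptyVariantTable())
    }
    df <- as.data.frame(dt)
    .checkVariantTable(df)
    df$chrom <- as.character(df$chrom)
    return(df)
  }
  .readPairedVcf(path, sampleId)
}

.emptyVariantTable <- function() {
  df <- as.data.frame(
    stats::setNames(rep(list(character(0)), length(.VARIANT_COLUMNS)),
                    .VARIANT_COLUMNS))
  num <- c("pos", "normal_ref_reads", "normal_alt_reads", "tumor_ref_reads",
           "tumor_alt_reads", "maf_global", paste0("maf_", .SUBPOPS))
  for (cl in num) df[[cl]] <- numeric(0)
  for (cl in c("in_reference_db", "passes_db_qc", "is_multinucleotide")) {
    df[[cl]] <- logical(0)
  }
  df
}

.readPairedVcf <- function(path, sampleId = NULL) {
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  if (ncol(vcf) < 2L) {
    stop("paired VCF must have two genotype columns (normal, tumor)",
         call. = FALSE)
  }
  if (nrow(vcf) == 0L) return(.emptyVariantTable())
  sampleId <- sampleId %||% colnames(vcf)[1L]
  ad <- VariantAnnotation::geno(vcf)$AD
  gt <- tryCatch(VariantAnnotation::geno(vcf)$GT, error = function(e) NULL)
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  altL <- rr$ALT
  nAlt <- S4Vectors::elementNROWS(altL)
  altAll <- as.character(unlist(altL))
  rows <- list()
  skipped <- 0L
  k <- 0L
  for (i in seq_len(nrow(vcf))) {
    adN <- ad[[i, 1L]]
    adT <- ad[[i, 2L]]
    if (is.null(adN) || is.null(adT) || anyNA(adN) || anyNA(adT) ||
        length(adN) < 2L || length(adT) < 2L) {
      skipped <- skipped + 1L
      next
    }
    gti <- if (!is.null(gt)) gt[i, 1L] else NA_character_
    geno <- if (is.na(gti)) "het"
            else if (gti %in% c("1/1", "1|1")) "hom_alt" else "het"
    for (a in seq_len(nAlt[i])) {
      k <- k + 1L
      alt <- altAll[sum(nAlt[seq_len(i - 1L)]) + a]
      rows[[k]] <- data.frame(
        sample_id = sampleId,
        variant_id = sprintf("%s:%d:%s:%s",
                             as.character(GenomicRanges::seqnames(rr)[i]),
                             GenomicRanges::start(rr)[i], ref[i], alt),
        chrom = as.character(GenomicRanges::seqnames(rr)[i]),
        pos = GenomicRanges::start(rr)[i],
        ref_allele = ref[i], alt_allele = alt,
        functional_class = NA_character_,
        normal_ref_reads = adN[1L], normal_alt_reads = adN[1L + a],
        tumor_ref_reads = adT[1L], tumor_alt_reads = adT[1L + a],
        normal_genotype = geno,
        stringsAsFactors = FALSE)
    }
  }
  if (skipped > 0L) {
    warning(sprintf("%d VCF record(s) without usable allele depths skipped",
                    skipped), call. = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else .emptyVariantTable()
  for (cl in setdiff(.VARIANT_COLUMNS, names(out))) {
    out[[cl]] <- if (cl %in% c("in_reference_db", "passes_db_qc",
                               "is_multinucleotide")) NA else NA_real_
  }
  out[, .VARIANT_COLUMNS]
}

#' Write a variant table in the TSV dialect
#'
#' @param variants Variant observation data.frame.
#' @param path Output file.
#' @return Invisibly, \code{path}.
#' @export
writeVariantTable <- function(variants, path) {
  .checkVariantTable(variants)
  data.table::fwrite(variants[, .VARIANT_COLUMNS], path, sep = "\t",
                     quote = FALSE, na = "NA")
  invisible(path)
}

#' Merge external variant annotations into a variant table
#'
#' Annotations (functional class, deleteriousness call, reference-database
#' allele frequencies and QC flags) are consumed, never computed. The
#' annotation table is keyed by \code{variant_id}; its columns overwrite
#' any same-named columns already present.
#'
#' @param variants Variant observation data.frame.
#' @param annotations data.frame with a \code{variant_id} column plus any
#'   of the annotation columns of the TSV dialect.
#' @return The annotated variant data.frame.
#' @export
annotateVariants <- function(variants, annotations) {
  stopifnot("variant_id" %in% names(annotations))
  keep <- intersect(names(annotations), .VARIANT_COLUMNS)
  keep <- setdiff(keep, c("sample_id"))
  idx <- match(variants$variant_id, annotations$variant_id)
  for (cl in setdiff(keep, "variant_id")) {
    variants[[cl]] <- annotations[[cl]][idx]
  }
  variants
}

#' Read gene regions or a coverage mask from BED
#'
#' Thin wrappers over \code{rtracklayer::import} (BED's 0-based half-open
#' coordinates are converted to the 1-based closed convention used
#' internally by GRanges).
#'
#' @param path BED file.
#' @return A \code{GRanges}; for gene regions, names are taken from the BED
#'   name column.
#' @export
readGeneRegions <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (!is.null(gr$name)) names(gr) <- gr$name
  gr
}

#' @rdname readGeneRegions
#' @export
readBedMask <- function(path) {
  rtracklayer::import(path, format = "BED")
}

#' Read sample metadata
#'
#' Tab-separated with header; expected columns \code{sample_id},
#' \code{group} (case/control), \code{cancer_type}, \code{batch}.
#'
#' @param path TSV file.
#' @return data.frame of sample metadata.
#' @export
readSampleMeta <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  stopifnot(all(c("sample_id", "group") %in% names(df)))
  df
}

#' Restrict variants to the intersection of coverage masks
#'
#' Each mask is a set of genomic intervals with adequate sequencing
#' coverage (e.g. one per sequencing center); only variants whose position
#' lies in the intersection of all masks are retained. Supplying no masks
#' is the identity. Intersection is commutative and idempotent.
#'
#' @param variants Variant observation data.frame.
#' @param masks A list of \code{GRanges} (or a \code{GRangesList}).
#' @return The filtered variant data.frame.
#' @export
applyCoverageMask <- function(variants, masks) {
  if (length(masks) == 0L) return(variants)
  masks <- as.list(masks)
  inter <- Reduce(function(a, b) {
    GenomicRanges::intersect(a, b, ignore.strand = TRUE)
  }, masks)
  if (length(inter) == 0L) {
    warning("coverage mask intersection is empty; all variants removed",
            call. = FALSE)
    return(variants[0L, , drop = FALSE])
  }
  if (nrow(variants) == 0L) return(variants)
  vgr <- GenomicRanges::GRanges(variants$chrom,
                                IRanges::IRanges(variants$pos, width = 1L))
  hit <- IRanges::overlapsAny(vgr, inter, ignore.strand = TRUE)
  variants[hit, , drop = FALSE]
}

#' Drop samples with the fewest called nonsynonymous variants
#'
#' Ranks samples by their number of distinct nonsynonymous variants
#' (everything except synonymous class) and removes the lowest
#' \code{floor(fraction * N)}. Ties at the cutoff are broken by sample id
#' (lexicographic), so the result is deterministic.
#'
#' @param variants Variant observation data.frame.
#' @param sampleIds Optional full sample universe (samples with zero
#'   variants would otherwise be invisible); defaults to samples present in
#'   \code{variants}.
#' @param fraction Fraction of samples to drop (default 0.02, i.e. the
#'   bottom 2\%).
#' @return Character vector of retained sample ids.
#' @export
filterLowVariantSamples <- function(variants, fraction = 0.02,
                                    sampleIds = NULL) {
  stopifnot(fraction >= 0, fraction < 1)
  sampleIds <- sort(unique(sampleIds %||% variants$sample_id))
  nonsyn <- variants[!is.na(variants$functional_class) &
                       variants$functional_class != "synonymous", ]
  cnt <- tapply(nonsyn$variant_id, nonsyn$sample_id,
                function(v) length(unique(v)))
  counts <- stats::setNames(rep(0L, length(sampleIds)), sampleIds)
  counts[names(cnt)] <- as.integer(cnt)
  nDrop <- floor(fraction * length(sampleIds))
  if (nDrop == 0L) return(sampleIds)
  ord <- order(counts, names(counts))
  sort(names(counts)[ord][-seq_len(nDrop)])
}

#' Build the gene x sample indicator matrices
#'
#' Combines per-gene allelic-imbalance calls, RDGV classifications and gene
#' bodies into a [TwoHitCohort-class]. A sample is an RDGV carrier for a
#' gene iff it carries at least one qualifying variant inside the gene body
#' (window variants outside the gene count only towards AI, never towards
#' carrier status); it has a two-hit event iff at least one such RDGV's
#' tumor VAF exceeds its normal VAF by \code{vafIncreaseThreshold}. AI
#' status is NA where the sample had no informative heterozygous variant in
#' the gene window.
#'
#' @param variants Variant observation data.frame.
#' @param aiCalls data.frame from [callCohortAI()] with columns
#'   \code{sample_id}, \code{gene_id}, \code{pooled_p}, \code{ai_flag},
#'   \code{n_variants_used}.
#' @param rdgvFlags data.frame from [classifyRDGV()].
#' @param genes \code{GRanges} of gene bodies, named by gene id.
#' @param sampleMeta Optional sample metadata data.frame (defines the
#'   sample universe and column order).
#' @param vafIncreaseThreshold Minimum tumor-minus-normal VAF increase for
#'   a two-hit event (default 0.10).
#' @return A [TwoHitCohort-class].
#' @export
buildCohortMatrices <- function(variants, aiCalls, rdgvFlags, genes,
                                sampleMeta = NULL,
                                vafIncreaseThreshold = 0.10) {
  geneIds <- names(genes)
  if (is.null(geneIds)) stop("genes must be named by gene id")
  if (!all(aiCalls$gene_id %in% geneIds)) {
    stop("aiCalls contain gene ids absent from 'genes'")
  }
  samples <- if (!is.null(sampleMeta)) sampleMeta$sample_id else
    sort(unique(c(variants$sample_id, aiCalls$sample_id)))
  nG <- length(geneIds); nS <- length(samples)

  ai <- matrix(NA_integer_, nG, nS, dimnames = list(geneIds, samples))
  ok <- aiCalls$sample_id %in% samples
  ii <- cbind(match(aiCalls$gene_id[ok], geneIds),
              match(aiCalls$sample_id[ok], samples))
  ai[ii] <- ifelse(aiCalls$ai_flag[ok] == "AI", 1L,
                   ifelse(aiCalls$ai_flag[ok] == "no_AI", 0L, NA_integer_))

  carrier <- matrix(FALSE, nG, nS, dimnames = list(geneIds, samples))
  twohit <- matrix(FALSE, nG, nS, dimnames = list(geneIds, samples))
  fl <- rdgvFlags[rdgvFlags$is_rdgv, , drop = FALSE]
  rdKey <- paste(variants$sample_id, variants$variant_id)
  rd <- variants[rdKey %in% paste(fl$sample_id, fl$variant_id), ,
                 drop = FALSE]
  if (nrow(rd)) {
    vgr <- GenomicRanges::GRanges(rd$chrom,
                                  IRanges::IRanges(rd$pos, width = 1L))
    hits <- GenomicRanges::findOverlaps(vgr, genes, ignore.strand = TRUE)
    if (length(hits)) {
      qi <- S4Vectors::queryHits(hits)
      gi <- S4Vectors::subjectHits(hits)
      si <- match(rd$sample_id[qi], samples)
      keep <- !is.na(si)
      carrier[cbind(gi[keep], si[keep])] <- TRUE
      vafN <- rd$normal_alt_reads / (rd$normal_alt_reads + rd$normal_ref_reads)
      vafT <- rd$tumor_alt_reads / (rd$tumor_alt_reads + rd$tumor_ref_reads)
      up <- (vafT - vafN)[qi] >= vafIncreaseThreshold
      keep2 <- keep & !is.na(up) & up
      twohit[cbind(gi[keep2], si[keep2])] <- TRUE
    }
  }

  cd <- if (!is.null(sampleMeta)) {
    S4Vectors::DataFrame(sampleMeta, row.names = sampleMeta$sample_id)
  } else {
    S4Vectors::DataFrame(sample_id = samples, row.names = samples)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(rdgvCarrier = carrier, aiStatus = ai, twoHitEvent = twohit),
    rowRanges = genes, colData = cd)
  methods::new("TwoHitCohort", se)
}
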