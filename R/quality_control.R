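#' Sample-level sequencing QC
#'
#' A tumor/normal WES pair passes when mean tumor coverage is at least
#' 60x, mean normal coverage at least 20x, and the tumor-normal SNP
#' genotype correlation at least 0.8 (lower values indicate possible
#' sample confusion). Missing metrics fail with reason `missing_<metric>`.
#'
#' @param metrics data.frame with `sample_id`, `tumor_coverage`,
#'   `normal_coverage`, `snp_correlation`
#' @param min_tumor,min_normal,min_correlation QC thresholds
#' @return the input with `passed` flag and semicolon-joined `reasons`
#' @export
sample_qc <- function(metrics, min_tumor = 60, min_normal = 20,
                      min_correlation = 0.8) {
  fail <- function(value, ok, reason) {
    ifelse(is.na(value), paste0("missing_", reason),
           ifelse(ok, NA_character_, reason))
  }
  r1 <- fail(metrics$tumor_coverage, metrics$tumor_coverage >= min_tumor,
             "tumor_coverage")
  r2 <- fail(metrics$normal_coverage, metrics$normal_coverage >= min_normal,
             "normal_coverage")
  r3 <- fail(metrics$snp_correlation, metrics$snp_correlation >= min_correlation,
             "snp_correlation")
  reasons <- apply(cbind(r1, r2, r3), 1L, function(r) {
    paste(r[!is.na(r)], collapse = ";")
  })
  metrics$passed <- !nzchar(reasons)
  metrics$reasons <- reasons
  metrics
}

#' Somatic variant QC filter
#'
#' Keeps variants with tumor depth > 20, normal depth > 20, tumor VAF >=
#' 0.05, normal VAF < 0.17 x tumor VAF, and at least 3 supporting reads.
#' Removed variants carry the first rule they failed, in that order.
#'
#' @param variants data.frame of somatic variants
#' @return list with `kept` and `removed` (the latter with a `reason` column)
#' @export
filter_variants <- function(variants) {
  if (nrow(variants) == 0) {
    removed <- variants
    removed$reason <- character(0)
    return(list(kept = variants, removed = removed))
  }
  reason <- rep(NA_character_, nrow(variants))
  rule <- function(ok, label) {
    reason <<- ifelse(is.na(reason) & !ok, label, reason)
  }
  rule(variants$tumor_depth > 20, "tumor_depth")
  rule(variants$normal_depth > 20, "normal_depth")
  rule(variants$tumor_vaf >= 0.05, "vaf")
  rule(variants$normal_vaf < 0.17 * variants$tumor_vaf, "normal_vaf")
  rule(variants$alt_reads >= 3, "alt_reads")
  kept <- variants[is.na(reason), , drop = FALSE]
  removed <- variants[!is.na(reason), , drop = FALSE]
  removed$reason <- reason[!is.na(reason)]
  rownames(kept) <- rownames(removed) <- NULL
  list(kept = kept, removed = removed)
}

#' CNV segment QC filter
#'
#' Discards segments whose caller log-likelihood is below 100.
#' @param segments data.frame of CNV segments with a `loglik` column
#' @return the retained segments
#' @export
filter_cnvs <- function(segments) {
  out <- segments[segments$loglik >= 100, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep one sample per patient
#'
#' When several sequenced samples of the same tumor exist, the one with
#' the lexicographically greatest accession string is retained.
#'
#' @param samples data.frame with at least `patient_id` and `accession`
#' @return the deduplicated data.frame
#' @export
dedupe_patient_samples <- function(samples) {
  ord <- order(samples$patient_id, samples$accession, decreasing = c(FALSE, TRUE),
               method = "radix")
  sorted <- samples[ord, , drop = FALSE]
  out <- sorted[!duplicated(sorted$patient_id), , drop = FALSE]
  out[order(match(out$accession, samples$accession)), , drop = FALSE]
}

#' Construct a sub-cohort target region
#'
#' A base enters the target region when it is covered (>= 20x upstream)
#' in at least half of the samples' coverage tracks — implemented as a
#' count of at least `ceiling(n/2)` — and lies within the exon
#' coordinates padded by `pad` bases on each side.
#'
#' @param tracks list of per-sample covered interval sets (`GRanges`)
#' @param exons exon interval set
#' @param pad exon padding in bases (default 2)
#' @return merged, sorted `GRanges`
#' @export
build_target_region <- function(tracks, exons, pad = 2L) {
  if (length(tracks) == 0) stop("at least one coverage track required")
  if (is.null(exons) || length(exons) == 0) stop("exon set must be non-empty")
  majority <- coverage_at_least(tracks, lower = ceiling(length(tracks) / 2))
  interval_intersect(majority, pad_intervals(exons, pad))
}

#' Intersect sub-cohort target regions
#'
#' The meta-cohort target region keeps only bases present in every
#' sub-cohort's target, avoiding coverage-driven batch effects in the
#' per-megabase burden metrics.
#'
#' @param regions list of interval sets
#' @return `GRanges` of the common bases (possibly empty)
#' @export
intersect_cohort_regions <- function(regions) {
  if (length(regions) == 0) stop("no regions supplied")
  out <- Reduce(interval_intersect, regions)
  if (interval_size(out) == 0) {
    message("intersection of cohort target regions is empty")
  }
  out
}

#' Batch-correct a TPM expression matrix
#'
#' Applies the parametric empirical-Bayes location/scale adjustment
#' (ComBat model, via \pkg{sva}) on the log2(TPM + 1) scale, then
#' back-transforms and clamps at zero. Genes without variance are passed
#' through unchanged. A single batch returns the input untouched.
#'
#' @param expr numeric matrix of TPM, genes x samples
#' @param batches batch label per sample, aligned with `colnames(expr)`
#' @return corrected TPM matrix of the same shape
#' @export
correct_batch <- function(expr, batches) {
  if (length(batches) != ncol(expr)) {
    stop("one batch label per sample required")
  }
  batches <- as.character(batches)
  if (length(unique(batches)) < 2) return(expr)
  sizes <- table(batches)
  if (any(sizes < 2)) {
    stop("batch with a single sample: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  logx <- log2(expr + 1)
  v <- apply(logx, 1L, stats::var)
  usable <- v > 0
  adj <- logx
  if (any(usable)) {
    dat <- logx[usable, , drop = FALSE]
    corrected <- tryCatch(
      suppressMessages(sva::ComBat(dat = dat, batch = batches,
                                   par.prior = TRUE, prior.plots = FALSE)),
      error = function(e) {
        # degenerate scale priors (e.g. identical per-gene dispersions)
        # break the location/scale iteration; fall back to location-only
        message("location/scale fit degenerate; using location-only ComBat")
        suppressMessages(sva::ComBat(dat = dat, batch = batches,
                                     par.prior = TRUE, prior.plots = FALSE,
                                     mean.only = TRUE))
      })
    adj[usable, ] <- corrected
  }
  out <- pmax(2^adj - 1, 0)
  dimnames(out) <- dimnames(expr)
  out
}
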