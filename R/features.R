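#' Run the full feature layer of a cohort
#'
#' Applies sample-, variant- and CNV-level QC, constructs the
#' meta-cohort target region (per-sub-cohort majority-coverage regions
#' intersected across sub-cohorts; the plain exon set when no coverage
#' tracks are available), batch-corrects expression across sub-cohorts,
#' and computes the genomic and transcriptomic biomarker matrices.
#'
#' @param cohort an `ici_cohort`
#' @param fixtures shipped fixtures from [ici_fixtures()]
#' @param correct_batches batch-correct expression before RNA features
#'   (disable only for diagnostics)
#' @return an `ici_features` list: `dna` and `rna` matrices (samples x
#'   features), updated `samples` sheet, `target`, `target_mb`, `nstmb`
#'   vector, QC tables and exclusion log
#' @export
prepare_cohort_features <- function(cohort, fixtures = ici_fixtures(),
                                    correct_batches = TRUE) {
  samples <- cohort$samples
  empty_df <- function(...) {
    cols <- c(...)
    stats::setNames(data.frame(matrix(nrow = 0, ncol = length(cols))), cols)
  }
  if (is.null(cohort$variants)) {
    cohort$variants <- empty_df(VARIANT_COLUMNS)
  }
  if (is.null(cohort$cnvs)) {
    cohort$cnvs <- empty_df("sample_id", "chrom", "start", "end",
                            "copy_number", "loglik")
  }
  if (is.null(cohort$neoantigens)) {
    cohort$neoantigens <- empty_df("sample_id", "mut_peptide", "wt_peptide",
                                   "mut_affinity_nM", "wt_affinity_nM",
                                   "recognition_potential", "hex_score",
                                   "dissimilarity")
  }
  if (is.null(cohort$clonotypes)) {
    cohort$clonotypes <- empty_df("sample_id", "chain", "clonotype_id",
                                  "read_count")
  }
  if (is.null(cohort$fusions)) {
    cohort$fusions <- empty_df("sample_id", "gene5", "gene3", "frame")
  }
  excluded <- data.frame(sample_id = character(), stage = character(),
                         reason = character(), stringsAsFactors = FALSE)

  qc <- NULL
  if (!is.null(cohort$qc_metrics)) {
    qc <- sample_qc(cohort$qc_metrics)
    failed <- qc$sample_id[!qc$passed]
    if (length(failed)) {
      excluded <- rbind(excluded, data.frame(
        sample_id = failed, stage = "sample_qc",
        reason = qc$reasons[!qc$passed], stringsAsFactors = FALSE))
      samples$has_wes[samples$sample_id %in% failed] <- FALSE
    }
  }

  vres <- filter_variants(cohort$variants)
  variants <- vres$kept
  segments <- filter_cnvs(cohort$cnvs)

  if (length(cohort$coverage)) {
    wes_ids <- samples$sample_id[samples$has_wes]
    tracks <- cohort$coverage[intersect(names(cohort$coverage), wes_ids)]
    groups <- split(names(tracks),
                    samples$sub_cohort[match(names(tracks), samples$sample_id)])
    sub_targets <- lapply(groups, function(members) {
      build_target_region(tracks[members], cohort$exons)
    })
    target <- intersect_cohort_regions(sub_targets)
  } else {
    if (is.null(cohort$exons)) stop("no coverage tracks and no exon set")
    target <- cohort$exons
  }
  tt <- target_table(target)
  target_mb <- attr(tt, "size") / 1e6

  wes_ids <- samples$sample_id[samples$has_wes]
  dna <- NULL
  if (length(wes_ids)) {
    var_by <- split(variants, variants$sample_id)
    seg_by <- split(segments, segments$sample_id)
    neo_by <- split(cohort$neoantigens, cohort$neoantigens$sample_id)
    hla_by <- split(cohort$hla_genotypes, cohort$hla_genotypes$sample_id)
    empty <- function(df) df[0, , drop = FALSE]
    dna <- t(vapply(wes_ids, function(s) {
      compute_dna_features(
        variants = if (is.null(var_by[[s]])) empty(variants) else var_by[[s]],
        segments = if (is.null(seg_by[[s]])) empty(segments) else seg_by[[s]],
        neoantigens = if (is.null(neo_by[[s]])) empty(cohort$neoantigens) else neo_by[[s]],
        hla_genotype = hla_by[[s]],
        hla_sequences = cohort$hla_sequences,
        tumor_purity = samples$tumor_purity[samples$sample_id == s],
        target = tt, fixtures = fixtures)
    }, stats::setNames(numeric(length(dna_feature_names())),
                       dna_feature_names())))
  }

  rna_ids <- samples$sample_id[samples$has_rna]
  rna <- NULL
  expr <- cohort$expression
  if (length(rna_ids) && !is.null(expr)) {
    rna_ids <- intersect(rna_ids, colnames(expr))
    if (correct_batches) {
      batches <- samples$sub_cohort[match(colnames(expr), samples$sample_id)]
      expr <- correct_batch(expr, batches)
    }
    clono <- cohort$clonotypes
    fus <- cohort$fusions
    cl_by <- split(clono, clono$sample_id)
    fu_by <- split(fus, fus$sample_id)
    empty_cl <- clono[0, , drop = FALSE]
    empty_fu <- fus[0, , drop = FALSE]
    rna <- suppressWarnings(t(vapply(rna_ids, function(s) {
      compute_rna_features(
        expr = expr,
        clonotypes = if (is.null(cl_by[[s]])) empty_cl else cl_by[[s]],
        fusions = if (is.null(fu_by[[s]])) empty_fu else fu_by[[s]],
        sample_id = s, sigs = fixtures$signatures)
    }, stats::setNames(numeric(length(rna_feature_names())),
                       rna_feature_names()))))
  }

  nstmb <- stats::setNames(rep(NA_real_, nrow(samples)), samples$sample_id)
  if (!is.null(dna)) nstmb[rownames(dna)] <- dna[, "ns_tmb"]

  structure(list(dna = dna, rna = rna, samples = samples, target = target,
                 target_mb = target_mb, nstmb = nstmb, sample_qc = qc,
                 removed_variants = vres$removed, excluded = excluded),
            class = "ici_features")
}

#' Write a feature matrix as TSV
#' @param X samples x features matrix
#' @param path output path
#' @export
write_feature_matrix <- function(X, path) {
  df <- data.frame(sample_id = rownames(X),
                   signif(X, 10), check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  tab <- read_tsv(path, "sample_id")
  m <- as.matrix(tab[, setdiff(colnames(tab), "sample_id"), drop = FALSE])
  rownames(m) <- tab$sample_id
  m
}
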