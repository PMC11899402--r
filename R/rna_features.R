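#' Shannon entropy of a clonotype repertoire
#'
#' Entropy in nats of the clonotype frequency distribution,
#' \eqn{-\sum_i p_i \ln p_i} with \eqn{p_i} the read-count fractions.
#' Zero or one clonotype gives 0. Natural-log units are a documented
#' choice: the base only rescales a feature that is z-scored downstream.
#'
#' @param counts vector of clonotype read counts (>= 1)
#' @return entropy in nats
#' @export
repertoire_entropy <- function(counts) {
  if (any(counts < 0)) stop("negative clonotype count")
  counts <- counts[counts > 0]
  if (length(counts) <= 1) return(0)
  p <- counts / sum(counts)
  -sum(p * log(p))
}

#' Mean log-expression signature score
#'
#' Mean of log2(TPM + 1) over the listed genes present in the matrix;
#' absent genes are dropped with a message.
#'
#' @param expr TPM matrix, genes x samples
#' @param genes signature gene symbols
#' @param sample sample (column) identifier
#' @return signature score
#' @export
signature_score <- function(expr, genes, sample) {
  present <- intersect(genes, rownames(expr))
  if (length(present) == 0) {
    stop("none of the signature genes present in the expression matrix")
  }
  n_missing <- length(genes) - length(present)
  if (n_missing > 0) {
    message(n_missing, " signature gene(s) absent from the matrix")
  }
  mean(log2(expr[present, sample] + 1))
}

#' Interferon-gamma to immunosuppression signature ratio
#'
#' Ratio of the IFNG signature score to the immunosuppression signature
#' score, each guarded by a small epsilon against zero scores.
#'
#' @param expr TPM matrix
#' @param sigs signature sets from [signature_sets()]
#' @param sample sample identifier
#' @param eps additive guard (default 1e-6)
#' @return positive ratio
#' @export
ifng_ims_ratio <- function(expr, sigs, sample, eps = 1e-6) {
  (signature_score(expr, sigs$ifng_signature, sample) + eps) /
    (signature_score(expr, sigs$immunosuppression_signature, sample) + eps)
}

#' Count of in-frame fusion neoepitope candidates
#' @param fusions fusion calls of one sample
#' @return integer count; calls of unknown frame never count
#' @export
fusion_neoepitope_count <- function(fusions) {
  sum(fusions$frame == "in_frame")
}

#' Names of the transcriptomic biomarkers, in canonical order
#' @return character vector of RNA feature names
#' @export
rna_feature_names <- function() {
  c("lymphocyte_infiltration", "tcr_alpha_entropy", "tcr_beta_entropy",
    "igh_entropy", "ifng_ims_ratio", "fusion_neoepitope_count",
    "gep_hla_class1", "gep_pdl1", "gep_b2m")
}

#' Compute the transcriptomic biomarker vector of one sample
#'
#' Expression must already be batch-corrected; GEP features and signature
#' scores are computed on log2(TPM + 1). A missing clonotype table yields
#' zero entropy for that chain with a warning.
#'
#' @param expr batch-corrected TPM matrix containing the sample
#' @param clonotypes clonotype count rows of the sample (may be empty)
#' @param fusions fusion call rows of the sample (may be empty)
#' @param sample_id the sample identifier
#' @param sigs signature sets from [signature_sets()]
#' @return named numeric vector over [rna_feature_names()]
#' @export
compute_rna_features <- function(expr, clonotypes, fusions, sample_id,
                                 sigs = signature_sets()) {
  if (is.null(expr) || !sample_id %in% colnames(expr)) {
    stop("missing expression data for sample ", sample_id)
  }
  chain_entropy <- function(chain) {
    rows <- clonotypes[clonotypes$chain == chain, , drop = FALSE]
    if (nrow(rows) == 0) {
      warning("no ", chain, " clonotypes for ", sample_id,
              "; entropy set to 0")
      return(0)
    }
    repertoire_entropy(rows$read_count)
  }
  c(lymphocyte_infiltration = signature_score(expr, sigs$lymphocyte_markers,
                                              sample_id),
    tcr_alpha_entropy = chain_entropy("TRA"),
    tcr_beta_entropy = chain_entropy("TRB"),
    igh_entropy = chain_entropy("IGH"),
    ifng_ims_ratio = ifng_ims_ratio(expr, sigs, sample_id),
    fusion_neoepitope_count = fusion_neoepitope_count(fusions),
    gep_hla_class1 = signature_score(expr, sigs$hla_class1_genes, sample_id),
    gep_pdl1 = signature_score(expr, "CD274", sample_id),
    gep_b2m = signature_score(expr, "B2M", sample_id))
}
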