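#' @importFrom utils read.table write.table
NULL

RECIST_CODES <- c("CR", "PR", "SD", "PD", "MR")
RESPONDER_CODES <- c("CR", "PR")

CONSEQUENCE_LEVELS <- c("missense", "synonymous", "stop_gained", "stop_lost",
                        "start_lost", "frameshift", "inframe_indel", "splice",
                        "multi_aa", "other")

#' Consequence term mapping
#'
#' Fixed mapping from Sequence Ontology annotation terms to the coarse
#' consequence classes used by the burden metrics. Notable choices, kept
#' deliberate and visible here rather than buried in logic:
#' * only splice-site terms (`splice_acceptor_variant`,
#'   `splice_donor_variant`) count as `splice`; `splice_region_variant`
#'   maps to `other` and therefore never enters the splice burden;
#' * `protein_altering_variant` and any missense whose protein change
#'   spans more than one residue map to `multi_aa`.
#' Enum values pass through unchanged so written tables round-trip.
#'
#' @return data.frame with columns `term` and `consequence`
#' @export
so_consequence_table <- function() {
  map <- c(
    missense_variant = "missense",
    synonymous_variant = "synonymous",
    stop_retained_variant = "synonymous",
    stop_gained = "stop_gained",
    stop_lost = "stop_lost",
    start_lost = "start_lost",
    frameshift_variant = "frameshift",
    inframe_insertion = "inframe_indel",
    inframe_deletion = "inframe_indel",
    conservative_inframe_insertion = "inframe_indel",
    conservative_inframe_deletion = "inframe_indel",
    disruptive_inframe_insertion = "inframe_indel",
    disruptive_inframe_deletion = "inframe_indel",
    splice_acceptor_variant = "splice",
    splice_donor_variant = "splice",
    splice_region_variant = "other",
    protein_altering_variant = "multi_aa",
    intron_variant = "other",
    intergenic_variant = "other",
    upstream_gene_variant = "other",
    downstream_gene_variant = "other"
  )
  map <- c(map, stats::setNames(CONSEQUENCE_LEVELS, CONSEQUENCE_LEVELS))
  data.frame(term = names(map), consequence = unname(map),
             stringsAsFactors = FALSE)
}

#' Map annotation terms to consequence classes
#'
#' @param term character vector of SO terms or consequence enum values
#' @param protein_change protein-level change strings; a change spanning
#'   more than one residue (range notation with `_`) upgrades a missense
#'   call to `multi_aa`
#' @return character vector of consequence classes
#' @export
map_consequence <- function(term, protein_change = "") {
  tab <- so_consequence_table()
  out <- tab$consequence[match(term, tab$term)]
  unknown <- is.na(out)
  if (any(unknown)) {
    warning("unknown annotation term(s) mapped to 'other': ",
            paste(unique(term[unknown]), collapse = ", "))
    out[unknown] <- "other"
  }
  if (length(protein_change) == 1L) {
    protein_change <- rep(protein_change, length(out))
  }
  multi <- out == "missense" & grepl("[0-9]_[A-Za-z]*[0-9]", protein_change)
  out[multi] <- "multi_aa"
  out
}

derive_response <- function(recist) {
  ifelse(recist %in% RESPONDER_CODES, "responder", "non_responder")
}

#' Read the cohort sample sheet
#'
#' Tab-separated with header columns `sample_id`, `recist`, `sub_cohort`,
#' `has_wes`, `has_rna`, `tumor_purity` and optionally `split`. Response is
#' derived from RECIST: CR/PR are responders; PD/SD/MR (mixed response)
#' are non-responders.
#'
#' @param path sample sheet path
#' @return data.frame of validated sample records
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("no such sample sheet: ", path)
  if (file.info(path)$size == 0) {
    return(empty_sample_sheet())
  }
  tab <- read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (nrow(tab) == 0) return(empty_sample_sheet())
  required <- c("sample_id", "recist", "sub_cohort", "has_wes", "has_rna")
  missing_cols <- setdiff(required, colnames(tab))
  if (length(missing_cols)) {
    stop("sample sheet lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  validate_sample_sheet(tab)
}

empty_sample_sheet <- function() {
  data.frame(sample_id = character(), response = character(),
             recist = character(), sub_cohort = character(),
             has_wes = logical(), has_rna = logical(),
             tumor_purity = numeric(), split = character(),
             stringsAsFactors = FALSE)
}

validate_sample_sheet <- function(tab) {
  if (anyDuplicated(tab$sample_id)) {
    stop("duplicate sample_id in sample sheet: ",
         paste(unique(tab$sample_id[duplicated(tab$sample_id)]), collapse = ", "))
  }
  no_response <- is.na(tab$recist)
  if (any(no_response)) {
    warning("excluding ", sum(no_response),
            " sample(s) without a response label: ",
            paste(tab$sample_id[no_response], collapse = ", "))
    tab <- tab[!no_response, , drop = FALSE]
  }
  bad <- !tab$recist %in% RECIST_CODES
  if (any(bad)) {
    stop("unknown RECIST code(s): ", paste(unique(tab$recist[bad]), collapse = ", "))
  }
  tab$has_wes <- as.logical(tab$has_wes)
  tab$has_rna <- as.logical(tab$has_rna)
  if (is.null(tab$tumor_purity)) tab$tumor_purity <- NA_real_
  if (any(tab$has_wes & is.na(tab$tumor_purity))) {
    stop("tumor_purity required for WES samples: ",
         paste(tab$sample_id[tab$has_wes & is.na(tab$tumor_purity)], collapse = ", "))
  }
  ok_purity <- is.na(tab$tumor_purity) |
    (tab$tumor_purity >= 0 & tab$tumor_purity <= 1)
  if (!all(ok_purity)) stop("tumor_purity outside [0,1]")
  tab$response <- derive_response(tab$recist)
  if (is.null(tab$split)) tab$split <- "unassigned"
  tab$split[is.na(tab$split)] <- "unassigned"
  rownames(tab) <- NULL
  tab[, c("sample_id", "response", "recist", "sub_cohort", "has_wes",
          "has_rna", "tumor_purity", "split")]
}

#' Write a sample sheet
#' @param samples data.frame as returned by [read_sample_sheet()]
#' @param path output path
#' @export
write_sample_sheet <- function(samples, path) {
  write_tsv(samples[, setdiff(colnames(samples), "response"), drop = FALSE], path)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, required = character()) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.info(path)$size == 0) stop("empty table (no header): ", path)
  tab <- read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, na.strings = c("NA", ""))
  missing_cols <- setdiff(required, colnames(tab))
  if (length(missing_cols)) {
    stop(path, " lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  tab
}

VARIANT_COLUMNS <- c("sample_id", "chrom", "pos", "ref", "alt", "gene",
                     "consequence", "protein_change", "tumor_depth",
                     "normal_depth", "tumor_vaf", "normal_vaf", "alt_reads")

#' Read an annotated somatic variant table
#'
#' TSV with columns `sample_id`, `chrom`, `pos` (1-based), `ref`, `alt`,
#' `gene`, `consequence` (SO term or consequence class), `protein_change`,
#' `tumor_depth`, `normal_depth`, `tumor_vaf`, `normal_vaf`, `alt_reads`.
#'
#' @param path variant table path
#' @return data.frame of somatic variants with mapped consequence classes
#' @export
read_variant_table <- function(path) {
  tab <- read_tsv(path, setdiff(VARIANT_COLUMNS, "protein_change"))
  if (nrow(tab) == 0) return(tab)
  if (is.null(tab$protein_change)) tab$protein_change <- ""
  tab$protein_change[is.na(tab$protein_change)] <- ""
  for (col in c("tumor_vaf", "normal_vaf")) {
    bad <- is.na(tab[[col]]) | tab[[col]] < 0 | tab[[col]] > 1
    if (any(bad)) {
      stop("malformed ", col, " outside [0,1] at row ", which(bad)[1L],
           " of ", path)
    }
  }
  tab$consequence <- map_consequence(tab$consequence, tab$protein_change)
  tab[, VARIANT_COLUMNS]
}

#' Write a somatic variant table
#' @param variants data.frame of variants
#' @param path output path
#' @export
write_variant_table <- function(variants, path) write_tsv(variants, path)

#' Read a CNV segment table
#'
#' TSV with `sample_id`, `chrom`, `start`, `end` (0-based half-open),
#' `copy_number`, `loglik`.
#' @param path table path
#' @return data.frame of segments
#' @export
read_cnv_table <- function(path) {
  tab <- read_tsv(path, c("sample_id", "chrom", "start", "end",
                          "copy_number", "loglik"))
  if (nrow(tab) > 0 && any(tab$start >= tab$end)) {
    stop("CNV segment with start >= end at row ",
         which(tab$start >= tab$end)[1L])
  }
  if (nrow(tab) > 0 && any(tab$copy_number < 0)) stop("negative copy number")
  tab
}

#' @rdname read_cnv_table
#' @param segments data.frame of segments
#' @export
write_cnv_table <- function(segments, path) write_tsv(segments, path)

#' Read a neoantigen candidate table
#'
#' TSV with `sample_id`, `mut_peptide`, `wt_peptide` (empty for
#' frameshift-derived candidates), `mut_affinity_nM`, `wt_affinity_nM`,
#' `recognition_potential`, `hex_score`, `dissimilarity`. Affinities are
#' binding Kd values in nM and must be strictly positive.
#'
#' @param path table path
#' @return data.frame of candidates
#' @export
read_neoantigen_table <- function(path) {
  tab <- read_tsv(path, c("sample_id", "mut_peptide", "wt_peptide",
                          "mut_affinity_nM", "wt_affinity_nM",
                          "recognition_potential", "hex_score",
                          "dissimilarity"))
  if (nrow(tab) == 0) return(tab)
  tab$wt_peptide[is.na(tab$wt_peptide)] <- ""
  has_wt <- nzchar(tab$wt_peptide)
  if (any(tab$mut_affinity_nM <= 0, na.rm = TRUE) ||
      any(tab$wt_affinity_nM[has_wt] <= 0, na.rm = TRUE)) {
    stop("binding affinities must be strictly positive")
  }
  if (any(has_wt & nchar(tab$wt_peptide) != nchar(tab$mut_peptide))) {
    stop("wt and mut peptides must have equal length when wt present")
  }
  tab
}

#' @rdname read_neoantigen_table
#' @param candidates data.frame of candidates
#' @export
write_neoantigen_table <- function(candidates, path) write_tsv(candidates, path)

#' Read a clonotype count table
#'
#' TSV with `sample_id`, `chain` (TRA/TRB/IGH), `clonotype_id`,
#' `read_count`.
#' @param path table path
#' @return data.frame of clonotype counts
#' @export
read_clonotype_table <- function(path) {
  tab <- read_tsv(path, c("sample_id", "chain", "clonotype_id", "read_count"))
  if (nrow(tab) == 0) return(tab)
  if (any(!tab$chain %in% c("TRA", "TRB", "IGH"))) {
    stop("unknown chain: ", paste(setdiff(tab$chain, c("TRA", "TRB", "IGH")),
                                  collapse = ", "))
  }
  if (any(tab$read_count < 1)) stop("clonotype read_count must be >= 1")
  key <- paste(tab$sample_id, tab$chain, tab$clonotype_id)
  if (anyDuplicated(key)) stop("duplicate clonotype_id within a sample/chain")
  tab
}

#' @rdname read_clonotype_table
#' @param clonotypes data.frame of clonotype counts
#' @export
write_clonotype_table <- function(clonotypes, path) write_tsv(clonotypes, path)

#' Read HLA class I genotypes
#'
#' TSV with `sample_id`, `locus` (A/B/C), `allele1`, `allele2` at 4-digit
#' resolution; exactly one row per sample and locus.
#' @param path table path
#' @return data.frame of genotypes
#' @export
read_hla_table <- function(path) {
  tab <- read_tsv(path, c("sample_id", "locus", "allele1", "allele2"))
  if (nrow(tab) == 0) return(tab)
  if (any(!tab$locus %in% c("A", "B", "C"))) stop("HLA locus must be A, B or C")
  if (anyDuplicated(paste(tab$sample_id, tab$locus))) {
    stop("multiple genotype rows for one sample/locus")
  }
  tab
}

#' @rdname read_hla_table
#' @param genotypes data.frame of genotypes
#' @export
write_hla_table <- function(genotypes, path) write_tsv(genotypes, path)

#' Read HLA allele protein sequences
#'
#' TSV with `allele`, `sequence` (peptide-binding domain, aligned so that
#' both alleles of a locus have equal length).
#' @param path table path
#' @return named character vector, allele -> sequence
#' @export
read_hla_sequences <- function(path) {
  tab <- read_tsv(path, c("allele", "sequence"))
  stats::setNames(tab$sequence, tab$allele)
}

#' @rdname read_hla_sequences
#' @param sequences named character vector
#' @export
write_hla_sequences <- function(sequences, path) {
  write_tsv(data.frame(allele = names(sequences), sequence = unname(sequences),
                       stringsAsFactors = FALSE), path)
}

#' Read a gene expression matrix in TPM
#'
#' TSV matrix with first column `gene_id` and one column per sample.
#' @param path matrix path
#' @return numeric matrix, genes x samples
#' @export
read_expression_matrix <- function(path) {
  tab <- read_tsv(path, "gene_id")
  if (anyDuplicated(tab$gene_id)) stop("duplicate gene symbols")
  m <- as.matrix(tab[, setdiff(colnames(tab), "gene_id"), drop = FALSE])
  rownames(m) <- tab$gene_id
  if (any(m < 0)) stop("negative TPM values")
  m
}

#' @rdname read_expression_matrix
#' @param expr numeric matrix, genes x samples
#' @export
write_expression_matrix <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read a fusion call table
#'
#' TSV with `sample_id`, `gene5`, `gene3`, `frame`
#' (in_frame/frameshift/unknown).
#' @param path table path
#' @return data.frame of fusion calls
#' @export
read_fusion_table <- function(path) {
  tab <- read_tsv(path, c("sample_id", "gene5", "gene3", "frame"))
  if (nrow(tab) > 0 &&
      any(!tab$frame %in% c("in_frame", "frameshift", "unknown"))) {
    stop("fusion frame must be in_frame, frameshift or unknown")
  }
  tab
}

#' @rdname read_fusion_table
#' @param fusions data.frame of fusion calls
#' @export
write_fusion_table <- function(fusions, path) write_tsv(fusions, path)

#' Read per-sample sequencing QC metrics
#'
#' TSV with `sample_id`, `tumor_coverage`, `normal_coverage`,
#' `snp_correlation` (all consumed as upstream estimates).
#' @param path table path
#' @return data.frame of metrics
#' @export
read_qc_metrics <- function(path) {
  read_tsv(path, c("sample_id", "tumor_coverage", "normal_coverage",
                   "snp_correlation"))
}

#' @rdname read_qc_metrics
#' @param metrics data.frame of metrics
#' @export
write_qc_metrics <- function(metrics, path) write_tsv(metrics, path)

COHORT_FILES <- c(samples = "samples.tsv", variants = "variants.tsv",
                  cnvs = "cnvs.tsv", neoantigens = "neoantigens.tsv",
                  clonotypes = "clonotypes.tsv",
                  hla_genotypes = "hla_genotypes.tsv",
                  hla_sequences = "hla_sequences.tsv",
                  expression = "expression.tsv", fusions = "fusions.tsv",
                  qc_metrics = "qc_metrics.tsv", exons = "exons.bed")

#' Read a complete on-disk cohort
#'
#' Expects the fixed file layout written by [write_cohort()]: the tables of
#' `COHORT_FILES` plus a `coverage/` directory with one BED per WES sample.
#' Missing omics files are tolerated; availability is tracked per sample.
#'
#' @param dir cohort directory
#' @return an `ici_cohort` list
#' @export
read_cohort <- function(dir) {
  p <- function(f) file.path(dir, f)
  samples <- read_sample_sheet(p(COHORT_FILES["samples"]))
  opt <- function(key, reader) {
    f <- p(COHORT_FILES[[key]])
    if (file.exists(f)) reader(f) else NULL
  }
  cov_dir <- file.path(dir, "coverage")
  coverage <- list()
  if (dir.exists(cov_dir)) {
    beds <- list.files(cov_dir, pattern = "\\.bed$", full.names = TRUE)
    coverage <- lapply(beds, read_intervals)
    names(coverage) <- sub("\\.bed$", "", basename(beds))
  }
  structure(list(
    samples = samples,
    variants = opt("variants", read_variant_table),
    cnvs = opt("cnvs", read_cnv_table),
    neoantigens = opt("neoantigens", read_neoantigen_table),
    clonotypes = opt("clonotypes", read_clonotype_table),
    hla_genotypes = opt("hla_genotypes", read_hla_table),
    hla_sequences = opt("hla_sequences", read_hla_sequences),
    expression = opt("expression", read_expression_matrix),
    fusions = opt("fusions", read_fusion_table),
    qc_metrics = opt("qc_metrics", read_qc_metrics),
    exons = opt("exons", read_intervals),
    coverage = coverage
  ), class = "ici_cohort")
}

#' Write a cohort to disk
#' @param cohort an `ici_cohort`
#' @param dir output directory (created if needed)
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_sample_sheet(cohort$samples, p(COHORT_FILES["samples"]))
  put <- function(key, writer) {
    if (!is.null(cohort[[key]])) writer(cohort[[key]], p(COHORT_FILES[[key]]))
  }
  put("variants", write_variant_table)
  put("cnvs", write_cnv_table)
  put("neoantigens", write_neoantigen_table)
  put("clonotypes", write_clonotype_table)
  put("hla_genotypes", write_hla_table)
  put("hla_sequences", write_hla_sequences)
  put("expression", write_expression_matrix)
  put("fusions", write_fusion_table)
  put("qc_metrics", write_qc_metrics)
  if (!is.null(cohort$exons)) write_intervals(cohort$exons, p(COHORT_FILES["exons"]))
  if (length(cohort$coverage)) {
    dir.create(file.path(dir, "coverage"), showWarnings = FALSE)
    for (s in names(cohort$coverage)) {
      write_intervals(cohort$coverage[[s]],
                      file.path(dir, "coverage", paste0(s, ".bed")))
    }
  }
  invisible(dir)
}

#' @export
print.ici_cohort <- function(x, ...) {
  cat("ici_cohort:", nrow(x$samples), "samples (",
      sum(x$samples$has_wes), "WES,", sum(x$samples$has_rna), "RNA,",
      sum(x$samples$has_wes & x$samples$has_rna), "paired )\n")
  invisible(x)
}
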