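#' Default generative coefficients of the synthetic truth
#'
#' Non-zero weight is placed on the headline biomarkers the analysis is
#' expected to recover — nsTMB, fsIndel burden, the response pathway,
#' B2M alterations, HED, TCR alpha-chain entropy, the IFNG-IMS ratio and
#' IGH entropy — so selection-recovery tests have a known sparse truth.
#' Weights are on the cohort-standardized biomarker scale.
#'
#' @return named numeric vector over the signal biomarkers
#' @export
default_truth_effects <- function() {
  c(ns_tmb = 0.9, fsindel_burden = 0.8, response_pathway = 0.8,
    alt_b2m = -0.8, hed_mean = 0.8, tcr_alpha_entropy = 0.9,
    ifng_ims_ratio = 0.8, igh_entropy = 0.8)
}

#' Synthetic cohort configuration
#'
#' Defaults mirror the meta-cohort structure the analysis assumes:
#' 511 patients in 203:62:246 WES-only / RNA-only / paired proportions
#' (449 WES, 308 RNA), a 192/449 responder fraction, eight sub-cohorts
#' with batch-structured expression, and nsTMB spanning roughly 0.5-50
#' mutations/Mb log-normally.
#'
#' @param n_total cohort size
#' @param wes_only_fraction,rna_only_fraction availability mix; the
#'   remainder is paired
#' @param responder_fraction target responder prevalence
#' @param n_subcohorts number of batch-labelled sub-cohorts
#' @param seed mandatory RNG seed
#' @param label_noise probability of flipping a generated label
#' @param nstmb_meanlog,nstmb_sdlog log-normal nsTMB parameters (per Mb)
#' @param effects named generative coefficients (zero vector gives a
#'   null cohort)
#' @param batch_sd standard deviation of per-gene log2 batch shifts
#' @param exon_count,exon_width synthetic exome grid (defaults: 30 Mb)
#' @param n_decoy_genes expression decoy genes
#' @return a `cohort_config` list
#' @export
cohort_config <- function(n_total = 511, wes_only_fraction = 203 / 511,
                          rna_only_fraction = 62 / 511,
                          responder_fraction = 192 / 449, n_subcohorts = 8,
                          seed, label_noise = 0.05,
                          nstmb_meanlog = log(4), nstmb_sdlog = 1,
                          effects = default_truth_effects(), batch_sd = 0.8,
                          exon_count = 300, exon_width = 1e5,
                          n_decoy_genes = 40) {
  if (missing(seed)) stop("a seed is mandatory")
  paired_fraction <- 1 - wes_only_fraction - rna_only_fraction
  if (wes_only_fraction < 0 || rna_only_fraction < 0 || paired_fraction < 0) {
    stop("infeasible availability fractions")
  }
  structure(list(n_total = n_total, wes_only_fraction = wes_only_fraction,
                 rna_only_fraction = rna_only_fraction,
                 paired_fraction = paired_fraction,
                 responder_fraction = responder_fraction,
                 n_subcohorts = n_subcohorts, seed = seed,
                 label_noise = label_noise, nstmb_meanlog = nstmb_meanlog,
                 nstmb_sdlog = nstmb_sdlog, effects = effects,
                 batch_sd = batch_sd, exon_count = exon_count,
                 exon_width = exon_width, n_decoy_genes = n_decoy_genes),
            class = "cohort_config")
}

random_peptide <- function(n, len = 9) {
  if (n == 0) return(character(0))
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  m <- matrix(sample(aa, n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

BASES <- c("A", "C", "G", "T")

#' Generate a synthetic anti-PD1 cohort with known truth
#'
#' Emits every upstream-call-level input the pipeline consumes — sample
#' sheet, somatic variants with QC fields, CNV segments, neoantigen
#' candidates, HLA genotypes with (synthetic) allele protein sequences,
#' clonotype tables, a TPM expression matrix with injected per-sub-cohort
#' batch shifts, fusion calls, per-sample QC metrics, exon coordinates
#' and per-sample coverage tracks — plus the generative truth. A latent
#' per-sample immunogenicity drives correlated clonotype diversity and
#' interferon signature expression and lowers tumor purity. Response
#' labels are Bernoulli draws from a sigmoid-linear model over the
#' cohort-standardized realized signal biomarkers, with label noise.
#'
#' @param config a [cohort_config()]
#' @param dir optional directory; when given the cohort files and a
#'   `truth.json` are written there
#' @param fixtures shipped fixtures from [ici_fixtures()]
#' @return list with `cohort` (an `ici_cohort`) and `truth`
#' @export
generate_cohort <- function(config, dir = NULL, fixtures = ici_fixtures()) {
  stopifnot(inherits(config, "cohort_config"))
  out <- with_seed(config$seed, generate_cohort_impl(config, fixtures))
  if (!is.null(dir)) {
    write_cohort(out$cohort, dir)
    jsonlite::write_json(out$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  out
}

generate_cohort_impl <- function(config, fixtures) {
  n <- config$n_total
  n_wes_only <- round(config$wes_only_fraction * n)
  n_rna_only <- round(config$rna_only_fraction * n)
  n_paired <- n - n_wes_only - n_rna_only
  if (n_paired < 0) stop("infeasible availability fractions")

  ids <- sprintf("S%04d", seq_len(n))
  has_wes <- c(rep(TRUE, n_wes_only), rep(FALSE, n_rna_only),
               rep(TRUE, n_paired))
  has_rna <- c(rep(FALSE, n_wes_only), rep(TRUE, n_rna_only),
               rep(TRUE, n_paired))
  sub_cohort <- sample(rep_len(sprintf("batch%02d", seq_len(config$n_subcohorts)), n))
  # three correlated immune axes: T-cell infiltration (latent), B-cell
  # infiltration (latent_b) and interferon tone (latent_ifn); purity is
  # moderately anti-correlated with T-cell infiltration
  latent <- stats::rnorm(n)
  latent_b <- 0.4 * latent + sqrt(1 - 0.4^2) * stats::rnorm(n)
  latent_ifn <- 0.5 * latent + sqrt(1 - 0.5^2) * stats::rnorm(n)
  latent_t2 <- 0.7 * latent + sqrt(1 - 0.7^2) * stats::rnorm(n)
  purity <- pmin(0.98, pmax(0.05, 0.72 - 0.05 * latent +
                              stats::rnorm(n, 0, 0.09)))

  # synthetic exome: a non-overlapping grid plus the real gene bodies the
  # alteration rules need
  k <- config$exon_count
  chroms <- rep_len(paste0("chr", 1:22), k)
  tier <- (seq_len(k) - 1) %/% 22
  grid <- GenomicRanges::GRanges(chroms,
                                 IRanges::IRanges(1e6 + tier * 2 * config$exon_width + 1,
                                                  width = config$exon_width))
  exons <- interval_union(grid, fixtures$gene_regions)

  wes_ids <- ids[has_wes]
  # exons are disjoint, so a subset needs no further merging
  coverage <- lapply(seq_along(wes_ids), function(i) {
    exons[stats::runif(length(exons)) < 0.97]
  })
  names(coverage) <- wes_ids

  sub_targets <- lapply(split(wes_ids, sub_cohort[has_wes]), function(members) {
    build_target_region(coverage[members], exons)
  })
  target <- intersect_cohort_regions(sub_targets)
  mb <- interval_size(target) / 1e6

  # --- somatic variants -------------------------------------------------
  nstmb_lat <- pmin(60, pmax(0.2, stats::rlnorm(n, config$nstmb_meanlog,
                                                config$nstmb_sdlog)))
  fs_lat <- pmin(5, pmax(0.01, stats::rlnorm(n, log(0.35), 0.8)))
  class_rates <- c(missense = 0.72, synonymous = 0.30, stop_gained = 0.05,
                   stop_lost = 0.003, start_lost = 0.003, multi_aa = 0.01,
                   splice = 0.04)
  wes_idx <- which(has_wes)
  # per-sample, per-class multiplicative jitter: mutational signature
  # composition varies across tumors, so class shares are not a fixed
  # multiple of the total load
  counts <- sapply(names(class_rates), function(cl) {
    jit <- exp(stats::rnorm(length(wes_idx), 0, 0.5))
    stats::rpois(length(wes_idx), class_rates[[cl]] * jit * nstmb_lat[wes_idx] * mb)
  })
  # indel processes run on their own per-sample rates, largely decoupled
  # from the SNV load
  inframe_lat <- pmin(2, pmax(0.005, stats::rlnorm(n, log(0.08), 0.8)))
  counts <- cbind(counts,
                  inframe_indel = stats::rpois(length(wes_idx),
                                               inframe_lat[wes_idx] * mb),
                  frameshift = stats::rpois(length(wes_idx),
                                            fs_lat[wes_idx] * mb))

  driver_p <- c(BRAF = 0.28, B2M = 0.10, TP53 = 0.15, STK11 = 0.04,
                PTEN = 0.06, KRAS = 0.04, JAK1 = 0.05, JAK2 = 0.05,
                CTNNB1 = 0.06)
  drivers <- sapply(driver_p, function(p) stats::runif(length(wes_idx)) < p)
  driver_class <- c(BRAF = "missense", B2M = "frameshift", TP53 = "frameshift",
                    STK11 = "frameshift", PTEN = "frameshift",
                    KRAS = "missense", JAK1 = "missense", JAK2 = "missense",
                    CTNNB1 = "missense")

  n_per_class <- colSums(counts)
  total_passenger <- sum(n_per_class)
  pass_idx <- sample.int(length(target), total_passenger, replace = TRUE,
                         prob = GenomicRanges::width(target))
  pass_pos <- GenomicRanges::start(target)[pass_idx] +
    floor(stats::runif(total_passenger) *
            (GenomicRanges::width(target)[pass_idx] - 10))
  cls_long <- rep(colnames(counts), n_per_class)
  sid_long <- unlist(lapply(colnames(counts), function(cl) rep(wes_ids, counts[, cl])),
                     use.names = FALSE)
  variants <- data.frame(
    sample_id = sid_long,
    chrom = as.character(GenomicRanges::seqnames(target))[pass_idx],
    pos = pass_pos,
    consequence = cls_long,
    gene = sprintf("GENE%03d", sample.int(500, total_passenger, TRUE)),
    stringsAsFactors = FALSE)

  # driver variants at their real gene coordinates (inside the exon set)
  drv_rows <- do.call(rbind, lapply(colnames(drivers), function(g) {
    hit <- drivers[, g]
    if (!any(hit)) return(NULL)
    region <- fixtures$gene_regions[g]
    data.frame(sample_id = wes_ids[hit],
               chrom = as.character(GenomicRanges::seqnames(region)),
               pos = GenomicRanges::start(region) +
                 sample.int(GenomicRanges::width(region) - 10, sum(hit), TRUE),
               consequence = driver_class[[g]], gene = g,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(drv_rows)) variants <- rbind(variants, drv_rows)

  nv <- nrow(variants)
  is_fs <- variants$consequence == "frameshift"
  is_inf <- variants$consequence == "inframe_indel"
  ref1 <- BASES[sample.int(4, nv, TRUE)]
  variants$ref <- ifelse(is_fs, paste0(ref1, "T"),
                         ifelse(is_inf, paste0(ref1, "TTA"),
                                ifelse(variants$consequence == "multi_aa",
                                       paste0(ref1, "G"), ref1)))
  alt1 <- BASES[(match(ref1, BASES) %% 4) + 1]
  variants$alt <- ifelse(is_fs | is_inf, ref1,
                         ifelse(variants$consequence == "multi_aa",
                                paste0(alt1, "C"), alt1))
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  res_pos <- sample.int(900, nv, TRUE)
  variants$protein_change <- ifelse(
    variants$consequence == "missense",
    paste0(sample(aa, nv, TRUE), res_pos, sample(aa, nv, TRUE)),
    ifelse(is_fs, paste0(sample(aa, nv, TRUE), res_pos, "fs"), ""))
  variants$protein_change[variants$gene == "BRAF" &
                            variants$consequence == "missense"] <- "V600E"
  variants$tumor_depth <- pmax(25L, round(stats::rlnorm(nv, log(90), 0.35)))
  variants$alt_reads <- pmax(3L, round(stats::runif(nv, 0.06, 0.6) *
                                         variants$tumor_depth))
  variants$tumor_vaf <- round(variants$alt_reads / variants$tumor_depth, 4)
  variants$normal_depth <- pmax(21L, round(stats::rlnorm(nv, log(50), 0.3)))
  variants$normal_vaf <- 0

  # QC-failing extras so the variant filter has work to do
  n_fail <- stats::rpois(length(wes_ids), 2)
  if (sum(n_fail) > 0) {
    nf <- sum(n_fail)
    fail_idx <- sample.int(length(target), nf, replace = TRUE,
                           prob = GenomicRanges::width(target))
    fails <- data.frame(
      sample_id = rep(wes_ids, n_fail),
      chrom = as.character(GenomicRanges::seqnames(target))[fail_idx],
      pos = GenomicRanges::start(target)[fail_idx] + 5L,
      consequence = sample(c("missense", "synonymous"), nf, TRUE),
      gene = sprintf("GENE%03d", sample.int(500, nf, TRUE)),
      ref = BASES[sample.int(4, nf, TRUE)], alt = BASES[sample.int(4, nf, TRUE)],
      protein_change = "",
      tumor_depth = 100L, alt_reads = 10L, tumor_vaf = 0.1,
      normal_depth = 60L, normal_vaf = 0,
      stringsAsFactors = FALSE)
    mode <- sample.int(3, nf, TRUE)
    fails$tumor_vaf[mode == 1] <- 0.02
    fails$alt_reads[mode == 1] <- 2L
    fails$normal_vaf[mode == 2] <- 0.1
    fails$tumor_depth[mode == 3] <- 15L
    variants <- rbind(variants, fails[, colnames(variants)])
  }
  variants <- variants[, VARIANT_COLUMNS]

  # --- CNV segments -----------------------------------------------------
  n_seg <- stats::rpois(length(wes_ids), 2.5)
  ns <- sum(n_seg)
  segs <- data.frame(
    sample_id = rep(wes_ids, n_seg),
    chrom = paste0("chr", sample.int(22, ns, TRUE)),
    start = round(stats::runif(ns, 1e6, 5e7)),
    copy_number = sample(c(0, 1, 1, 3, 4), ns, TRUE),
    loglik = round(stats::runif(ns, 100, 500), 1),
    stringsAsFactors = FALSE)
  segs$end <- segs$start + round(stats::runif(ns, 1e6, 8e6))
  low_ll <- stats::runif(ns) < 0.15
  segs$loglik[low_ll] <- round(stats::runif(sum(low_ll), 10, 99), 1)

  cnv_driver <- function(gene_or_region, p, cn) {
    hit <- stats::runif(length(wes_ids)) < p
    if (!any(hit)) return(NULL)
    region <- if (is.character(gene_or_region)) {
      fixtures$gene_regions[gene_or_region]
    } else gene_or_region
    data.frame(sample_id = wes_ids[hit],
               chrom = as.character(GenomicRanges::seqnames(region)),
               start = GenomicRanges::start(region) - 1000,
               end = GenomicRanges::end(region) + 1000,
               copy_number = cn, loglik = 300,
               stringsAsFactors = FALSE)
  }
  chr6_hit <- stats::runif(length(wes_ids)) < 0.06
  drv_segs <- rbind(cnv_driver("MDM2", 0.04, 5), cnv_driver("MDM4", 0.03, 5),
                    cnv_driver("EGFR", 0.04, 6), cnv_driver("PTEN", 0.03, 1))
  if (any(chr6_hit)) {
    r6 <- fixtures$chr6p21
    drv_segs <- rbind(drv_segs,
                      data.frame(sample_id = wes_ids[chr6_hit],
                                 chrom = as.character(GenomicRanges::seqnames(r6))[1],
                                 start = GenomicRanges::start(r6)[1],
                                 end = GenomicRanges::start(r6)[1] + 2e6,
                                 copy_number = 1, loglik = 300,
                                 stringsAsFactors = FALSE))
  }
  seg_cols <- c("sample_id", "chrom", "start", "end", "copy_number", "loglik")
  segs <- rbind(segs[, seg_cols], drv_segs[, seg_cols])

  # --- neoantigen candidates -------------------------------------------
  ns_counts <- rowSums(counts[, c("missense", "stop_gained", "multi_aa",
                                  "frameshift", "inframe_indel")])
  # neoantigen yield varies per sample beyond the mutation count (binding
  # landscape, HLA context), so the burden is a noisy proxy of nsTMB
  n_neo <- stats::rpois(length(wes_ids),
                        0.20 * ns_counts * exp(stats::rnorm(length(wes_ids), 0, 0.7)))
  nn <- sum(n_neo)
  neo <- data.frame(
    sample_id = rep(wes_ids, n_neo),
    mut_peptide = random_peptide(nn),
    wt_peptide = "",
    mut_affinity_nM = stats::rlnorm(nn, log(200), 1.2),
    wt_affinity_nM = NA_real_,
    recognition_potential = stats::rexp(nn, 1),
    hex_score = stats::runif(nn, 0, 12),
    dissimilarity = stats::rbeta(nn, 2, 5),
    stringsAsFactors = FALSE)
  if (nn > 0) {
    has_wt <- stats::runif(nn) < 0.85
    neo$wt_peptide[has_wt] <- random_peptide(sum(has_wt))
    neo$wt_affinity_nM[has_wt] <- neo$mut_affinity_nM[has_wt] *
      exp(stats::rnorm(sum(has_wt), 0.5, 1))
  }

  # --- HLA --------------------------------------------------------------
  hla_seqs <- synthetic_hla_sequences()
  pool <- split(names(hla_seqs), substr(names(hla_seqs), 1, 1))
  hla <- do.call(rbind, lapply(c("A", "B", "C"), function(loc) {
    a1 <- sample(pool[[loc]], n, TRUE)
    a2 <- sample(pool[[loc]], n, TRUE)
    data.frame(sample_id = ids, locus = loc, allele1 = a1, allele2 = a2,
               stringsAsFactors = FALSE)
  }))
  hla <- hla[order(hla$sample_id, hla$locus), ]

  # --- clonotypes (generated for every sample; emitted where RNA exists)
  make_chain <- function(chain, slope, base, axis = latent) {
    rich <- pmin(300, stats::rpois(n, exp(base + slope * axis)))
    total <- sum(rich)
    if (total == 0) {
      return(data.frame(sample_id = character(), chain = character(),
                        clonotype_id = character(), read_count = integer(),
                        stringsAsFactors = FALSE))
    }
    data.frame(sample_id = rep(ids, rich), chain = chain,
               clonotype_id = paste0(tolower(chain),
                                     unlist(lapply(rich[rich > 0], seq_len))),
               read_count = 1L + stats::rnbinom(total, size = 0.6, mu = 4),
               stringsAsFactors = FALSE)
  }
  clono <- rbind(make_chain("TRA", 0.8, 1.4),
                 make_chain("TRB", 0.8, 1.5, axis = latent_t2),
                 make_chain("IGH", 0.8, 1.2, axis = latent_b))

  # --- expression -------------------------------------------------------
  sigs <- fixtures$signatures
  genes <- unique(c(unlist(sigs, use.names = FALSE), "CD274", "B2M",
                    sprintf("GENE%03d", seq_len(config$n_decoy_genes))))
  mu_g <- stats::runif(length(genes), 1, 6)
  eff <- eff_ifn <- stats::setNames(numeric(length(genes)), genes)
  eff[sigs$ifng_signature] <- 0.4
  eff_ifn[sigs$ifng_signature] <- 0.9
  eff[sigs$lymphocyte_markers] <- 0.7
  eff[sigs$hla_class1_genes] <- 0.3
  eff["B2M"] <- 0.3
  eff["CD274"] <- 0.5
  clean <- mu_g + outer(eff, latent) + outer(eff_ifn, latent_ifn) +
    matrix(stats::rnorm(length(genes) * n, 0, 0.4), length(genes), n)
  rownames(clean) <- genes
  colnames(clean) <- ids
  shifts <- matrix(stats::rnorm(length(genes) * config$n_subcohorts, 0,
                                config$batch_sd),
                   length(genes), config$n_subcohorts,
                   dimnames = list(genes, sort(unique(sub_cohort))))
  observed <- clean + shifts[, sub_cohort]
  expr <- pmax(2^observed - 1, 0)

  # --- fusions ----------------------------------------------------------
  n_fus <- stats::rpois(n, 0.4)
  nf2 <- sum(n_fus)
  fusions <- data.frame(
    sample_id = rep(ids, n_fus),
    gene5 = sprintf("GENE%03d", sample.int(500, nf2, TRUE)),
    gene3 = sprintf("GENE%03d", sample.int(500, nf2, TRUE)),
    frame = sample(c("in_frame", "frameshift", "unknown"), nf2, TRUE,
                   prob = c(0.5, 0.3, 0.2)),
    stringsAsFactors = FALSE)

  # --- sequencing QC metrics -------------------------------------------
  qc <- data.frame(sample_id = wes_ids,
                   tumor_coverage = round(stats::rnorm(length(wes_ids), 120, 20), 1),
                   normal_coverage = round(stats::rnorm(length(wes_ids), 45, 8), 1),
                   snp_correlation = round(pmin(1, 0.93 +
                                                  0.05 * stats::rnorm(length(wes_ids))), 3),
                   stringsAsFactors = FALSE)
  fail_mode <- stats::runif(length(wes_ids))
  qc$tumor_coverage[fail_mode < 0.01] <- round(stats::runif(sum(fail_mode < 0.01), 30, 59), 1)
  qc$snp_correlation[fail_mode > 0.99] <- round(stats::runif(sum(fail_mode > 0.99), 0.5, 0.79), 3)

  # --- realized signal biomarkers and labels ---------------------------
  per_sample_counts <- function(classes) {
    m <- counts[, intersect(classes, colnames(counts)), drop = FALSE]
    v <- stats::setNames(rowSums(m), wes_ids)
    full <- stats::setNames(numeric(n), ids)
    full[wes_ids] <- v
    full
  }
  drv_fs <- rowSums(drivers[, driver_class == "frameshift", drop = FALSE])
  drv_ns <- rowSums(drivers)
  ns_real <- per_sample_counts(ns_tmb_classes())
  ns_real[wes_ids] <- ns_real[wes_ids] + drv_ns
  ns_real <- ns_real / mb
  fs_real <- per_sample_counts("frameshift")
  fs_real[wes_ids] <- fs_real[wes_ids] + drv_fs
  fs_real <- fs_real / mb
  # for RNA-only samples the latent mutational biology still exists
  latent_fill <- !has_wes
  ns_real[latent_fill] <- nstmb_lat[latent_fill]
  fs_real[latent_fill] <- fs_lat[latent_fill]

  rp_real <- stats::setNames(numeric(n), ids)
  rp_hit <- drivers[, "JAK1"] | drivers[, "JAK2"] | drivers[, "CTNNB1"] | chr6_hit
  rp_real[wes_ids] <- as.numeric(rp_hit)
  b2m_real <- stats::setNames(numeric(n), ids)
  b2m_real[wes_ids] <- as.numeric(drivers[, "B2M"])

  gm <- fixtures$grantham
  hed_cache <- new.env(parent = emptyenv())
  hed_pair <- function(a1, a2) {
    key <- paste(sort(c(a1, a2)), collapse = "|")
    if (is.null(hed_cache[[key]])) {
      hed_cache[[key]] <- hed_locus(hla_seqs[[a1]], hla_seqs[[a2]], gm)
    }
    hed_cache[[key]]
  }
  hla_by_sample <- split(hla, hla$sample_id)
  hed_real <- vapply(ids, function(s) {
    g <- hla_by_sample[[s]]
    mean(mapply(hed_pair, g$allele1, g$allele2))
  }, numeric(1))

  entropy_by <- function(chain) {
    rows <- clono[clono$chain == chain, ]
    h <- vapply(split(rows$read_count, rows$sample_id), repertoire_entropy,
                numeric(1))
    full <- stats::setNames(numeric(n), ids)
    full[names(h)] <- h
    full
  }
  tra_real <- entropy_by("TRA")
  igh_real <- entropy_by("IGH")
  ifng_real <- colMeans(clean[sigs$ifng_signature, , drop = FALSE]) /
    pmax(colMeans(clean[sigs$immunosuppression_signature, , drop = FALSE]), 0.1)

  signal <- cbind(ns_tmb = ns_real, fsindel_burden = fs_real,
                  response_pathway = rp_real, alt_b2m = b2m_real,
                  hed_mean = hed_real, tcr_alpha_entropy = tra_real,
                  ifng_ims_ratio = ifng_real, igh_entropy = igh_real)
  zsig <- apply(signal, 2L, function(x) {
    s <- stats::sd(x)
    if (s == 0) return(x * 0)
    (x - mean(x)) / s
  })
  beta <- config$effects[colnames(signal)]
  beta[is.na(beta)] <- 0
  lp <- drop(zsig %*% beta)
  intercept <- stats::uniroot(function(c0) {
    mean(stats::plogis(lp + c0)) - config$responder_fraction
  }, c(-20, 20))$root
  prob <- stats::plogis(lp + intercept)
  y <- stats::rbinom(n, 1, prob)
  flip <- stats::runif(n) < config$label_noise
  y[flip] <- 1L - y[flip]

  recist <- ifelse(y == 1,
                   sample(c("CR", "PR"), n, TRUE, prob = c(0.3, 0.7)),
                   sample(c("PD", "SD", "MR"), n, TRUE, prob = c(0.5, 0.4, 0.1)))
  samples <- data.frame(sample_id = ids, response = derive_response(recist),
                        recist = recist, sub_cohort = sub_cohort,
                        has_wes = has_wes, has_rna = has_rna,
                        tumor_purity = ifelse(has_wes, round(purity, 3), NA),
                        split = "unassigned", stringsAsFactors = FALSE)

  cohort <- structure(list(
    samples = samples,
    variants = variants,
    cnvs = segs,
    neoantigens = neo,
    clonotypes = clono[clono$sample_id %in% ids[has_rna], , drop = FALSE],
    hla_genotypes = hla[hla$sample_id %in% wes_ids, , drop = FALSE],
    hla_sequences = hla_seqs,
    expression = expr[, ids[has_rna], drop = FALSE],
    fusions = fusions[fusions$sample_id %in% ids[has_rna], , drop = FALSE],
    qc_metrics = qc,
    exons = exons,
    coverage = coverage
  ), class = "ici_cohort")

  truth <- list(coefficients = as.list(beta), intercept = intercept,
                label_noise = config$label_noise,
                batch_sd = config$batch_sd,
                signal_features = names(which(beta != 0)),
                latent = stats::setNames(latent, ids),
                linear_predictor = stats::setNames(lp + intercept, ids),
                probability = stats::setNames(prob, ids),
                target_mb = mb)
  list(cohort = cohort, truth = truth)
}
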