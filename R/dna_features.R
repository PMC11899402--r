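#' Consequence class sets used by the burden metrics
#'
#' `ns_tmb_classes()` defines the nonsynonymous TMB numerator: missense,
#' nonsense (stop gained/lost), start lost, frameshift, in-frame indel and
#' multi-amino-acid changes; synonymous and pure splice calls are
#' excluded. `protein_altering_classes()` is the same set and forms the
#' denominator of the frameshift proportion.
#'
#' @return character vector of consequence classes
#' @export
ns_tmb_classes <- function() {
  c("missense", "stop_gained", "stop_lost", "start_lost", "frameshift",
    "inframe_indel", "multi_aa")
}

#' @rdname ns_tmb_classes
#' @export
protein_altering_classes <- function() ns_tmb_classes()

nonsyn_snv_classes <- function() {
  c("missense", "stop_gained", "stop_lost", "start_lost", "multi_aa")
}

lof_classes <- function() {
  c("frameshift", "stop_gained", "start_lost", "splice")
}

is_snv <- function(variants) {
  nchar(variants$ref) == 1L & nchar(variants$alt) == 1L
}

#' Mutation burden per megabase
#'
#' @param variants QC-passed variants restricted to the target region
#' @param target_mb target region size in megabases (> 0)
#' @param classes consequence classes counted in the numerator
#' @return mutations per Mb
#' @export
mutation_burden <- function(variants, target_mb, classes = ns_tmb_classes()) {
  if (!is.numeric(target_mb) || target_mb <= 0) {
    stop("target_mb must be positive")
  }
  sum(variants$consequence %in% classes) / target_mb
}

#' Fraction of protein-altering variants that are frameshifts
#' @param variants data.frame of variants
#' @return fraction in [0,1]; 0 when no protein-altering variants
#' @export
frameshift_proportion <- function(variants) {
  denom <- sum(variants$consequence %in% protein_altering_classes())
  if (denom == 0) return(0)
  sum(variants$consequence == "frameshift") / denom
}

#' Pseudocount-stabilised dN/dS count ratio
#'
#' (nonsynonymous SNVs + 1) / (synonymous SNVs + 1); only single-nucleotide
#' substitutions enter either count.
#' @param variants data.frame of variants
#' @return ratio >= 0
#' @export
dnds_ratio <- function(variants) {
  snv <- is_snv(variants)
  n_ns <- sum(snv & variants$consequence %in% nonsyn_snv_classes())
  n_s <- sum(snv & variants$consequence == "synonymous")
  (n_ns + 1) / (n_s + 1)
}

segments_to_granges <- function(segments) {
  if (nrow(segments) == 0) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(segments$chrom,
                         IRanges::IRanges(segments$start + 1L, segments$end))
}

#' CNV and deletion burden over the target region
#'
#' Fraction of target bases overlapped by QC-passed segments with copy
#' number different from 2 (CNV burden) or below 2 (deletion burden).
#'
#' @param segments QC-passed CNV segments for one sample
#' @param target target interval set (`GRanges`, non-empty)
#' @return named vector `c(cnv_burden, deletion_burden)`
#' @export
cnv_burdens <- function(segments, target) {
  tt <- if (is.list(target) && !is.null(attr(target, "size"))) target
        else target_table(target)
  denom <- attr(tt, "size")
  if (denom == 0) stop("empty target region")
  frac <- function(segs) {
    if (nrow(segs) == 0) return(0)
    segment_overlap_bases(segs, tt) / denom
  }
  c(cnv_burden = frac(segments[segments$copy_number != 2, , drop = FALSE]),
    deletion_burden = frac(segments[segments$copy_number < 2, , drop = FALSE]))
}

#' Differential agretopicity index of one neoantigen candidate
#'
#' Natural log of the wildtype/mutant binding Kd ratio; positive when the
#' mutant peptide binds more strongly (lower Kd) than its wildtype
#' counterpart.
#'
#' @param wt_affinity_nM,mut_affinity_nM binding Kd in nM, > 0
#' @return signed DAI value
#' @export
dai <- function(wt_affinity_nM, mut_affinity_nM) {
  if (any(wt_affinity_nM <= 0) || any(mut_affinity_nM <= 0)) {
    stop("affinities must be strictly positive")
  }
  log(wt_affinity_nM / mut_affinity_nM)
}

#' Per-sample neoantigen aggregate features
#'
#' Computes the neoantigen burden plus eight aggregates: strongest
#' binding encoded as -log(Kd) so larger means stronger; mean, median,
#' maximum and upper-decile (90th percentile, linear interpolation) DAI
#' over candidates with a wildtype peptide; and the maxima of the
#' precomputed recognition potential, HEX alignment score and
#' dissimilarity. With no candidates the burden is 0 and every aggregate
#' is `NA` (imputed with training medians at modelling time).
#'
#' @param candidates neoantigen candidates of one sample
#' @param target_mb target size in megabases
#' @return named numeric vector of 9 values
#' @export
neoantigen_aggregates <- function(candidates, target_mb) {
  if (!is.numeric(target_mb) || target_mb <= 0) stop("target_mb must be positive")
  out <- c(neoantigen_burden = nrow(candidates) / target_mb,
           max_neo_affinity = NA_real_, dai_mean = NA_real_,
           dai_median = NA_real_, dai_max = NA_real_,
           dai_upper_decile = NA_real_, max_recognition_potential = NA_real_,
           max_hex = NA_real_, max_dissimilarity = NA_real_)
  if (nrow(candidates) == 0) return(out)
  out["max_neo_affinity"] <- max(-log(candidates$mut_affinity_nM))
  has_wt <- nzchar(candidates$wt_peptide) & !is.na(candidates$wt_affinity_nM)
  if (any(has_wt)) {
    d <- dai(candidates$wt_affinity_nM[has_wt],
             candidates$mut_affinity_nM[has_wt])
    out["dai_mean"] <- mean(d)
    out["dai_median"] <- stats::median(d)
    out["dai_max"] <- max(d)
    out["dai_upper_decile"] <- unname(stats::quantile(d, 0.9, type = 7))
  }
  out["max_recognition_potential"] <- max(candidates$recognition_potential)
  out["max_hex"] <- max(candidates$hex_score)
  out["max_dissimilarity"] <- max(candidates$dissimilarity)
  out
}

split_residues <- function(seq) strsplit(seq, "")[[1]]

hed_locus <- function(seq1, seq2, gm) {
  a <- split_residues(seq1)
  b <- split_residues(seq2)
  if (length(a) != length(b)) {
    stop("allele sequences differ in aligned length (", length(a), " vs ",
         length(b), ")")
  }
  mean(gm[cbind(a, b)])
}

#' Mean HLA evolutionary divergence
#'
#' Per class I locus, the mean Grantham distance between the two allele
#' protein sequences over aligned positions; `hed_mean` averages the
#' three locus values. Homozygous loci contribute 0.
#'
#' @param genotype data.frame with one row per locus (`locus`, `allele1`,
#'   `allele2`) for one sample
#' @param sequences named character vector, allele -> aligned protein sequence
#' @param gm Grantham matrix from [grantham_matrix()]
#' @return mean divergence across loci
#' @export
hed_mean <- function(genotype, sequences, gm = grantham_matrix()) {
  stopifnot(all(c("A", "B", "C") %in% genotype$locus))
  per_locus <- vapply(c("A", "B", "C"), function(loc) {
    row <- genotype[genotype$locus == loc, , drop = FALSE][1, ]
    missing_alleles <- setdiff(c(row$allele1, row$allele2), names(sequences))
    if (length(missing_alleles)) {
      stop("no protein sequence for allele(s): ",
           paste(missing_alleles, collapse = ", "))
    }
    hed_locus(sequences[[row$allele1]], sequences[[row$allele2]], gm)
  }, numeric(1))
  mean(per_locus)
}

#' HLA supertype and homozygosity flags
#'
#' @param genotype per-locus genotype rows of one sample
#' @param supertypes allele -> supertype table from [hla_supertype_table()]
#' @return named logical vector: `hla_b27`, `hla_b44`, `hla_b62`,
#'   `hom_hla_b`, `hom_hla_c`
#' @export
hla_flags <- function(genotype, supertypes = hla_supertype_table()) {
  b <- genotype[genotype$locus == "B", , drop = FALSE][1, ]
  c_row <- genotype[genotype$locus == "C", , drop = FALSE][1, ]
  st <- supertypes$supertype[match(c(b$allele1, b$allele2), supertypes$allele)]
  c(hla_b27 = "B27" %in% st,
    hla_b44 = "B44" %in% st,
    hla_b62 = "B62" %in% st,
    hom_hla_b = identical(b$allele1, b$allele2),
    hom_hla_c = identical(c_row$allele1, c_row$allele2))
}

segments_hit_region <- function(segments, chrom, start1, end1) {
  any(segments$chrom == chrom & segments$start + 1 <= end1 &
        segments$end >= start1)
}

regions_frame <- function(regions) {
  data.frame(gene = names(regions),
             chrom = as.character(GenomicRanges::seqnames(regions)),
             start = GenomicRanges::start(regions),
             end = GenomicRanges::end(regions),
             stringsAsFactors = FALSE)
}

qualifying_alteration <- function(gene, class, variants, segments, rframe) {
  gene_vars <- variants[variants$gene == gene, , drop = FALSE]
  r <- rframe[rframe$gene == gene, ]
  overlap <- function(segs_df) {
    nrow(segs_df) > 0 && segments_hit_region(segs_df, r$chrom, r$start, r$end)
  }
  switch(class,
    lof = any(gene_vars$consequence %in% lof_classes()) ||
      overlap(segments[segments$copy_number < 2, , drop = FALSE]),
    nonsyn = any(gene_vars$consequence %in% nonsyn_snv_classes()),
    amp = overlap(segments[segments$copy_number >= 4, , drop = FALSE]),
    stop("unknown alteration class: ", class))
}

#' Resistance-gene and response-pathway alteration flags
#'
#' Eight resistance flags (one per gene, per the shipped rules file) and
#' one merged response-pathway flag: any qualifying JAK1/JAK2 or CTNNB1
#' alteration, or a QC-passed deletion segment overlapping chr6p21.3
#' (the HLA class I-containing locus).
#'
#' @param variants QC-passed variants of one sample
#' @param segments QC-passed CNV segments of one sample
#' @param rules gene alteration rules table
#' @param regions named gene-coordinate `GRanges`
#' @param chr6p21 the chr6p21.3 interval set
#' @return named logical vector: `alt_*` flags plus `response_pathway`
#' @export
gene_alteration_flags <- function(variants, segments,
                                  rules = resistance_rules(),
                                  regions = gene_regions(),
                                  chr6p21 = chr6p21_region()) {
  response_genes <- c("JAK1", "JAK2", "CTNNB1")
  rframe <- if (is.data.frame(regions)) regions else regions_frame(regions)
  if (is.matrix(chr6p21) || is.data.frame(chr6p21)) {
    c6 <- chr6p21
  } else {
    c6 <- data.frame(chrom = as.character(GenomicRanges::seqnames(chr6p21))[1],
                     start = GenomicRanges::start(chr6p21)[1],
                     end = GenomicRanges::end(chr6p21)[1])
  }
  hit <- vapply(seq_len(nrow(rules)), function(i) {
    qualifying_alteration(rules$gene[i], rules$class[i], variants, segments,
                          rframe)
  }, logical(1))
  names(hit) <- rules$gene
  dels <- segments[segments$copy_number < 2, , drop = FALSE]
  chr6_del <- nrow(dels) > 0 &&
    segments_hit_region(dels, c6$chrom, c6$start, c6$end)
  resistance <- hit[setdiff(rules$gene, response_genes)]
  names(resistance) <- paste0("alt_", tolower(names(resistance)))
  c(resistance,
    response_pathway = unname(any(hit[intersect(response_genes, names(hit))])) ||
      chr6_del)
}

#' BRAF V600E status
#' @param variants data.frame of variants with `gene` and `protein_change`
#' @return TRUE iff a BRAF variant with protein change V600E is present
#' @export
braf_v600e <- function(variants) {
  pc <- sub("^p\\.", "", variants$protein_change)
  any(variants$gene == "BRAF" & pc == "V600E")
}

#' Names of the genomic biomarkers, in canonical order
#' @return character vector of DNA feature names
#' @export
dna_feature_names <- function() {
  c("braf_v600e", "tumor_purity", "ns_tmb", "indel_burden", "fsindel_burden",
    "inframe_burden", "splice_burden", "missense_burden", "synonymous_burden",
    "multi_aa_burden", "frameshift_proportion", "dnds_ratio", "cnv_burden",
    "deletion_burden", "neoantigen_burden", "max_neo_affinity", "dai_mean",
    "dai_median", "dai_max", "dai_upper_decile", "max_recognition_potential",
    "max_hex", "max_dissimilarity", "hed_mean", "hla_b27", "hla_b44",
    "hla_b62", "hom_hla_b", "hom_hla_c", "alt_b2m", "alt_tp53", "alt_stk11",
    "alt_pten", "alt_kras", "alt_mdm2", "alt_mdm4", "alt_egfr",
    "response_pathway")
}

#' Compute the genomic biomarker vector of one sample
#'
#' Orchestrates all DNA-level biomarker computations. Inputs must already
#' be QC-filtered; burdens count only variants overlapping the target
#' region, while alteration flags consider every QC-passed call.
#'
#' @param variants QC-passed variants of the sample
#' @param segments QC-passed CNV segments of the sample
#' @param neoantigens neoantigen candidates of the sample
#' @param hla_genotype per-locus genotype rows of the sample
#' @param hla_sequences allele -> protein sequence map
#' @param tumor_purity upstream purity estimate in [0,1]
#' @param target meta-cohort target region (`GRanges`)
#' @param fixtures shipped reference fixtures from [ici_fixtures()]
#' @return named numeric vector over [dna_feature_names()] (flags as 0/1)
#' @export
compute_dna_features <- function(variants, segments, neoantigens,
                                 hla_genotype, hla_sequences, tumor_purity,
                                 target, fixtures = ici_fixtures()) {
  for (nm in c("variants", "segments", "neoantigens", "hla_genotype",
               "hla_sequences", "tumor_purity", "target")) {
    if (is.null(get(nm))) stop("missing required input: ", nm)
  }
  tt <- if (is.list(target) && !is.null(attr(target, "size"))) target
        else target_table(target)
  target_mb <- attr(tt, "size") / 1e6
  if (target_mb <= 0) stop("empty target region")
  on_target <- variants_on_target(variants, tt)

  burden <- function(classes) mutation_burden(on_target, target_mb, classes)
  neo <- neoantigen_aggregates(neoantigens, target_mb)
  flags <- gene_alteration_flags(
    variants, segments, fixtures$rules,
    if (is.null(fixtures$gene_regions_frame)) fixtures$gene_regions
    else fixtures$gene_regions_frame,
    if (is.null(fixtures$chr6p21_frame)) fixtures$chr6p21
    else fixtures$chr6p21_frame)
  hla <- hla_flags(hla_genotype, fixtures$supertypes)

  out <- c(
    braf_v600e = as.numeric(braf_v600e(variants)),
    tumor_purity = as.numeric(tumor_purity),
    ns_tmb = burden(ns_tmb_classes()),
    indel_burden = burden(c("frameshift", "inframe_indel")),
    fsindel_burden = burden("frameshift"),
    inframe_burden = burden("inframe_indel"),
    splice_burden = burden("splice"),
    missense_burden = burden("missense"),
    synonymous_burden = burden("synonymous"),
    multi_aa_burden = burden("multi_aa"),
    frameshift_proportion = frameshift_proportion(on_target),
    dnds_ratio = dnds_ratio(on_target),
    cnv_burdens(segments, tt),
    neo,
    hed_mean = hed_mean(hla_genotype, hla_sequences, fixtures$grantham),
    as.numeric(hla), as.numeric(flags)
  )
  names(out) <- dna_feature_names()
  out
}

variants_on_target <- function(variants, target) {
  if (nrow(variants) == 0) return(variants)
  tt <- if (is.list(target) && !is.null(attr(target, "size"))) target
        else target_table(target)
  hits <- positions_on_target(variants$chrom, variants$pos, tt)
  variants[hits, , drop = FALSE]
}
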