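#' Hand-checkable worked-example cohort
#'
#' A fixed four-sample cohort in which every biomarker value can be
#' verified by manual arithmetic: a 2 Mb two-exon target, single-digit
#' variant counts per sample, two-candidate neoantigen lists, ten-residue
#' synthetic HLA sequences, and power-of-two TPM values. Sample WE04
#' additionally carries three variants that each fail one QC rule. The
#' independently derived expected feature matrices ship as
#' `worked_example_dna.tsv` / `worked_example_rna.tsv` (see
#' [worked_example_expected()]); expression is treated as already
#' batch-corrected.
#'
#' @return an `ici_cohort`
#' @export
generate_worked_example <- function() {
  samples <- data.frame(
    sample_id = c("WE01", "WE02", "WE03", "WE04"),
    recist = c("PR", "SD", "PD", "CR"),
    sub_cohort = c("cohortA", "cohortA", "cohortB", "cohortB"),
    has_wes = TRUE, has_rna = TRUE,
    tumor_purity = c(0.8, 0.6, 0.5, 0.9),
    stringsAsFactors = FALSE)
  samples$response <- derive_response(samples$recist)
  samples$split <- "unassigned"
  samples <- samples[, c("sample_id", "response", "recist", "sub_cohort",
                         "has_wes", "has_rna", "tumor_purity", "split")]

  v <- function(sample_id, chrom, pos, ref, alt, gene, consequence,
                protein_change = "", tumor_depth = 100, normal_depth = 60,
                tumor_vaf = 0.3, normal_vaf = 0, alt_reads = 30) {
    data.frame(sample_id = sample_id, chrom = chrom, pos = pos, ref = ref,
               alt = alt, gene = gene, consequence = consequence,
               protein_change = protein_change, tumor_depth = tumor_depth,
               normal_depth = normal_depth, tumor_vaf = tumor_vaf,
               normal_vaf = normal_vaf, alt_reads = alt_reads,
               stringsAsFactors = FALSE)
  }
  variants <- rbind(
    v("WE01", "chr1", 1000, "A", "T", "BRAF", "missense", "V600E"),
    v("WE01", "chr1", 2000, "C", "T", "GENE1", "missense", "A10T"),
    v("WE01", "chr1", 3000, "G", "A", "GENE2", "synonymous"),
    v("WE01", "chr1", 4000, "AT", "A", "B2M", "frameshift", "K45fs"),
    v("WE01", "chr1", 5000, "AAAT", "A", "GENE3", "inframe_indel"),
    v("WE01", "chr1", 6000, "C", "T", "JAK1", "missense", "L100F"),
    v("WE03", "chr2", 10000, "AG", "TC", "GENE4", "multi_aa", "A5_K6delinsFL"),
    v("WE03", "chr2", 11000, "A", "G", "GENE5", "splice"),
    v("WE03", "chr2", 12000, "C", "T", "TP53", "stop_gained", "R50*"),
    v("WE03", "chr2", 13000, "G", "A", "KRAS", "missense", "G12D"),
    v("WE04", "chr1", 20000, "A", "G", "GENE6", "missense", "K7E"),
    v("WE04", "chr1", 21000, "C", "T", "GENE7", "missense", "P9S",
      tumor_vaf = 0.04, alt_reads = 4),
    v("WE04", "chr1", 22000, "G", "A", "GENE8", "synonymous",
      normal_vaf = 0.1),
    v("WE04", "chr1", 23000, "T", "C", "GENE9", "missense", "D3G",
      tumor_depth = 15))

  cnvs <- data.frame(
    sample_id = c("WE01", "WE01", "WE03", "WE03", "WE03"),
    chrom = c("chr1", "chr1", "chr12", "chr6", "chr2"),
    start = c(0, 600000, 68808000, 28600000, 0),
    end = c(500000, 700000, 68851000, 28700000, 1000000),
    copy_number = c(1, 3, 5, 1, 4),
    loglik = c(200, 50, 300, 250, 400),
    stringsAsFactors = FALSE)

  neoantigens <- data.frame(
    sample_id = c("WE01", "WE01", "WE03"),
    mut_peptide = c("AAAAAAAAF", "CCCCCCCCL", "DDDDDDDDK"),
    wt_peptide = c("AAAAAAAAL", "CCCCCCCCV", "DDDDDDDDR"),
    mut_affinity_nM = c(50, 100, 400),
    wt_affinity_nM = c(500, 100, 200),
    recognition_potential = c(0.5, 1.5, 2.0),
    hex_score = c(2, 8, 5),
    dissimilarity = c(0.1, 0.4, 0.9),
    stringsAsFactors = FALSE)

  hla_genotypes <- data.frame(
    sample_id = rep(c("WE01", "WE02", "WE03", "WE04"), each = 3),
    locus = rep(c("A", "B", "C"), 4),
    allele1 = c("A*01:01", "B*27:05", "C*07:01",
                "A*01:01", "B*07:02", "C*07:01",
                "A*01:01", "B*15:01", "C*07:01",
                "A*01:01", "B*44:02", "C*07:01"),
    allele2 = c("A*02:01", "B*44:02", "C*07:01",
                "A*01:01", "B*07:02", "C*07:01",
                "A*02:01", "B*07:02", "C*16:01",
                "A*01:01", "B*44:02", "C*07:01"),
    stringsAsFactors = FALSE)
  hla_sequences <- c(
    "A*01:01" = "SAAAAAAAAA", "A*02:01" = "RAAAAAAAAA",
    "B*27:05" = "CAAAAAAAAA", "B*44:02" = "WCAAAAAAAA",
    "B*07:02" = "DDDDDDDDDD", "B*15:01" = "EEEEEEEEEE",
    "C*07:01" = "LLLLLLLLLL", "C*16:01" = "LLLLLLLLLM")

  clonotypes <- data.frame(
    sample_id = c(rep("WE01", 6), rep("WE03", 8), rep("WE04", 4)),
    chain = c("TRA", "TRA", "TRA", "TRB", "TRB", "IGH",
              "TRA", "TRA", "TRA", "TRA", "TRB", "TRB", "IGH", "IGH",
              "TRA", "IGH", "IGH", "IGH"),
    clonotype_id = c("a1", "a2", "a3", "b1", "b2", "h1",
                     "a1", "a2", "a3", "a4", "b1", "b2", "h1", "h2",
                     "a1", "h1", "h2", "h3"),
    read_count = c(2, 1, 1, 1, 1, 5,
                   1, 1, 1, 1, 3, 1, 2, 2,
                   8, 1, 1, 3),
    stringsAsFactors = FALSE)

  fusions <- data.frame(
    sample_id = c("WE01", "WE01", "WE03", "WE03", "WE04", "WE04"),
    gene5 = c("GENE1", "GENE2", "GENE3", "GENE4", "GENE5", "GENE6"),
    gene3 = c("GENE7", "GENE8", "GENE9", "GENE1", "GENE2", "GENE3"),
    frame = c("in_frame", "unknown", "frameshift", "frameshift",
              "in_frame", "in_frame"),
    stringsAsFactors = FALSE)

  genes <- c("IFNG", "STAT1", "TGFB1", "IL10", "CD3E", "CD8A",
             "HLA-A", "HLA-B", "HLA-C", "CD274", "B2M")
  expression <- matrix(
    c(7, 1, 0, 1, 3, 3, 7, 7, 1, 1, 15,     # WE01
      0, 0, 3, 1, 0, 0, 1, 1, 1, 0, 3,      # WE02
      3, 3, 1, 1, 7, 1, 3, 1, 1, 7, 7,      # WE03
      1, 0, 1, 0, 1, 1, 0, 0, 0, 3, 1),     # WE04
    nrow = length(genes),
    dimnames = list(genes, c("WE01", "WE02", "WE03", "WE04")))

  qc_metrics <- data.frame(
    sample_id = samples$sample_id,
    tumor_coverage = c(80, 75, 90, 70),
    normal_coverage = c(30, 28, 35, 25),
    snp_correlation = c(0.95, 0.97, 0.92, 0.99),
    stringsAsFactors = FALSE)

  exons <- as_intervals(c("chr1", "chr2"), c(0, 0), c(1e6, 1e6))
  coverage <- stats::setNames(rep(list(exons), 4), samples$sample_id)

  structure(list(samples = samples, variants = variants, cnvs = cnvs,
                 neoantigens = neoantigens, hla_genotypes = hla_genotypes,
                 hla_sequences = hla_sequences, clonotypes = clonotypes,
                 fusions = fusions, expression = expression,
                 qc_metrics = qc_metrics, exons = exons,
                 coverage = coverage),
            class = "ici_cohort")
}

#' Expected worked-example feature matrices
#'
#' The manually derived biomarker values for the [generate_worked_example()]
#' cohort, as shipped.
#'
#' @return list with `dna` and `rna` matrices
#' @export
worked_example_expected <- function() {
  list(dna = read_feature_matrix(extdata("worked_example_dna.tsv")),
       rna = read_feature_matrix(extdata("worked_example_rna.tsv")))
}
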