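fx <- ici_fixtures()

test_that("mutation burdens divide qualifying counts by target megabases", {
  expect_equal(mutation_burden(make_variants(character(0)), 10), 0)
  v35 <- make_variants(rep("missense", 35))
  expect_equal(mutation_burden(v35, 35, "missense"), 1)
  mixed <- make_variants(c(rep("missense", 4), rep("synonymous", 2)))
  expect_equal(mutation_burden(mixed, 2, ns_tmb_classes()), 2)
  expect_error(mutation_burden(mixed, 0), "positive")
})

test_that("burdens are additive over disjoint variant sets and nested by class", {
  set.seed(14)
  for (i in 1:8) {
    a <- make_variants(sample(iciomics:::CONSEQUENCE_LEVELS, 12, TRUE))
    b <- make_variants(sample(iciomics:::CONSEQUENCE_LEVELS, 7, TRUE))
    expect_equal(mutation_burden(rbind(a, b), 3),
                 mutation_burden(a, 3) + mutation_burden(b, 3))
    expect_gte(mutation_burden(a, 3, ns_tmb_classes()),
               mutation_burden(a, 3, "missense"))
    expect_gte(mutation_burden(a, 3, ns_tmb_classes()),
               mutation_burden(a, 3, "frameshift"))
  }
})

test_that("frameshift proportion over protein-altering variants", {
  expect_equal(frameshift_proportion(make_variants(character(0))), 0)
  v <- make_variants(c(rep("frameshift", 2), rep("missense", 6)))
  expect_equal(frameshift_proportion(v), 0.25)
  expect_equal(frameshift_proportion(make_variants(rep("frameshift", 3))), 1)
  # synonymous variants do not enter the denominator
  v2 <- make_variants(c("frameshift", "synonymous", "synonymous"))
  expect_equal(frameshift_proportion(v2), 1)
})

test_that("dN/dS uses pseudocount-stabilised SNV counts", {
  v <- make_variants(c(rep("missense", 10), rep("synonymous", 5)))
  expect_equal(dnds_ratio(v), 11 / 6)
  expect_equal(dnds_ratio(make_variants(character(0))), 1)
  expect_equal(dnds_ratio(make_variants(rep("synonymous", 9))), 0.1)
  # indels are not substitutions
  fs <- make_variant(consequence = "frameshift", ref = "AT", alt = "A")
  expect_equal(dnds_ratio(fs), 1)
})

test_that("CNV and deletion burden are target-overlap fractions", {
  target <- as_intervals("chr1", 0, 1000)
  expect_equal(unname(cnv_burdens(no_segments(), target)), c(0, 0))
  del <- make_segment(start = 0, end = 500, copy_number = 1)
  expect_equal(cnv_burdens(del, target),
               c(cnv_burden = 0.5, deletion_burden = 0.5))
  amp <- make_segment(start = 0, end = 500, copy_number = 5)
  expect_equal(cnv_burdens(amp, target),
               c(cnv_burden = 0.5, deletion_burden = 0))
  # overlapping segments are not double-counted
  both <- rbind(make_segment(start = 0, end = 600, copy_number = 1),
                make_segment(start = 300, end = 800, copy_number = 4))
  expect_equal(cnv_burdens(both, target)[["cnv_burden"]], 0.8)
  expect_error(cnv_burdens(del, GenomicRanges::GRanges()), "empty target")
})

test_that("DAI is the log wildtype/mutant Kd ratio and antisymmetric", {
  expect_equal(dai(500, 50), log(10))
  expect_equal(dai(100, 100), 0)
  expect_equal(dai(50, 500), -log(10))
  expect_error(dai(-1, 50), "positive")
  set.seed(3)
  wt <- rlnorm(20, 5, 1); mut <- rlnorm(20, 5, 1)
  expect_equal(dai(wt, mut), -dai(mut, wt))
})

test_that("neoantigen aggregates match brute-force statistics", {
  expect_true(all(is.na(neoantigen_aggregates(no_neoantigens(), 2)[-1])))
  expect_equal(neoantigen_aggregates(no_neoantigens(), 2)[["neoantigen_burden"]], 0)

  single <- make_neo(wt = 500, mut = 50)
  agg <- neoantigen_aggregates(single, 2)
  expect_equal(agg[["dai_mean"]], log(10))
  expect_equal(agg[["dai_median"]], log(10))
  expect_equal(agg[["dai_max"]], log(10))
  expect_equal(agg[["max_neo_affinity"]], -log(50))

  ten <- do.call(rbind, lapply(1:10, function(i) {
    make_neo(wt = 50 * exp(i), mut = 50)   # DAI = i + log(...) spacing
  }))
  ten$wt_affinity_nM <- ten$mut_affinity_nM * exp(1:10)  # DAI exactly 1..10
  agg10 <- neoantigen_aggregates(ten, 2)
  expect_equal(agg10[["dai_upper_decile"]], 9.1)
  expect_equal(agg10[["dai_median"]], 5.5)
  expect_equal(agg10[["dai_upper_decile"]], oracle_quantile90(1:10))
  expect_equal(agg10[["neoantigen_burden"]], 5)

  # maxima dominate every per-candidate value
  set.seed(4)
  rnd <- do.call(rbind, lapply(1:12, function(i) {
    make_neo(wt = rlnorm(1, 5), mut = rlnorm(1, 5), rp = rexp(1),
             hex = runif(1, 0, 10), dis = runif(1))
  }))
  agg_r <- neoantigen_aggregates(rnd, 1)
  expect_true(all(agg_r[["max_recognition_potential"]] >= rnd$recognition_potential))
  expect_true(all(agg_r[["max_hex"]] >= rnd$hex_score))
  expect_true(all(agg_r[["max_dissimilarity"]] >= rnd$dissimilarity))
  expect_true(all(agg_r[["dai_max"]] >=
                    dai(rnd$wt_affinity_nM, rnd$mut_affinity_nM)))
})

worked_hla <- function(sample_id = "X") {
  data.frame(sample_id = sample_id, locus = c("A", "B", "C"),
             allele1 = c("A*01:01", "B*27:05", "C*07:01"),
             allele2 = c("A*01:01", "B*27:05", "C*07:01"),
             stringsAsFactors = FALSE)
}

test_that("HED is zero for homozygotes and single mismatches scale by 1/length", {
  seqs <- c("A*01:01" = "SAAAAAAAAA", "A*02:01" = "RAAAAAAAAA",
            "B*27:05" = "CCCCCCCCCC", "C*07:01" = "LLLLLLLLLL")
  gm <- fx$grantham
  hom <- worked_hla()
  expect_equal(hed_mean(hom, seqs, gm), 0)
  het <- hom
  het$allele2[1] <- "A*02:01"
  expect_equal(hed_mean(het, seqs, gm), gm["S", "R"] / 10 / 3)
  # allele order is immaterial
  swapped <- het
  swapped[1, c("allele1", "allele2")] <- het[1, c("allele2", "allele1")]
  expect_equal(hed_mean(swapped, seqs, gm), hed_mean(het, seqs, gm))
  # aligned lengths are enforced
  seqs_bad <- seqs
  seqs_bad[["A*02:01"]] <- "RAAAA"
  expect_error(hed_mean(het, seqs_bad, gm), "length")
})

test_that("HLA supertype and homozygosity flags follow the shipped table", {
  g <- data.frame(sample_id = "X", locus = c("A", "B", "C"),
                  allele1 = c("A*01:01", "B*27:05", "C*07:01"),
                  allele2 = c("A*02:01", "B*44:02", "C*07:01"),
                  stringsAsFactors = FALSE)
  f <- hla_flags(g, fx$supertypes)
  expect_equal(unname(f), c(TRUE, TRUE, FALSE, FALSE, TRUE))
  g$allele2[3] <- "C*07:02"
  expect_false(hla_flags(g, fx$supertypes)[["hom_hla_c"]])
})

test_that("gene alteration flags implement the per-gene rule classes", {
  none <- gene_alteration_flags(make_variants(character(0)), no_segments(),
                                fx$rules, fx$gene_regions, fx$chr6p21)
  expect_false(any(none))

  b2m <- gene_alteration_flags(
    make_variant(gene = "B2M", consequence = "frameshift"),
    no_segments(), fx$rules, fx$gene_regions, fx$chr6p21)
  expect_true(b2m[["alt_b2m"]])
  expect_false(b2m[["response_pathway"]])

  # a deletion over chr6p21.3 triggers only the response pathway
  del6 <- gene_alteration_flags(
    make_variants(character(0)),
    make_segment(chrom = "chr6", start = 29e6, end = 30e6, copy_number = 1),
    fx$rules, fx$gene_regions, fx$chr6p21)
  expect_true(del6[["response_pathway"]])
  expect_false(any(del6[names(del6) != "response_pathway"]))

  # amplification class needs copy number >= 4 over the gene body
  amp3 <- gene_alteration_flags(
    make_variants(character(0)),
    make_segment(chrom = "chr12", start = 68808000, end = 68851000,
                 copy_number = 3),
    fx$rules, fx$gene_regions, fx$chr6p21)
  expect_false(amp3[["alt_mdm2"]])
  amp5 <- gene_alteration_flags(
    make_variants(character(0)),
    make_segment(chrom = "chr12", start = 68808000, end = 68851000,
                 copy_number = 5),
    fx$rules, fx$gene_regions, fx$chr6p21)
  expect_true(amp5[["alt_mdm2"]])

  # synonymous changes never qualify
  syn <- gene_alteration_flags(
    make_variant(gene = "KRAS", consequence = "synonymous"),
    no_segments(), fx$rules, fx$gene_regions, fx$chr6p21)
  expect_false(syn[["alt_kras"]])
})

test_that("rules naming genes without coordinates are rejected at load", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tclass", "NOSUCHGENE\tlof"), path)
  expect_error(resistance_rules(path), "coordinates")
})

test_that("BRAF V600E detection is an exact protein-change match", {
  expect_true(braf_v600e(make_variant(gene = "BRAF",
                                      protein_change = "V600E")))
  expect_true(braf_v600e(make_variant(gene = "BRAF",
                                      protein_change = "p.V600E")))
  expect_false(braf_v600e(make_variant(gene = "BRAF",
                                       protein_change = "V600K")))
  expect_false(braf_v600e(make_variants(character(0))))
})

test_that("the per-sample DNA feature vector is complete and deterministic", {
  target <- as_intervals("chr1", 0, 2e6)
  seqs <- c("A*01:01" = "SAAAAAAAAA", "B*27:05" = "CCCCCCCCCC",
            "C*07:01" = "LLLLLLLLLL")
  base <- compute_dna_features(
    variants = make_variants(character(0)), segments = no_segments(),
    neoantigens = no_neoantigens(), hla_genotype = worked_hla(),
    hla_sequences = seqs, tumor_purity = 0.5, target = target,
    fixtures = fx)
  expect_equal(names(base), dna_feature_names())
  burdens <- c("ns_tmb", "indel_burden", "fsindel_burden", "inframe_burden",
               "splice_burden", "missense_burden", "synonymous_burden",
               "multi_aa_burden", "cnv_burden", "deletion_burden")
  expect_true(all(base[burdens] == 0))
  expect_equal(base[["hed_mean"]], 0)
  expect_equal(base[["dnds_ratio"]], 1)

  v <- make_variants(c("missense", "frameshift", "synonymous", "splice"))
  full <- compute_dna_features(v, no_segments(), no_neoantigens(),
                               worked_hla(), seqs, 0.5, target, fx)
  shuffled <- compute_dna_features(v[c(3, 1, 4, 2), ], no_segments(),
                                   no_neoantigens(), worked_hla(), seqs,
                                   0.5, target, fx)
  expect_identical(full, shuffled)

  # doubling the target halves every per-Mb burden exactly
  double <- compute_dna_features(v, no_segments(), no_neoantigens(),
                                 worked_hla(), seqs, 0.5,
                                 as_intervals(c("chr1", "chr2"), c(0, 0),
                                              c(2e6, 2e6)), fx)
  per_mb <- c("ns_tmb", "indel_burden", "fsindel_burden", "missense_burden",
              "synonymous_burden", "splice_burden")
  expect_equal(unname(double[per_mb]), unname(full[per_mb]) / 2)
  expect_error(compute_dna_features(NULL, no_segments(), no_neoantigens(),
                                    worked_hla(), seqs, 0.5, target, fx),
               "variants")
})
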