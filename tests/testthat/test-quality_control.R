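test_that("sample QC applies the 60x/20x/0.8 thresholds inclusively", {
  metrics <- data.frame(
    sample_id = paste0("S", 1:5),
    tumor_coverage = c(65, 59, 65, 60, NA),
    normal_coverage = c(25, 25, 25, 20, 25),
    snp_correlation = c(0.95, 0.95, 0.79, 0.8, 0.95))
  qc <- sample_qc(metrics)
  expect_equal(qc$passed, c(TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(qc$reasons[2], "tumor_coverage")
  expect_equal(qc$reasons[3], "snp_correlation")
  expect_equal(qc$reasons[5], "missing_tumor_coverage")
})

test_that("variant filter applies the four QC rules with boundary values", {
  v <- rbind(
    make_variant(tumor_depth = 30, normal_depth = 30, tumor_vaf = 0.10,
                 normal_vaf = 0.01, alt_reads = 5),
    make_variant(tumor_vaf = 0.04),
    make_variant(tumor_vaf = 0.10, normal_vaf = 0.02),
    make_variant(tumor_depth = 20),
    make_variant(normal_depth = 20),
    make_variant(alt_reads = 2),
    make_variant(tumor_vaf = 0.05))   # inclusive lower bound
  res <- filter_variants(v)
  expect_equal(nrow(res$kept), 2)
  # 0.02 >= 0.17 * 0.10, so the normal shows too much signal
  expect_equal(res$removed$reason,
               c("vaf", "normal_vaf", "tumor_depth", "normal_depth",
                 "alt_reads"))
})

test_that("variant filtering is idempotent", {
  set.seed(8)
  v <- make_variants(sample(c("missense", "synonymous"), 40, TRUE))
  v$tumor_depth <- sample(10:60, 40, TRUE)
  v$tumor_vaf <- runif(40, 0, 0.3)
  v$normal_vaf <- runif(40, 0, 0.05)
  v$alt_reads <- sample(1:20, 40, TRUE)
  once <- filter_variants(v)$kept
  twice <- filter_variants(once)$kept
  expect_identical(once, twice)
})

test_that("CNV segments below log-likelihood 100 are discarded", {
  segs <- rbind(make_segment(loglik = 150), make_segment(loglik = 99.9),
                make_segment(loglik = 100))
  expect_equal(filter_cnvs(segs)$loglik, c(150, 100))
  expect_equal(nrow(filter_cnvs(no_segments())), 0)
})

test_that("duplicate patient samples keep the greatest accession", {
  s <- data.frame(patient_id = c("p1", "p1", "p2"),
                  accession = c("SRR100", "SRR200", "SRR050"),
                  stringsAsFactors = FALSE)
  out <- dedupe_patient_samples(s)
  expect_setequal(out$accession, c("SRR200", "SRR050"))
})

test_that("target region uses majority coverage within padded exons", {
  exons <- as_intervals("chr1", 0, 1000)
  t1 <- as_intervals("chr1", 0, 600)
  t2 <- as_intervals("chr1", 400, 1000)
  # base 100 covered in 1 of 2 tracks: 1 >= ceiling(2/2), included
  tr <- build_target_region(list(t1, t2), exons)
  expect_equal(interval_size(tr), 1000)
  # 1 of 3 tracks is below ceiling(3/2) = 2
  tr3 <- build_target_region(list(t1, t2, as_intervals("chr1", 400, 600)),
                             exons)
  expect_equal(interval_size(tr3), 200)
  # full coverage outside the padded exons contributes nothing
  far <- as_intervals("chr1", 5000, 6000)
  tr_far <- build_target_region(list(far), exons)
  expect_equal(interval_size(tr_far), 0)
  # padding pulls in +/- 2 bases around the exons
  tr_pad <- build_target_region(list(as_intervals("chr1", 0, 2000)), exons)
  expect_equal(interval_size(tr_pad), 1002)
  expect_error(build_target_region(list(), exons), "track")
})

test_that("adding covered bases never shrinks the target region", {
  set.seed(11)
  exons <- as_intervals("chr1", 0, 5000)
  for (i in 1:5) {
    tracks <- lapply(1:4, function(j) {
      st <- sort(sample(seq(0, 4800, 100), 5))
      as_intervals("chr1", st, st + sample(50:200, 5))
    })
    before <- interval_size(build_target_region(tracks, exons))
    tracks[[1]] <- interval_union(tracks[[1]], as_intervals("chr1", 0, 3000))
    after <- interval_size(build_target_region(tracks, exons))
    expect_gte(after, before)
  }
})

test_that("cohort region intersection behaves as a set intersection", {
  a <- as_intervals("chr1", 0, 10)
  expect_equal(interval_size(intersect_cohort_regions(list(a, a))), 10)
  b <- as_intervals("chr1", 20, 30)
  expect_equal(interval_size(
    suppressMessages(intersect_cohort_regions(list(a, b)))), 0)
  c2 <- as_intervals("chr1", 5, 15)
  got <- intersect_cohort_regions(list(a, c2))
  expect_equal(GenomicRanges::start(got), 6)
  expect_equal(GenomicRanges::end(got), 10)
})

test_that("batch correction removes a constant location shift", {
  set.seed(21)
  n_gene <- 30
  base <- matrix(rep(runif(n_gene, 2, 6), 8), n_gene, 8)
  # identical within-batch profiles across genes and one common shift, so
  # the empirical-Bayes shrinkage is exact in the location-only limit
  pattern <- c(-1.5, -0.5, 0.5, 1.5)
  logx <- base
  logx[, 1:4] <- logx[, 1:4] + matrix(pattern, n_gene, 4, byrow = TRUE)
  logx[, 5:8] <- logx[, 5:8] + matrix(pattern, n_gene, 4, byrow = TRUE) + 2
  tpm <- 2^logx - 1
  rownames(tpm) <- paste0("G", 1:n_gene)
  colnames(tpm) <- paste0("S", 1:8)
  batches <- rep(c("b1", "b2"), each = 4)
  corrected <- correct_batch(tpm, batches)
  logc <- log2(corrected + 1)
  diffs <- rowMeans(logc[, 1:4]) - rowMeans(logc[, 5:8])
  expect_lt(max(abs(diffs)), 1e-6)
  # grand means survive the adjustment
  expect_equal(rowMeans(logc), rowMeans(log2(tpm + 1)), tolerance = 1e-6)
})

test_that("batch correction edge cases", {
  tpm <- matrix(runif(40, 1, 10), 10, 4,
                dimnames = list(paste0("G", 1:10), paste0("S", 1:4)))
  expect_identical(correct_batch(tpm, rep("one", 4)), tpm)
  expect_error(correct_batch(tpm, c("a", "a", "a", "b")), "single sample")
})

test_that("batch correction reduces batch-explained expression variance", {
  out <- generate_cohort(cohort_config(n_total = 60, seed = 13))
  co <- out$cohort
  expr <- co$expression
  batches <- co$samples$sub_cohort[match(colnames(expr), co$samples$sample_id)]
  frac_var <- function(m) {
    pc1 <- prcomp(t(log2(m + 1)), center = TRUE, scale. = FALSE)$x[, 1]
    summary(lm(pc1 ~ batches))$r.squared
  }
  corrected <- correct_batch(expr, batches)
  expect_lt(frac_var(corrected), frac_var(expr))
})
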