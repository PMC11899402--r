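test_that("RECIST codes map onto the responder dichotomy", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\trecist\tsub_cohort\thas_wes\thas_rna\ttumor_purity",
               "P1\tPR\tA\tTRUE\tTRUE\t0.5",
               "P2\tSD\tA\tTRUE\tFALSE\t0.6",
               "P3\tCR\tA\tFALSE\tTRUE\tNA",
               "P4\tMR\tA\tFALSE\tTRUE\tNA",
               "P5\tPD\tA\tTRUE\tTRUE\t0.7"), path)
  sheet <- read_sample_sheet(path)
  expect_equal(sheet$response,
               c("responder", "non_responder", "responder",
                 "non_responder", "non_responder"))
})

test_that("sample sheet validation rejects bad rows and empty files pass", {
  path <- withr::local_tempfile(fileext = ".tsv")
  file.create(path)
  expect_equal(nrow(read_sample_sheet(path)), 0)

  writeLines(c("sample_id\trecist\tsub_cohort\thas_wes\thas_rna\ttumor_purity",
               "P1\tPR\tA\tTRUE\tTRUE\t0.5",
               "P1\tSD\tA\tTRUE\tTRUE\t0.5"), path)
  expect_error(read_sample_sheet(path), "duplicate")

  writeLines(c("sample_id\trecist\tsub_cohort\thas_wes\thas_rna\ttumor_purity",
               "P1\tXX\tA\tTRUE\tTRUE\t0.5"), path)
  expect_error(read_sample_sheet(path), "RECIST")

  writeLines(c("sample_id\trecist\tsub_cohort\thas_wes\thas_rna\ttumor_purity",
               "P1\tPR\tA\tTRUE\tTRUE\t0.5",
               "P2\t\tA\tTRUE\tTRUE\t0.5"), path)
  expect_warning(sheet <- read_sample_sheet(path), "without a response")
  expect_equal(sheet$sample_id, "P1")

  writeLines(c("sample_id\trecist\tsub_cohort\thas_wes\thas_rna\ttumor_purity",
               "P1\tPR\tA\tTRUE\tTRUE\t"), path)
  expect_error(read_sample_sheet(path), "tumor_purity")
})

test_that("annotation terms map to consequence classes by the fixed table", {
  expect_equal(map_consequence("missense_variant"), "missense")
  expect_equal(map_consequence("synonymous_variant"), "synonymous")
  expect_equal(map_consequence(c("inframe_deletion", "frameshift_variant",
                                 "splice_acceptor_variant",
                                 "splice_region_variant")),
               c("inframe_indel", "frameshift", "splice", "other"))
  # a missense spanning several residues is a multi-amino-acid change
  expect_equal(map_consequence("missense_variant", "A5_K6delinsFL"),
               "multi_aa")
  expect_warning(out <- map_consequence("made_up_term"), "unknown")
  expect_equal(out, "other")
})

test_that("variant tables round-trip and reject malformed VAFs", {
  v <- make_variants(c("missense", "synonymous", "frameshift"))
  # a 3-codon deletion preserving the frame: length difference 9
  v$ref[3] <- "TAAAGGGCCC"
  v$alt[3] <- "T"
  v$consequence[3] <- "inframe_deletion"
  path <- withr::local_tempfile(fileext = ".tsv")
  write_variant_table(v, path)
  back <- read_variant_table(path)
  expect_equal((nchar(back$ref[3]) - nchar(back$alt[3])) %% 3, 0)
  expect_equal(back$consequence[3], "inframe_indel")
  expect_equal(back$tumor_vaf, v$tumor_vaf)

  v$tumor_vaf[2] <- 1.4
  write_variant_table(v, path)
  expect_error(read_variant_table(path), "row 2")
})

test_that("interval sets obey BED half-open arithmetic", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t0\t10", path)
  expect_equal(interval_size(read_intervals(path)), 10)

  writeLines(c("chr1\t0\t10", "chr1\t5\t15"), path)
  expect_equal(interval_size(read_intervals(path)), 15)

  file.create(path)
  writeLines(character(0), path)
  expect_equal(interval_size(read_intervals(path)), 0)

  writeLines("chr1\t10\t10", path)
  expect_error(read_intervals(path), "start")
})

test_that("interval union and intersection sizes are complementary", {
  set.seed(5)
  for (i in 1:10) {
    a <- as_intervals(rep("chr1", 4), st <- sort(sample(0:100, 4)) * 10,
                      st * 10 + sample(5:80, 4))
    b <- as_intervals(rep("chr1", 4), st2 <- sort(sample(0:100, 4)) * 10,
                      st2 * 10 + sample(5:80, 4))
    expect_equal(interval_size(interval_union(a, b)) +
                   interval_size(interval_intersect(a, b)),
                 interval_size(a) + interval_size(b))
  }
})

test_that("every table type round-trips through its writer bit-for-bit", {
  dir <- withr::local_tempdir()
  out <- generate_cohort(cohort_config(n_total = 16, seed = 3), dir = dir)
  back <- read_cohort(dir)
  expect_equal(back$samples$response, out$cohort$samples$response)
  expect_equal(back$variants$pos, out$cohort$variants$pos)
  expect_equal(back$variants$tumor_vaf, out$cohort$variants$tumor_vaf)
  expect_equal(back$cnvs$loglik, out$cohort$cnvs$loglik)
  expect_equal(back$clonotypes$read_count, out$cohort$clonotypes$read_count)
  expect_equal(back$hla_sequences, out$cohort$hla_sequences)
  expect_equal(dim(back$expression), dim(out$cohort$expression))
  expect_equal(unname(back$expression), unname(out$cohort$expression),
               tolerance = 1e-7)
  expect_equal(interval_size(back$exons), interval_size(out$cohort$exons))
  expect_equal(length(back$coverage), sum(out$cohort$samples$has_wes))
})
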