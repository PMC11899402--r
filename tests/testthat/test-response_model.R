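test_that("z-transform uses population moments and survives flat features", {
  X <- cbind(a = c(0, 2), b = c(5, 5))
  expect_message(std <- standardize_fit(X), "zero-variance")
  Z <- standardize_apply(std, X)
  expect_equal(unname(Z[, "a"]), c(-1, 1))
  expect_equal(unname(Z[, "b"]), c(0, 0))

  set.seed(2)
  X2 <- matrix(rnorm(50), 10, 5, dimnames = list(NULL, letters[1:5]))
  std2 <- standardize_fit(X2)
  Z2 <- standardize_apply(std2, X2)
  expect_true(all(abs(colMeans(Z2)) < 1e-12))
  expect_error(standardize_apply(std2, X2[, 5:1]), "feature names")
})

test_that("the penalised fit collapses and relaxes as the penalty dictates", {
  set.seed(31)
  n <- 80
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  X <- scale(X, scale = apply(X, 2, function(x) sqrt(mean((x - mean(x))^2))))
  y <- as.numeric(X[, 2] > 0)

  hard <- fit_lasso_cv(X, y, seed = 1, alpha = 100)
  expect_true(all(hard$coefficients == 0))
  expect_equal(hard$intercept, mean(y))

  soft <- fit_lasso_cv(X, y, seed = 1, alpha = 1e-5)
  ols <- coef(lm(y ~ X[, 2]))
  expect_equal(soft$coefficients[["f2"]], ols[[2]], tolerance = 1e-2)
  expect_lt(max(abs(soft$coefficients[c("f1", "f3", "f4", "f5")])), 0.05)

  expect_error(fit_lasso_cv(X, rep(1, n)), "both classes")
})

test_that("cross-validated fits are deterministic under a fixed seed", {
  d <- toy_model_data(n = 70)
  m1 <- train_model(d$X, d$y, seed = 5)
  m2 <- train_model(d$X, d$y, seed = 5)
  expect_identical(m1$coefficients, m2$coefficients)
  expect_identical(m1$alpha, m2$alpha)
  d2 <- list(X = rbind(d$X, d$X[1, , drop = FALSE]), y = c(d$y, d$y[1]))
  rownames(d2$X) <- NULL
  m3 <- train_model(d2$X, d2$y, seed = 5)
  m4 <- train_model(d2$X, d2$y, seed = 5)
  expect_identical(m3$coefficients, m4$coefficients)
})

test_that("the number of active coefficients shrinks monotonically in alpha", {
  d <- toy_model_data(n = 60, p = 6)
  Z <- scale(d$X)
  alphas <- exp(seq(log(1e-4), log(1), length.out = 12))
  nz <- vapply(alphas, function(a) {
    sum(fit_lasso_cv(Z, d$y, alpha = a)$coefficients != 0)
  }, numeric(1))
  expect_true(all(diff(nz) <= 0))
})

test_that("rank-statistic AUC equals pairwise comparison on small instances", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(c(0.2, 0.8), c(1, 0)), 0)
  set.seed(12)
  for (i in 1:20) {
    n <- sample(6:50, 1)
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # forces ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    expect_equal(roc_auc(scores, labels), oracle_auc(scores, labels))
  }
  # large-sample independence gives chance performance
  set.seed(13)
  s <- rnorm(4000); l <- rbinom(4000, 1, 0.4)
  expect_lt(abs(roc_auc(s, l) - 0.5), 0.05)
})

test_that("rank AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(17)
  for (i in 1:5) {
    scores <- rnorm(40)
    labels <- rbinom(40, 1, 0.5)
    if (length(unique(labels)) < 2) next
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(roc_auc(scores, labels), ref)
  }
})

test_that("Youden threshold equals exhaustive search", {
  expect_equal(youden_threshold(c(0.1, 0.4, 0.6, 0.9), c(0, 0, 1, 1)), 0.5)
  # perfectly separated scores sit at the gap midpoint with J = 1
  expect_equal(youden_threshold(c(1, 2, 10, 11), c(0, 0, 1, 1)), 6)
  # degenerate scores carry no information
  expect_equal(youden_threshold(rep(0.3, 6), c(0, 1, 0, 1, 0, 1)), 0.3)
  expect_error(youden_threshold(1:4, rep(1, 4)), "both classes")
  set.seed(15)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    scores <- round(runif(n), 2)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    got <- youden_threshold(scores, labels)
    ora <- oracle_youden(scores, labels)
    sens <- sum(scores >= got & labels == 1) / sum(labels == 1)
    spec <- sum(scores < got & labels == 0) / sum(labels == 0)
    expect_equal(sens + spec - 1, ora$j)
    expect_equal(got, ora$threshold)
  }
})

test_that("permutation importance isolates predictive features", {
  set.seed(41)
  n <- 150
  X <- cbind(signal = rnorm(n), noise1 = rnorm(n), noise2 = rnorm(n))
  rownames(X) <- sprintf("P%03d", 1:n)
  y <- as.numeric(X[, "signal"] + rnorm(n, 0, 0.4) > 0)
  m <- train_model(X, y, seed = 2)
  imp <- permutation_importance(m, X, y, repeats = 20, seed = 3)
  expect_equal(imp$feature[which.max(imp$mean_importance)], "signal")
  expect_gt(max(imp$mean_importance), 0.1)
  noise_rows <- imp[imp$feature != "signal", ]
  # pure-noise features sit within 2 sd of zero importance (when active at all)
  expect_true(all(abs(noise_rows$mean_importance) <=
                    pmax(2 * noise_rows$sd_importance, 1e-8)))
  # zero-coefficient features are never permuted into effect
  zero <- imp[imp$coefficient == 0, ]
  expect_true(all(zero$mean_importance == 0))
  expect_true(all(zero$sd_importance == 0))
  expect_error(permutation_importance(m, X, y, repeats = 1), "at least 2")
})

test_that("the importance gate is strict and deterministically ordered", {
  imp <- data.frame(feature = c("a", "b", "c", "d"),
                    coefficient = c(1, 1, 1, 0),
                    mean_importance = c(0.02, 0.0055, 0.001, 0.9),
                    sd_importance = 0)
  expect_equal(select_features(imp, 0.0055), "a")
  imp2 <- data.frame(feature = c("b", "a"), coefficient = 1,
                     mean_importance = c(0.02, 0.02), sd_importance = 0)
  expect_equal(select_features(imp2, 0.0055), c("a", "b"))
  imp3 <- data.frame(feature = "a", coefficient = 1,
                     mean_importance = 0.001, sd_importance = 0)
  expect_error(select_features(imp3), "threshold")
})

test_that("evaluation reports model and nsTMB baseline on shared samples", {
  d <- toy_model_data(n = 80)
  m <- train_model(d$X, d$y, seed = 9)
  nstmb <- abs(d$X[, 1]) * 8
  ev <- evaluate(m, d$X, d$y, nstmb)
  expect_gt(ev$auc, 0.8)
  expect_equal(ev$baseline_auc, roc_auc(nstmb, d$y))
  expect_equal(sum(ev$confusion), length(d$y))
  expect_equal(sum(ev$baseline_confusion_at_10), length(d$y))
  # samples without WES drop out of the baseline only
  nstmb2 <- nstmb; nstmb2[1:10] <- NA
  ev2 <- evaluate(m, d$X, d$y, nstmb2)
  expect_equal(ev2$auc, ev$auc)
  expect_equal(ev2$baseline_n, 70)
})

test_that("stratified split holds out paired samples proportionately", {
  set.seed(77)
  n <- 120
  samples <- data.frame(
    sample_id = sprintf("S%03d", 1:n),
    response = sample(c("responder", "non_responder"), n, TRUE),
    has_wes = TRUE, has_rna = rep(c(TRUE, FALSE), c(100, 20)),
    stringsAsFactors = FALSE)
  nstmb <- setNames(rlnorm(n, log(6), 1), samples$sample_id)
  sp <- split_cohort(samples, nstmb, test_fraction = 0.2, seed = 4)
  test <- sp$split == "test"
  expect_equal(sum(test), 20)
  expect_true(all(sp$has_rna[test]))
  sp2 <- split_cohort(samples, nstmb, test_fraction = 0.2, seed = 4)
  expect_identical(sp$split, sp2$split)
  # responder share in the test set tracks the paired cohort share
  paired <- samples$has_wes & samples$has_rna
  for (resp in c("responder", "non_responder")) {
    for (bin in c(TRUE, FALSE)) {
      in_stratum <- paired & sp$response == resp &
        (nstmb[sp$sample_id] >= 10) == bin
      expect_lte(abs(sum(in_stratum & test) - 0.2 * sum(in_stratum)), 1)
    }
  }
})

test_that("model bundles survive JSON serialization", {
  d <- toy_model_data(n = 50)
  m <- train_model(d$X, d$y, seed = 21)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  back <- read_model(path)
  expect_equal(predict(back, d$X), predict(m, d$X))
  expect_equal(back$prob_threshold, m$prob_threshold)
  expect_equal(back$alpha, m$alpha)
})

test_that("the cascade trains on availability-consistent sample sets", {
  set.seed(55)
  n <- 90
  ids <- sprintf("C%03d", 1:n)
  dna_X <- matrix(rnorm(n * 6), n, 6,
                  dimnames = list(ids, paste0("d", 1:6)))
  rna_ids <- ids[1:60]
  rna_X <- matrix(rnorm(60 * 3), 60, 3,
                  dimnames = list(rna_ids, paste0("r", 1:3)))
  y <- setNames(as.numeric(dna_X[, 1] + c(rna_X[, 1], rep(0, 30)) +
                             rnorm(n, 0, 0.5) > 0), ids)
  casc <- train_cascade(dna_X, rna_X, y, rna_ids,
                        cascade_config(seed = 3, repeats = 10))
  expect_s3_class(casc$dna, "ici_model")
  expect_true(all(casc$selected_dna %in% colnames(dna_X)))
  expect_true(all(casc$selected_rna %in% colnames(rna_X)))
  # multi-omics predictions exist exactly for paired samples
  mm <- multiomics_matrix(casc, dna_X, rna_X, rna_ids)
  expect_equal(rownames(mm), rna_ids)
  expect_equal(length(predict(casc$multi, mm)), length(rna_ids))
  expect_error(train_cascade(dna_X, rna_X, y, rna_ids[1:5],
                             cascade_config(seed = 3)), "2 x folds")
  # determinism end to end
  casc2 <- train_cascade(dna_X, rna_X, y, rna_ids,
                         cascade_config(seed = 3, repeats = 10))
  expect_identical(casc$multi$coefficients, casc2$multi$coefficients)
})
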