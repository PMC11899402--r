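#' @importFrom glmnet glmnet cv.glmnet
#' @importFrom stats coef median predict quantile setNames var
NULL

# Run code with a temporarily seeded RNG, restoring global state after.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Feature standardization (z-transform)
#'
#' Fits per-feature centre and scale on training data (population
#' standard deviation, so two values 0 and 2 map to -1 and +1).
#' Zero-variance features are centred and given scale 1.
#'
#' @param X numeric matrix, samples x features
#' @return list with `feature_names`, `center`, `scale`
#' @export
standardize_fit <- function(X) {
  if (nrow(X) < 2) stop("need at least two samples to standardize")
  ctr <- colMeans(X)
  sc <- sqrt(colMeans(sweep(X, 2L, ctr)^2))
  flat <- sc == 0 | !is.finite(sc)
  if (any(flat)) {
    message("zero-variance feature(s) scaled by 1: ",
            paste(colnames(X)[flat], collapse = ", "))
    sc[flat] <- 1
  }
  list(feature_names = colnames(X), center = ctr, scale = sc)
}

#' @rdname standardize_fit
#' @param params standardization parameters from `standardize_fit`
#' @export
standardize_apply <- function(params, X) {
  if (!identical(colnames(X), params$feature_names)) {
    stop("feature names do not match the standardization parameters")
  }
  scale(X, center = params$center, scale = params$scale)[, , drop = FALSE]
}

impute_fit <- function(X) {
  med <- apply(X, 2L, median, na.rm = TRUE)
  med[!is.finite(med)] <- 0
  med
}

impute_apply <- function(medians, X) {
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- medians[[colnames(X)[j]]]
  }
  X
}

#' Fit an L1-penalised least-squares model with cross-validated penalty
#'
#' LASSO on the 0/1 response with the penalty chosen by minimising mean
#' squared error over a geometric grid of `n_lambda` points spanning
#' [1e-4, 1] times the smallest penalty that zeroes every coefficient,
#' using `folds`-fold cross-validation with a seeded fold assignment.
#' Fitted values serve as response scores; they are clipped to [0,1]
#' only for display, never before AUC computation.
#'
#' @param X standardized feature matrix, samples x features
#' @param y binary 0/1 labels
#' @param folds number of CV folds (default 5)
#' @param seed RNG seed for the fold shuffle
#' @param n_lambda grid resolution
#' @param alpha optional fixed penalty; skips cross-validation
#' @return an `ici_model` bundle (no standardization attached)
#' @export
fit_lasso_cv <- function(X, y, folds = 5, seed = 1, n_lambda = 100,
                         alpha = NULL) {
  if (length(unique(y)) < 2) stop("both classes must be present in y")
  y <- as.numeric(y)
  # glmnet requires >= 2 columns; pad single-feature problems with a dead
  # column that is removed again below
  padded <- ncol(X) == 1
  if (padded) X <- cbind(X, `..pad..` = 0)
  lam_max <- max(abs(crossprod(X, y - mean(y)))) / nrow(X)
  if (!is.finite(lam_max) || lam_max <= 0) lam_max <- 1
  grid <- exp(seq(log(lam_max), log(lam_max * 1e-4), length.out = n_lambda))
  if (is.null(alpha)) {
    foldid <- with_seed(seed, sample(rep(seq_len(folds), length.out = nrow(X))))
    cv <- cv.glmnet(X, y, family = "gaussian", lambda = grid,
                    foldid = foldid, standardize = FALSE)
    alpha <- cv$lambda.min
    fit <- cv$glmnet.fit
  } else {
    fit <- glmnet(X, y, family = "gaussian",
                  lambda = sort(unique(c(grid, alpha)), decreasing = TRUE),
                  standardize = FALSE)
  }
  co <- as.matrix(coef(fit, s = alpha, exact = FALSE))
  if (padded) {
    X <- X[, 1L, drop = FALSE]
    co <- co[rownames(co) != "..pad..", , drop = FALSE]
  }
  structure(list(feature_names = colnames(X),
                 coefficients = setNames(co[-1L, 1L], colnames(X)),
                 intercept = co[1L, 1L],
                 alpha = alpha,
                 cv_folds = folds,
                 prob_threshold = NA_real_,
                 rng_seed = seed),
            class = "ici_model")
}

#' Train a model bundle on raw features
#'
#' Imputes missing values with training medians, fits the z-transform,
#' runs the cross-validated LASSO, and stores the Youden probability
#' threshold derived from the training scores.
#'
#' @param X raw feature matrix, samples x features
#' @param y binary 0/1 labels
#' @inheritParams fit_lasso_cv
#' @return an `ici_model` with standardization, imputation medians and
#'   threshold attached
#' @export
train_model <- function(X, y, folds = 5, seed = 1, n_lambda = 100) {
  medians <- impute_fit(X)
  Xi <- impute_apply(medians, X)
  std <- standardize_fit(Xi)
  Z <- standardize_apply(std, Xi)
  model <- fit_lasso_cv(Z, y, folds = folds, seed = seed, n_lambda = n_lambda)
  model$standardization <- std
  model$impute_medians <- medians
  scores <- drop(Z %*% model$coefficients) + model$intercept
  model$prob_threshold <- youden_threshold(scores, y)
  model
}

#' Predict response scores from a model bundle
#'
#' @param object an `ici_model` from [train_model()]
#' @param newdata raw feature matrix with the model's features
#' @param clip clip scores into [0,1] for display (never done before AUC)
#' @param ... unused
#' @return numeric vector of response scores
#' @export
predict.ici_model <- function(object, newdata, clip = FALSE, ...) {
  if (!identical(colnames(newdata), object$feature_names)) {
    stop("feature mismatch between model and data")
  }
  Z <- standardize_apply(object$standardization,
                         impute_apply(object$impute_medians, newdata))
  scores <- drop(Z %*% object$coefficients) + object$intercept
  if (clip) scores <- pmin(pmax(scores, 0), 1)
  setNames(scores, rownames(newdata))
}

#' @export
print.ici_model <- function(x, ...) {
  nz <- sum(x$coefficients != 0)
  cat("ici_model:", length(x$feature_names), "features,", nz,
      "non-zero coefficients, alpha =", signif(x$alpha, 3),
      ", threshold =", signif(x$prob_threshold, 3), "\n")
  invisible(x)
}

#' ROC AUC from the rank statistic
#'
#' Computed with midranks, equivalent to trapezoidal integration of the
#' ROC curve with tied scores handled by midrank averaging.
#'
#' @param scores continuous classifier scores
#' @param labels binary 0/1 (or logical) labels
#' @return AUC in [0,1]
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels > 0 | labels == TRUE)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes required for AUC")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#' @inheritParams roc_auc
#' @return data.frame with `threshold`, `fpr`, `tpr`
#' @export
roc_points <- function(scores, labels) {
  labels <- as.logical(labels > 0 | labels == TRUE)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- t(vapply(thr, function(t) {
    pred <- scores >= t
    c(fpr = sum(pred & !labels) / sum(!labels),
      tpr = sum(pred & labels) / sum(labels))
  }, c(fpr = 0, tpr = 0)))
  data.frame(threshold = thr, fpr = pts[, "fpr"], tpr = pts[, "tpr"])
}

#' Youden-optimal classification threshold
#'
#' Scans the midpoints between adjacent sorted unique scores and returns
#' the one maximising J = sensitivity + specificity - 1 (prediction rule:
#' score >= threshold is positive). Ties are broken toward the smaller
#' threshold. With fewer than two distinct scores J is 0 and the single
#' score value is returned.
#'
#' @inheritParams roc_auc
#' @return the threshold value
#' @export
youden_threshold <- function(scores, labels) {
  labels <- as.logical(labels > 0 | labels == TRUE)
  if (all(labels) || !any(labels)) stop("both classes required")
  u <- sort(unique(scores))
  if (length(u) < 2) return(u[1])
  mids <- (u[-length(u)] + u[-1]) / 2
  j <- vapply(mids, function(t) {
    sens <- sum(scores >= t & labels) / sum(labels)
    spec <- sum(scores < t & !labels) / sum(!labels)
    sens + spec - 1
  }, numeric(1))
  mids[which.max(j)]
}

#' Permutation feature importance
#'
#' Importance of a feature is the mean drop in ROC AUC when its column is
#' permuted, over `repeats` seeded permutations. Features with a zero
#' coefficient cannot change the score and are reported as exactly 0.
#'
#' @param model an `ici_model`
#' @param X raw feature matrix the model was trained on
#' @param y binary labels
#' @param repeats number of permutations per feature (>= 2)
#' @param seed RNG seed
#' @return data.frame with `feature`, `coefficient`, `mean_importance`,
#'   `sd_importance`, ordered as the model's features
#' @export
permutation_importance <- function(model, X, y, repeats = 30, seed = 1) {
  if (repeats < 2) stop("repeats must be at least 2")
  if (!identical(colnames(X), model$feature_names)) {
    stop("feature mismatch between model and data")
  }
  base_auc <- roc_auc(predict(model, X), y)
  active <- which(model$coefficients != 0)
  mean_imp <- sd_imp <- setNames(numeric(ncol(X)), colnames(X))
  if (length(active)) {
    drops <- with_seed(seed, {
      vapply(active, function(j) {
        vapply(seq_len(repeats), function(r) {
          Xp <- X
          Xp[, j] <- X[sample(nrow(X)), j]
          base_auc - roc_auc(predict(model, Xp), y)
        }, numeric(1))
      }, numeric(repeats))
    })
    mean_imp[active] <- colMeans(drops)
    sd_imp[active] <- apply(drops, 2L, stats::sd)
  }
  data.frame(feature = colnames(X),
             coefficient = unname(model$coefficients),
             mean_importance = unname(mean_imp),
             sd_importance = unname(sd_imp),
             stringsAsFactors = FALSE)
}

#' Gate features by permutation importance
#'
#' Retains features with a non-zero coefficient and mean importance
#' strictly above the threshold, ordered by descending importance with
#' ties broken by feature name.
#'
#' @param importance table from [permutation_importance()]
#' @param threshold importance gate (default 0.0055)
#' @return character vector of selected feature names
#' @export
select_features <- function(importance, threshold = 0.0055) {
  keep <- importance$coefficient != 0 & importance$mean_importance > threshold
  if (!any(keep)) {
    stop("no feature passes the importance gate; review the threshold")
  }
  sel <- importance[keep, , drop = FALSE]
  sel <- sel[order(-sel$mean_importance, sel$feature), , drop = FALSE]
  sel$feature
}

confusion_at <- function(scores, labels, threshold) {
  labels <- as.logical(labels > 0 | labels == TRUE)
  pred <- scores >= threshold
  c(TP = sum(pred & labels), TN = sum(!pred & !labels),
    FP = sum(pred & !labels), FN = sum(!pred & labels))
}

#' Evaluate a model against the nsTMB baseline
#'
#' Computes the ROC curve and AUC of the model's scores, the confusion
#' matrix at the model's stored Youden threshold, the AUC of raw nsTMB as
#' a continuous baseline score on the same samples, and the baseline
#' confusion at the 10 mutations/Mb operating point.
#'
#' @param model an `ici_model`
#' @param X raw feature matrix
#' @param y binary labels
#' @param baseline_nstmb nsTMB values aligned with the rows of `X`
#' @return an `ici_eval` list
#' @export
evaluate <- function(model, X, y, baseline_nstmb) {
  scores <- predict(model, X)
  # RNA-only samples have no nsTMB; the baseline is assessed on the
  # subset with WES data
  has_base <- !is.na(baseline_nstmb)
  structure(list(
    auc = roc_auc(scores, y),
    roc = roc_points(scores, y),
    confusion = confusion_at(scores, y, model$prob_threshold),
    threshold = model$prob_threshold,
    baseline_auc = roc_auc(baseline_nstmb[has_base], y[has_base]),
    baseline_confusion_at_10 = confusion_at(baseline_nstmb[has_base],
                                            y[has_base], 10),
    baseline_n = sum(has_base),
    n = length(y), scores = scores
  ), class = "ici_eval")
}

#' @export
print.ici_eval <- function(x, ...) {
  cat("ici_eval: AUC", round(x$auc, 3), "vs nsTMB", round(x$baseline_auc, 3),
      "on", x$n, "samples\n")
  invisible(x)
}

#' Stratified train/test split
#'
#' Test candidates are restricted to samples with both WES and RNA data
#' so one test set can evaluate all three models. The draw is stratified
#' by response crossed with the nsTMB bin (>= 10 vs < 10 mutations/Mb);
#' strata with fewer than 2 paired samples are merged into the other
#' nsTMB bin of the same response with a warning.
#'
#' @param samples sample sheet data.frame
#' @param nstmb named nsTMB vector (per sample; NA allowed for RNA-only)
#' @param test_fraction fraction of paired samples held out (default 0.2)
#' @param seed RNG seed for the draw
#' @return the sample sheet with `split` set to "train"/"test"
#' @export
split_cohort <- function(samples, nstmb, test_fraction = 0.2, seed = 1) {
  paired <- samples$has_wes & samples$has_rna
  bin <- ifelse(!is.na(nstmb[samples$sample_id]) &
                  nstmb[samples$sample_id] >= 10, "high", "low")
  stratum <- paste(samples$response, bin, sep = ".")
  sizes <- table(stratum[paired])
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("merging small stratum(s) into their response neighbour: ",
            paste(small, collapse = ", "))
    for (s in small) {
      resp <- sub("\\.(high|low)$", "", s)
      other <- paste0(resp, ".", ifelse(grepl("high$", s), "low", "high"))
      stratum[stratum == s] <- other
    }
  }
  samples$split <- "train"
  test_ids <- with_seed(seed, {
    unlist(lapply(unique(stratum[paired]), function(s) {
      ids <- samples$sample_id[paired & stratum == s]
      sample(ids, round(test_fraction * length(ids)))
    }), use.names = FALSE)
  })
  samples$split[samples$sample_id %in% test_ids] <- "test"
  samples
}

#' Cascade configuration defaults
#'
#' @param folds CV folds; @param seed master seed; @param repeats
#'   permutation-importance repeats; @param threshold importance gate;
#'   @param n_lambda penalty grid resolution
#' @return configuration list
#' @export
cascade_config <- function(folds = 5, seed = 1, repeats = 30,
                           threshold = 0.0055, n_lambda = 100) {
  list(folds = folds, seed = seed, repeats = repeats, threshold = threshold,
       n_lambda = n_lambda)
}

#' Train the DNA / RNA / multi-omics model cascade
#'
#' Trains the DNA model on every WES training sample and the RNA model on
#' every RNA training sample, gates each model's features by permutation
#' importance, then trains the multi-omics model on the paired training
#' samples restricted to the union of gated features. Each model stores
#' its own Youden threshold fitted on the training scores.
#'
#' @param dna_X raw DNA feature matrix (WES training samples x features)
#' @param rna_X raw RNA feature matrix (RNA training samples x features)
#' @param labels named binary vector over all training samples
#' @param paired_ids sample ids present in both matrices
#' @param config list from [cascade_config()]
#' @return an `ici_cascade` list: the three models, importance tables and
#'   selected features
#' @export
train_cascade <- function(dna_X, rna_X, labels, paired_ids,
                          config = cascade_config()) {
  if (!all(paired_ids %in% rownames(dna_X)) ||
      !all(paired_ids %in% rownames(rna_X))) {
    stop("paired ids must be training samples of both matrices")
  }
  if (length(paired_ids) < 2 * config$folds) {
    stop("paired training set smaller than 2 x folds")
  }
  seeds <- config$seed + 1:4

  dna_model <- train_model(dna_X, labels[rownames(dna_X)],
                           folds = config$folds, seed = seeds[1],
                           n_lambda = config$n_lambda)
  rna_model <- train_model(rna_X, labels[rownames(rna_X)],
                           folds = config$folds, seed = seeds[2],
                           n_lambda = config$n_lambda)
  imp_dna <- permutation_importance(dna_model, dna_X, labels[rownames(dna_X)],
                                    repeats = config$repeats, seed = seeds[3])
  imp_rna <- permutation_importance(rna_model, rna_X, labels[rownames(rna_X)],
                                    repeats = config$repeats, seed = seeds[3])
  sel_dna <- select_features(imp_dna, config$threshold)
  sel_rna <- select_features(imp_rna, config$threshold)

  multi_X <- cbind(dna_X[paired_ids, sel_dna, drop = FALSE],
                   rna_X[paired_ids, setdiff(sel_rna, sel_dna), drop = FALSE])
  multi_model <- train_model(multi_X, labels[paired_ids],
                             folds = config$folds, seed = seeds[4],
                             n_lambda = config$n_lambda)
  structure(list(dna = dna_model, rna = rna_model, multi = multi_model,
                 importance_dna = imp_dna, importance_rna = imp_rna,
                 selected_dna = sel_dna, selected_rna = sel_rna,
                 config = config),
            class = "ici_cascade")
}

#' Assemble the multi-omics feature matrix for a set of samples
#' @param cascade an `ici_cascade`
#' @param dna_X,rna_X raw feature matrices containing the samples
#' @param ids paired sample ids
#' @return matrix over the cascade's gated features
#' @export
multiomics_matrix <- function(cascade, dna_X, rna_X, ids) {
  cbind(dna_X[ids, cascade$selected_dna, drop = FALSE],
        rna_X[ids, setdiff(cascade$selected_rna, cascade$selected_dna),
              drop = FALSE])
}

#' Serialize a model bundle to JSON
#' @param model an `ici_model`
#' @param path output path
#' @export
write_model <- function(model, path) {
  payload <- unclass(model)
  payload$standardization$center <- as.list(payload$standardization$center)
  payload$standardization$scale <- as.list(payload$standardization$scale)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$coefficients <- unlist(raw$coefficients)
  raw$standardization$center <- unlist(raw$standardization$center)
  raw$standardization$scale <- unlist(raw$standardization$scale)
  raw$impute_medians <- unlist(raw$impute_medians)
  if (is.null(raw$prob_threshold)) raw$prob_threshold <- NA_real_
  structure(raw, class = "ici_model")
}
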