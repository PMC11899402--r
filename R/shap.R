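#' Exact SHAP values for a linear model
#'
#' For a linear model the Shapley decomposition under feature
#' independence has the closed form
#' \eqn{\phi_{ij} = \beta_j (z_{ij} - \bar z_j)} on the standardized
#' scale, with the base value \eqn{\beta_0 + \sum_j \beta_j \bar z_j}
#' taken over the background matrix (the training matrix by default).
#' Local accuracy — base value plus the sum of a sample's SHAP values
#' equals its prediction — holds exactly.
#'
#' @param model an `ici_model`
#' @param X raw feature matrix of the samples to explain
#' @param background raw background matrix (defaults to `X`)
#' @param y optional binary labels; with the model's stored threshold
#'   they assign each sample a TP/TN/FP/FN group
#' @return an `ici_shap` report: `shap` matrix, `base_value`,
#'   `predictions`, `groups`, and the raw inputs for display
#' @export
linear_shap <- function(model, X, background = NULL, y = NULL) {
  if (!identical(colnames(X), model$feature_names)) {
    stop("feature mismatch between model and data")
  }
  if (is.null(background)) background <- X
  if (!identical(colnames(background), model$feature_names)) {
    stop("feature mismatch between model and background")
  }
  zx <- standardize_apply(model$standardization,
                          impute_apply(model$impute_medians, X))
  zb <- standardize_apply(model$standardization,
                          impute_apply(model$impute_medians, background))
  mu <- colMeans(zb)
  phi <- sweep(zx, 2L, mu) %*% diag(model$coefficients, ncol(zx))
  colnames(phi) <- colnames(X)
  rownames(phi) <- rownames(X)
  base_value <- model$intercept + sum(model$coefficients * mu)
  predictions <- base_value + rowSums(phi)
  groups <- NULL
  if (!is.null(y)) {
    if (is.na(model$prob_threshold)) stop("model has no stored threshold")
    pos <- predictions >= model$prob_threshold
    truth <- as.logical(y > 0 | y == TRUE)
    groups <- ifelse(pos & truth, "TP",
                     ifelse(!pos & !truth, "TN",
                            ifelse(pos & !truth, "FP", "FN")))
    names(groups) <- rownames(X)
  }
  structure(list(shap = phi, base_value = base_value,
                 predictions = predictions, groups = groups,
                 feature_names = colnames(X), X = X),
            class = "ici_shap")
}

#' SHAP group differences between true positives and true negatives
#'
#' For every feature, the difference in mean SHAP value between
#' correctly predicted responders (TP) and correctly predicted
#' non-responders (TN), tested with a two-sided Mann-Whitney U test
#' (exact enumeration when both groups have at most 8 samples and no
#' ties; midrank normal approximation with continuity correction
#' otherwise) and Bonferroni-adjusted over the tested features.
#'
#' @param report an `ici_shap` with groups assigned
#' @param alpha significance level applied to the adjusted p-values
#' @return data.frame per feature: group means, difference, U statistic,
#'   raw and adjusted p-values, significance flag
#' @export
group_difference <- function(report, alpha = 0.05) {
  if (is.null(report$groups)) stop("report carries no TP/TN groups")
  tp <- report$groups == "TP"
  tn <- report$groups == "TN"
  if (sum(tp) < 2 || sum(tn) < 2) {
    stop("need at least 2 TP and 2 TN samples")
  }
  m <- length(report$feature_names)
  rows <- lapply(report$feature_names, function(f) {
    x <- report$shap[tp, f]
    z <- report$shap[tn, f]
    exact <- length(x) <= 8 && length(z) <= 8 &&
      !any(duplicated(c(x, z)))
    wt <- suppressWarnings(stats::wilcox.test(x, z, exact = exact,
                                              correct = TRUE))
    data.frame(feature = f, mean_tp = mean(x), mean_tn = mean(z),
               difference = mean(x) - mean(z),
               u_statistic = unname(wt$statistic), p_value = wt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- pmin(1, out$p_value * m)
  # fully tied groups (e.g. a flag attribution constant in both groups)
  # yield an undefined normal-approximation p; they carry no evidence
  out$significant <- !is.na(out$p_adjusted) & out$p_adjusted < alpha
  out
}

#' Ordered per-sample SHAP decomposition (force-plot table)
#'
#' Features sorted by absolute contribution, zero contributions dropped,
#' with the original (pre-standardization) input values attached. The
#' local-accuracy identity is re-asserted before returning.
#'
#' @param report an `ici_shap`
#' @param sample_id sample to decompose
#' @return data.frame `feature`, `shap`, `input_value`, with attributes
#'   `base_value` and `prediction`
#' @export
force_decomposition <- function(report, sample_id) {
  if (!sample_id %in% rownames(report$shap)) {
    stop("unknown sample: ", sample_id)
  }
  phi <- report$shap[sample_id, ]
  pred <- report$predictions[[sample_id]]
  stopifnot(abs(report$base_value + sum(phi) - pred) < 1e-9)
  keep <- phi != 0
  ord <- order(-abs(phi[keep]))
  out <- data.frame(feature = names(phi)[keep][ord],
                    shap = unname(phi[keep][ord]),
                    input_value = unname(report$X[sample_id, keep][ord]),
                    stringsAsFactors = FALSE)
  attr(out, "base_value") <- report$base_value
  attr(out, "prediction") <- pred
  out
}
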