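#' Pipeline configuration defaults
#'
#' One master seed fans out to per-stage derived seeds (simulate: seed;
#' split: seed + 101; cascade: seed + 202) so stages are independently
#' reproducible.
#'
#' @param out_dir run directory
#' @param cohort_dir existing cohort directory (ignored when `simulate`)
#' @param simulate NULL, or a list of [cohort_config()] overrides to
#'   generate the cohort first
#' @param seed master seed
#' @param test_fraction held-out fraction of paired samples
#' @param folds,repeats,threshold,n_lambda modelling parameters
#' @param correct_batches batch-correct expression in the feature layer
#' @return configuration list
#' @export
pipeline_config <- function(out_dir, cohort_dir = NULL, simulate = NULL,
                            seed = 1, test_fraction = 0.2, folds = 5,
                            repeats = 30, threshold = 0.0055,
                            n_lambda = 100, correct_batches = TRUE) {
  list(out_dir = out_dir, cohort_dir = cohort_dir, simulate = simulate,
       seed = seed, test_fraction = test_fraction, folds = folds,
       repeats = repeats, threshold = threshold, n_lambda = n_lambda,
       correct_batches = correct_batches)
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML config path
#' @return configuration list with defaults filled in
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$out_dir)) stop("config must set out_dir")
  do.call(pipeline_config, raw)
}

#' Run the end-to-end analysis
#'
#' simulate (optional) -> QC + feature layer -> stratified split ->
#' cascade training -> evaluation against nsTMB -> SHAP explanation,
#' writing feature matrices, serialized models, evaluation tables, SHAP
#' tables and a run manifest (sample accounting per stage, input
#' checksums, seeds) under `config$out_dir`.
#'
#' @param config list from [pipeline_config()] /
#'   [read_pipeline_config()], or a path to a YAML config
#' @return invisibly, a list with the features, cascade, evaluations,
#'   SHAP report and manifest
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  fixtures <- ici_fixtures()
  manifest <- list(config = config[setdiff(names(config), "out_dir")],
                   seeds = list(master = config$seed,
                                split = config$seed + 101,
                                cascade = config$seed + 202),
                   stages = list())

  truth <- NULL
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- config$seed
    cohort_dir <- file.path(config$out_dir, "cohort")
    sim <- generate_cohort(do.call(cohort_config, sim_args),
                           dir = cohort_dir, fixtures = fixtures)
    cohort <- sim$cohort
    truth <- sim$truth
  } else {
    if (is.null(config$cohort_dir)) stop("config needs cohort_dir or simulate")
    cohort_dir <- config$cohort_dir
    cohort <- read_cohort(cohort_dir)
  }
  input_files <- list.files(cohort_dir, recursive = TRUE, full.names = TRUE)
  manifest$input_checksums <- as.list(tools::md5sum(input_files))
  manifest$fixture_checksums <- as.list(tools::md5sum(
    list.files(extdata(), full.names = TRUE)))
  manifest$stages$input <- list(samples_in = nrow(cohort$samples))

  feats <- prepare_cohort_features(cohort, fixtures = fixtures,
                                   correct_batches = config$correct_batches)
  manifest$stages$feature_layer <- list(
    samples_in = nrow(cohort$samples),
    wes_out = if (is.null(feats$dna)) 0L else nrow(feats$dna),
    rna_out = if (is.null(feats$rna)) 0L else nrow(feats$rna),
    excluded = feats$excluded,
    variants_removed = nrow(feats$removed_variants),
    target_mb = feats$target_mb)
  if (!is.null(feats$dna)) {
    write_feature_matrix(feats$dna, file.path(config$out_dir, "dna_features.tsv"))
  }
  if (!is.null(feats$rna)) {
    write_feature_matrix(feats$rna, file.path(config$out_dir, "rna_features.tsv"))
  }

  samples <- split_cohort(feats$samples, feats$nstmb,
                          test_fraction = config$test_fraction,
                          seed = config$seed + 101)
  train_ids <- samples$sample_id[samples$split == "train"]
  test_ids <- samples$sample_id[samples$split == "test"]
  labels <- stats::setNames(as.numeric(samples$response == "responder"),
                            samples$sample_id)
  manifest$stages$split <- list(train = length(train_ids),
                                test = length(test_ids))

  dna_train <- feats$dna[intersect(train_ids, rownames(feats$dna)), , drop = FALSE]
  if (is.null(feats$rna) || nrow(feats$rna) < 2 * config$folds) {
    message("no usable RNA data; training the DNA model only")
    dna_model <- train_model(dna_train, labels[rownames(dna_train)],
                             folds = config$folds, seed = config$seed + 203,
                             n_lambda = config$n_lambda)
    write_model(dna_model, file.path(config$out_dir, "dna_model.json"))
    ev <- evaluate(dna_model, dna_train, labels[rownames(dna_train)],
                   feats$nstmb[rownames(dna_train)])
    write_tsv(data.frame(model = "dna_train", n = ev$n, auc = ev$auc,
                         baseline_auc = ev$baseline_auc,
                         threshold = ev$threshold,
                         stringsAsFactors = FALSE),
              file.path(config$out_dir, "evaluation.tsv"))
    manifest$stages$train <- list(models = "dna", note = "rna_skipped")
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         force = TRUE)
    return(invisible(list(features = feats, samples = samples,
                          dna_model = dna_model,
                          evaluations = list(dna_train = ev),
                          truth = truth, manifest = manifest)))
  }
  rna_train <- feats$rna[intersect(train_ids, rownames(feats$rna)), , drop = FALSE]
  paired_train <- intersect(rownames(dna_train), rownames(rna_train))
  cascade <- train_cascade(dna_train, rna_train, labels, paired_train,
                           cascade_config(folds = config$folds,
                                          seed = config$seed + 202,
                                          repeats = config$repeats,
                                          threshold = config$threshold,
                                          n_lambda = config$n_lambda))
  for (m in c("dna", "rna", "multi")) {
    write_model(cascade[[m]], file.path(config$out_dir, paste0(m, "_model.json")))
  }
  write_tsv(cascade$importance_dna,
            file.path(config$out_dir, "importance_dna.tsv"))
  write_tsv(cascade$importance_rna,
            file.path(config$out_dir, "importance_rna.tsv"))

  evals <- list(
    dna_train = evaluate(cascade$dna, dna_train, labels[rownames(dna_train)],
                         feats$nstmb[rownames(dna_train)]),
    rna_train = evaluate(cascade$rna, rna_train, labels[rownames(rna_train)],
                         feats$nstmb[rownames(rna_train)]))
  multi_train_X <- multiomics_matrix(cascade, feats$dna, feats$rna, paired_train)
  evals$multi_train <- evaluate(cascade$multi, multi_train_X,
                                labels[paired_train], feats$nstmb[paired_train])
  paired_test <- intersect(test_ids,
                           intersect(rownames(feats$dna), rownames(feats$rna)))
  if (length(paired_test) >= 4 &&
      length(unique(labels[paired_test])) == 2) {
    evals$dna_test <- evaluate(cascade$dna,
                               feats$dna[paired_test, , drop = FALSE],
                               labels[paired_test], feats$nstmb[paired_test])
    evals$rna_test <- evaluate(cascade$rna,
                               feats$rna[paired_test, , drop = FALSE],
                               labels[paired_test], feats$nstmb[paired_test])
    evals$multi_test <- evaluate(
      cascade$multi,
      multiomics_matrix(cascade, feats$dna, feats$rna, paired_test),
      labels[paired_test], feats$nstmb[paired_test])
  }
  eval_tab <- do.call(rbind, lapply(names(evals), function(nm) {
    e <- evals[[nm]]
    data.frame(model = nm, n = e$n, auc = e$auc,
               baseline_auc = e$baseline_auc, threshold = e$threshold,
               TP = e$confusion["TP"], TN = e$confusion["TN"],
               FP = e$confusion["FP"], FN = e$confusion["FN"],
               stringsAsFactors = FALSE)
  }))
  write_tsv(eval_tab, file.path(config$out_dir, "evaluation.tsv"))
  manifest$stages$evaluate <- list(models = names(evals))

  # SHAP on the complete paired cohort with the multi-omics model
  paired_all <- intersect(rownames(feats$dna), rownames(feats$rna))
  shap <- linear_shap(cascade$multi,
                      multiomics_matrix(cascade, feats$dna, feats$rna, paired_all),
                      background = multi_train_X, y = labels[paired_all])
  shap_tab <- data.frame(sample_id = rownames(shap$shap),
                         group = shap$groups, prediction = shap$predictions,
                         shap$shap, check.names = FALSE,
                         stringsAsFactors = FALSE)
  write_tsv(shap_tab, file.path(config$out_dir, "shap_values.tsv"))
  groups <- table(factor(shap$groups, c("TP", "TN", "FP", "FN")))
  gd <- NULL
  if (groups["TP"] >= 2 && groups["TN"] >= 2) {
    gd <- group_difference(shap)
    write_tsv(gd, file.path(config$out_dir, "shap_group_difference.tsv"))
  }
  manifest$stages$explain <- list(groups = as.list(groups))

  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       force = TRUE)
  invisible(list(features = feats, samples = samples, cascade = cascade,
                 evaluations = evals, shap = shap, group_difference = gd,
                 truth = truth, manifest = manifest))
}
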