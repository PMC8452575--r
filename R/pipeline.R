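# End-to-end pipeline: simulate/load -> matched split -> harmonise (train
# parameters only) -> correlation filter (train only) -> elastic-net grid
# search -> Youden threshold on the training set -> evaluation on both sets.
# Supports the five model variants: radiomics, signs, radiomics+signs,
# clinical, radiomics+clinical.

.pipeline_defaults <- function() {
  list(
    seed = 1L,
    output_dir = "ichradiomics_run",
    variant = "radiomics",
    outcome = "expansion",
    cohort = list(),
    harmonisation = list(enabled = TRUE, covariates = c("age", "gender"),
                         include_growth = TRUE),
    selection = list(cutoff = 0.9),
    model = list(alphas = seq(0, 1, by = 0.1), folds = 10L),
    split = list(train_fraction = 0.7)
  )
}

.merge_config <- function(defaults, user) {
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && is.list(user[[nm]]))
      defaults[[nm]] <- .merge_config(defaults[[nm]], user[[nm]])
    else defaults[[nm]] <- user[[nm]]
  }
  defaults
}

.clinical_factor_names <- c("age", "gender_male", "onset_to_scan_h", "v0_ml",
                            "antiplatelet", "ultra_early_growth")
.sign_names <- c("blend_sign", "black_hole_sign", "hypodensities", "island_sign")
.pipeline_variants <- c("radiomics", "signs", "radiomics+signs", "clinical",
                        "radiomics+clinical")

#' Run the full prediction pipeline
#'
#' Executes simulate/load, matched train/test split, harmonisation with
#' strict train-then-apply, iterative correlation filtering on the training
#' set, elastic-net grid search with stratified CV by AUC, Youden threshold
#' selection on the training set, and evaluation of both sets. Every
#' artefact (feature table, harmonisation model, retained ids, grid-search
#' record, fitted model, metric reports, ROC points) is serialised into the
#' run directory together with a manifest carrying the config hash and seed.
#' Harmonisation, feature selection and the decision threshold are functions
#' of the training data only.
#'
#' @param config configuration list, or path to a YAML file with the same
#'   structure (see `.pipeline_defaults` in the source; unknown variants or
#'   outcomes are rejected).
#' @param output_dir optional override of `config$output_dir`.
#' @return invisibly, a list with the run artefacts (`split`, `retained`,
#'   `grid`, `model`, `threshold`, `metrics_train`, `metrics_test`,
#'   `output_dir`).
#' @export
run_pipeline <- function(config = list(), output_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .merge_config(.pipeline_defaults(), config)
  if (!cfg$variant %in% .pipeline_variants)
    stop("run_pipeline [config]: unknown variant '", cfg$variant, "'")
  if (!cfg$outcome %in% c("expansion", "poor_outcome"))
    stop("run_pipeline [config]: unknown outcome '", cfg$outcome, "'")
  if (!is.null(output_dir)) cfg$output_dir <- output_dir
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)

  # --- stage: cohort -------------------------------------------------------
  spec <- do.call(cohort_spec, c(cfg$cohort, list(seed = cfg$seed)))
  cohort <- generate_cohort(spec)
  feats <- cohort$features
  clinical <- cohort$clinical
  outcomes <- cohort$outcomes
  y_all <- if (cfg$outcome == "expansion") as.integer(outcomes$expansion)
           else as.integer(outcomes$poor_outcome)
  keep_rows <- !is.na(y_all)
  feats <- feats[keep_rows, , drop = FALSE]
  clinical <- clinical[keep_rows, , drop = FALSE]
  outcomes <- outcomes[keep_rows, , drop = FALSE]
  y_all <- y_all[keep_rows]
  utils::write.csv(cbind(clinical, outcomes[, c("v24_ml", "expansion",
                                                "mrs_day90", "poor_outcome")],
                         feats),
                   file.path(cfg$output_dir, "features.csv"),
                   row.names = FALSE)

  # --- stage: split --------------------------------------------------------
  split <- matched_split(clinical, cfg$split$train_fraction, seed = cfg$seed,
                         outcome = y_all)
  tr <- split$train; te <- split$test

  # --- stage: harmonisation (train-then-apply) -----------------------------
  growth <- outcomes$ultra_early_growth
  H <- feats
  if (isTRUE(cfg$harmonisation$include_growth))
    H <- cbind(H, ultra_early_growth = growth)
  if (isTRUE(cfg$harmonisation$enabled)) {
    covars <- clinical[, cfg$harmonisation$covariates, drop = FALSE]
    fit <- combat_fit(H[tr, , drop = FALSE], clinical$batch[tr], covars[tr, , drop = FALSE])
    H_train <- fit$harmonised
    H_test <- combat_apply(fit$model, H[te, , drop = FALSE],
                           clinical$batch[te], covars[te, , drop = FALSE])
    combat_model_to_json(fit$model, file.path(cfg$output_dir, "combat_model.json"))
  } else {
    H_train <- H[tr, , drop = FALSE]
    H_test <- H[te, , drop = FALSE]
  }

  # --- stage: selection (train only) ---------------------------------------
  retained <- correlation_filter(H_train, cutoff = cfg$selection$cutoff)
  jsonlite::write_json(retained, file.path(cfg$output_dir, "retained_features.json"))

  # --- stage: design matrix per variant ------------------------------------
  clin_design <- function(idx) {
    cbind(age = clinical$age[idx],
          gender_male = as.integer(clinical$gender[idx] == "male"),
          onset_to_scan_h = clinical$onset_to_scan_h[idx],
          v0_ml = clinical$v0_ml[idx],
          antiplatelet = clinical$antiplatelet[idx],
          ultra_early_growth = growth[idx])
  }
  sign_design <- function(idx) as.matrix(clinical[idx, .sign_names])
  radiomics_design <- function(H_set, idx) {
    cbind(H_set[, retained, drop = FALSE],
          treatment = clinical$treatment[idx])
  }
  build_design <- function(H_set, idx) {
    switch(cfg$variant,
      "radiomics" = radiomics_design(H_set, idx),
      "signs" = sign_design(idx),
      "radiomics+signs" = cbind(radiomics_design(H_set, idx), sign_design(idx)),
      "clinical" = clin_design(idx),
      "radiomics+clinical" = cbind(radiomics_design(H_set, idx), clin_design(idx)))
  }
  X_train <- build_design(H_train, tr)
  X_test <- build_design(H_test, te)
  y_train <- y_all[tr]; y_test <- y_all[te]

  # --- stage: model --------------------------------------------------------
  grid <- cv_grid_search(X_train, y_train, alphas = cfg$model$alphas,
                         k = cfg$model$folds, seed = cfg$seed)
  model <- grid$model
  jsonlite::write_json(
    list(records = grid$records, selected = grid$selected),
    file.path(cfg$output_dir, "grid_search.json"),
    digits = NA, auto_unbox = TRUE, dataframe = "columns")
  jsonlite::write_json(
    list(alpha = model$alpha, lambda = model$lambda,
         intercept = model$intercept,
         coefficients = as.list(model$coefficients),
         center = as.list(model$center), scale = as.list(model$scale)),
    file.path(cfg$output_dir, "model.json"), digits = NA, auto_unbox = TRUE)

  # --- stage: evaluation ---------------------------------------------------
  p_train <- predict_probability(model, X_train)
  p_test <- predict_probability(model, X_test)
  thr <- youden_threshold(roc_auc(p_train, y_train))
  m_train <- metric_report(p_train, y_train, thr)
  m_test <- metric_report(p_test, y_test, thr)
  report_json <- function(m, path) {
    jsonlite::write_json(unclass(m), path, digits = NA, auto_unbox = TRUE,
                         na = "null")
  }
  report_json(m_train, file.path(cfg$output_dir, "metrics_train.json"))
  report_json(m_test, file.path(cfg$output_dir, "metrics_test.json"))
  roc_te <- roc_auc(p_test, y_test)
  utils::write.table(roc_te$curve, file.path(cfg$output_dir, "roc_test.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  # --- manifest ------------------------------------------------------------
  cfg_file <- file.path(cfg$output_dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_file)
  manifest <- list(
    seed = cfg$seed, variant = cfg$variant, outcome = cfg$outcome,
    config_md5 = unname(tools::md5sum(cfg_file)),
    n_train = length(tr), n_test = length(te),
    n_retained = length(retained),
    train_only_stages = c("harmonisation", "selection", "threshold"))
  jsonlite::write_json(manifest, file.path(cfg$output_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(list(split = split, retained = retained, grid = grid,
                 model = model, threshold = thr,
                 metrics_train = m_train, metrics_test = m_test,
                 output_dir = cfg$output_dir))
}
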