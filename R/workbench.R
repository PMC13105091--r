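# Config-driven experiment orchestration: representation benchmarks
# (featurizer x model R-squared tables), representation shape analyses
# (pairwise Procrustes/CCA distance matrices), and full LORAX experiments
# with frozen comparator and naive baseline. Runs are deterministic per seed
# and emit machine-readable CSV/JSON when an output directory is given.

#' Load and validate an experiment configuration
#'
#' Configurations are plain named lists; this helper reads them from a YAML
#' file and checks the seed is present. All run functions accept either a
#' list or a YAML path.
#'
#' @param config named list or path to a YAML file.
#' @return validated named list.
#' @export
load_experiment_config <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  if (is.null(config[["seed"]])) stop("config must set a seed")
  config
}

# Resolve the dataset a config names: a CSV path or a simulation preset
# ("hallem" 110x24, "carey" 110x50, "m2or-like" sparse screen).
.config_dataset <- function(config) {
  if (!is.null(config[["dataset"]])) {
    if (inherits(config[["dataset"]], "interaction_dataset")) return(config[["dataset"]])
    return(load_interaction_table(config[["dataset"]],
                                  mode = config[["mode"]] %||% "regression"))
  }
  preset <- config[["preset"]] %||% "carey"
  sim_preset(preset, seed = config[["seed"]])$dataset
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a preset-shaped dataset
#'
#' `"hallem"`: full-factorial 110 odorants x 24 receptors continuous panel;
#' `"carey"`: 110 x 50 panel; `"m2or-like"`: sparse imbalanced binary screen
#' with quality tiers. Panel responses are globally z-scored, as the study
#' datasets are.
#'
#' @param preset preset name.
#' @param seed integer seed.
#' @param noise_sd relative noise level for the panels.
#' @return list with `dataset` and planted `truth`.
#' @export
sim_preset <- function(preset = c("carey", "hallem", "m2or-like"),
                       seed = 1L, noise_sd = 0.3) {
  preset <- match.arg(preset)
  if (preset == "m2or-like") {
    return(gen_sparse_screen(474, 503, density = 0.025, positive_rate = 0.2,
                             seed = seed))
  }
  n_rec <- if (preset == "hallem") 24L else 50L
  cf <- count_featurizer(normalize = TRUE)
  pm <- planted_model(planted_bilinear(ncol(cf("C")), 20, seed = seed),
                      noise_sd = noise_sd)
  panel <- gen_panel(110, n_rec, planted = pm, seed = seed)
  panel$dataset <- zscore_global(panel$dataset)$dataset
  panel
}

#' Run a representation benchmark
#'
#' For every (featurizer, model) combination in the config, runs the MO or
#' MP cross-validated ridge benchmark and collects mean +/- SD R-squared.
#' Per-cell failures are recorded in the `error` column and the run
#' continues. Identical configurations (including seed) reproduce identical
#' tables.
#'
#' @param config list (or YAML path) with fields `featurizers` (character),
#'   `models` (subset of `"MO"`, `"MP"`), `seed`, optional `dataset` /
#'   `preset`, `k`, `outdir`.
#' @return data.frame with one row per (featurizer, model).
#' @export
run_representation_benchmark <- function(config) {
  config <- load_experiment_config(config)
  dataset <- .config_dataset(config)
  k <- config[["k"]] %||% 5L
  models <- config[["models"]] %||% c("MO", "MP")
  prot_feat <- config[["protein_featurizer"]] %||% kmer_protein_featurizer(1)
  rows <- list()
  for (fz in config[["featurizers"]]) {
    for (mdl in models) {
      res <- tryCatch({
        br <- if (mdl == "MO")
          run_mo(dataset, fz, folds = k, seed = config[["seed"]])
        else
          run_mp(dataset, fz, prot_feat, folds = k, seed = config[["seed"]])
        data.frame(featurizer = fz, model = mdl, mean_r2 = br$mean_r2,
                   sd_r2 = br$sd_r2,
                   folds = paste(sprintf("%.4f", br$per_fold_r2),
                                 collapse = ";"),
                   error = NA_character_, stringsAsFactors = FALSE)
      }, error = function(e)
        data.frame(featurizer = fz, model = mdl, mean_r2 = NA_real_,
                   sd_r2 = NA_real_, folds = "",
                   error = conditionMessage(e), stringsAsFactors = FALSE))
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(config[["outdir"]])) {
    dir.create(config[["outdir"]], recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out, file.path(config[["outdir"]], "benchmark.csv"),
                     row.names = FALSE)
    jsonlite::write_json(out, file.path(config[["outdir"]], "benchmark.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Run a representation shape analysis
#'
#' Computes Procrustes and CCA distance matrices over the configured
#' featurizer representations, optionally including the measured neural
#' representation (full-factorial regression data required) and the
#' fine-tuned chemical embedding of a trained LORAX model.
#'
#' @param config list (or YAML path) with `featurizers`, `seed`, optional
#'   `dataset` / `preset`, `include_neural`, `lorax_fit` (a fitted
#'   [lorax()] object), `metrics`, `outdir`.
#' @return named list of `distance_matrix` objects, one per metric.
#' @export
run_shape_analysis <- function(config) {
  config <- load_experiment_config(config)
  dataset <- .config_dataset(config)
  reps <- lapply(config[["featurizers"]], featurize_molecules,
                 odorants = dataset$odorants)
  if (isTRUE(config[["include_neural"]])) {
    if (dataset$mode != "regression")
      stop("neural representation requires regression data")
    full <- nrow(dataset$interactions) ==
      nrow(dataset$odorants) * nrow(dataset$receptors)
    if (!full)
      stop("neural representation requires a full-factorial panel")
    reps <- c(reps, list(build_neural_representation(dataset)))
  }
  if (!is.null(config[["lorax_fit"]])) {
    reps <- c(reps, list(extract_cls_features(config[["lorax_fit"]]$model,
                                              dataset, type = "chem_mean",
                                              name = "lorax")))
  }
  metrics <- config[["metrics"]] %||% c("procrustes", "cca")
  out <- lapply(metrics, function(m) pairwise_distances(reps, metric = m))
  names(out) <- metrics
  if (!is.null(config[["outdir"]])) {
    dir.create(config[["outdir"]], recursive = TRUE, showWarnings = FALSE)
    for (m in metrics)
      write_distance_matrix(out[[m]],
                            file.path(config[["outdir"]],
                                      paste0("distance_", m, ".csv")))
  }
  out
}

#' Run a full LORAX experiment
#'
#' For each cross-validation fold under the configured scenario: stage-1
#' transformer training, stage-2 ensemble, and test metrics for LORAX, for
#' the frozen comparator (identical architecture and ensemble with LoRA
#' adapters disabled), and for the naive training-mean baseline; followed by
#' a statistical comparison across folds. Fold-level failures are caught and
#' surfaced in the summary.
#'
#' @param config list (or YAML path) with `seed`, optional `dataset` /
#'   `preset`, `scenario`, `k`, `models` (subset of `"LORAX"`,
#'   `"LORAX_frozen"`, `"naive"`), `lora`, `fusion`, `train`, `gbt_params`,
#'   `comparison_test`, `outdir`.
#' @return list with `scores` (models x folds matrix), `summary`
#'   data.frame (avg/std per model), per-fold `fits`, `comparison`, and
#'   `errors`.
#' @export
run_lorax_experiment <- function(config) {
  config <- load_experiment_config(config)
  dataset <- .config_dataset(config)
  scenario <- config[["scenario"]] %||% "random"
  k <- config[["k"]] %||% 5L
  models <- config[["models"]] %||% c("LORAX", "LORAX_frozen", "naive")
  train_cfg <- config[["train"]] %||% train_config(seed = config[["seed"]])
  lora_cfg <- config[["lora"]] %||% lora_config()
  fusion_cfg <- config[["fusion"]] %||% fusion_config()
  split <- make_splits(dataset, scenario = scenario, k = k,
                       seed = config[["seed"]])
  it <- dataset$interactions
  y <- if (dataset$mode == "regression") it$response else it$label
  scores <- matrix(NA_real_, length(models), k,
                   dimnames = list(models, paste0("fold", seq_len(k))))
  fits <- list(); errors <- list()
  for (f in seq_len(k)) {
    fold <- split$folds[[f]]
    for (mdl in models) {
      res <- tryCatch({
        if (mdl == "naive") {
          nb <- naive_baseline(y[c(fold$train, fold$val)], y[fold$test])
          list(score = nb$r2, fit = NULL)
        } else {
          tc <- train_cfg
          lc <- lora_cfg
          if (mdl == "LORAX_frozen") {
            lc$enabled <- FALSE
            tc$trainable_scope <- "head_and_fusion_only"
          }
          fit <- lorax(dataset, fold, lora = lc, fusion = fusion_cfg,
                       train = tc, gbt_params = config[["gbt_params"]] %||% list(),
                       seed = config[["seed"]] + f)
          list(score = fit$scores$test, fit = fit)
        }
      }, error = function(e) e)
      if (inherits(res, "error")) {
        errors[[paste(mdl, f, sep = ".")]] <- conditionMessage(res)
      } else {
        scores[mdl, f] <- res$score
        if (!is.null(res$fit)) fits[[paste(mdl, f, sep = ".")]] <- res$fit
      }
    }
  }
  summary_df <- data.frame(model = rownames(scores),
                           avg = rowMeans(scores, na.rm = TRUE),
                           std = apply(scores, 1, stats::sd, na.rm = TRUE),
                           stringsAsFactors = FALSE)
  comparison <- NULL
  ok <- rowSums(is.na(scores)) == 0
  if (sum(ok) >= 2)
    comparison <- compare_models(scores[ok, , drop = FALSE],
                                 test = config[["comparison_test"]] %||%
                                   "friedman_bh")
  out <- list(scores = scores, summary = summary_df, fits = fits,
              comparison = comparison, errors = errors,
              scenario = scenario, seed = config[["seed"]])
  if (!is.null(config[["outdir"]])) {
    dir.create(config[["outdir"]], recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(cbind(model = rownames(scores), as.data.frame(scores)),
                     file.path(config[["outdir"]], "fold_scores.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(summary = summary_df, errors = errors),
                         file.path(config[["outdir"]], "experiment.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  out
}
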