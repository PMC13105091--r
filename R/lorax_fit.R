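#' Fit the full LORAX model
#'
#' The package's central fitting function. Training proceeds in two stages:
#' (1) the multi-modal cross-attention transformer -- including the LoRA
#' adapters selected by `train$trainable_scope` -- is trained on the
#' training set and tuned on the validation set ([train_stage1()]); (2) the
#' transformer is frozen and its `<cls>` token, together with the frozen
#' original encoder representations, feed a three-model gradient-boosted
#' tree ensemble whose simplex weights are optimized on the validation set
#' ([fit_ensemble()], [optimize_weights()]). Final predictions are the
#' weighted ensemble output.
#'
#' Setting `lora = lora_config(enabled = FALSE)` (equivalently
#' `train$trainable_scope = "head_and_fusion_only"` with disabled adapters)
#' yields the frozen-representation comparator: same architecture and
#' ensemble, no fine-tuning of the chemical representation.
#'
#' @param dataset an [interaction_dataset()].
#' @param split list with integer index vectors `train`, `val`, and
#'   optionally `test` (e.g. one fold of [make_splits()]).
#' @param lora a [lora_config()].
#' @param fusion a [fusion_config()].
#' @param train a [train_config()].
#' @param gbt_params list of XGBoost overrides for the stage-2 ensemble.
#' @param grid_step simplex resolution for weight optimization.
#' @param seed master seed (model initialization and ensemble fitting).
#' @return Object of class `lorax`: list with the trained `model`, training
#'   `history`, stage-2 `bundle` (an `ensemble_bundle`), the `split`, per
#'   split-part `scores`, and fitted/test predictions. Methods: `print`,
#'   `summary`, `predict`, `plot`, `residuals`.
#' @seealso [train_stage1()], [ensemble_report()], [make_splits()]
#' @export
lorax <- function(dataset, split, lora = lora_config(),
                  fusion = fusion_config(), train = train_config(),
                  gbt_params = list(), grid_step = 0.05, seed = train$seed) {
  stopifnot(inherits(dataset, "interaction_dataset"))
  if (is.null(split$train) || is.null(split$val))
    stop("split must provide train and val indices")
  cl <- match.call()
  model0 <- build_lorax_model(mode = dataset$mode, lora = lora,
                              fusion = fusion, seed = seed)
  st1 <- train_stage1(model0, dataset, split, train)
  model <- st1$model

  it <- dataset$interactions
  y <- if (dataset$mode == "regression") it$response else it$label
  w <- it$weight
  orig <- .original_reps(model, dataset)
  feat_for <- function(idx) {
    cls <- extract_cls_features(model, dataset, idx)$values
    chem <- orig$chem$values[match(it$odorant_id[idx], orig$chem$item_ids), ,
                             drop = FALSE]
    prot <- orig$prot$values[match(it$receptor_id[idx], orig$prot$item_ids), ,
                             drop = FALSE]
    build_feature_sets(cls, chem, prot)
  }
  fs_train <- feat_for(split$train)
  fs_val <- feat_for(split$val)
  task <- dataset$mode
  models <- fit_ensemble(fs_train, y[split$train],
                         weights_train = w[split$train], task = task,
                         gbt_params = gbt_params, seed = seed)
  val_preds <- lapply(.FEATURE_SET_IDS, function(id)
    stats::predict(models[[id]], fs_val[[id]]))
  metric <- if (task == "regression") "r2" else "mcc"
  opt <- optimize_weights(val_preds, y[split$val], metric = metric,
                          grid_step = grid_step)
  score_of <- function(p, idx) {
    if (task == "regression") .r_squared(y[idx], p)
    else compute_metrics(y[idx], p, "classification")$mcc
  }
  per_model <- vapply(seq_along(val_preds), function(i)
    score_of(val_preds[[i]], split$val), numeric(1))
  tval <- attr(st1$history, "best_val_metric")
  bundle <- .ensemble_bundle(
    models, weights = list(w = opt$w),
    validation_scores = list(
      per_model = as.list(stats::setNames(per_model, .FEATURE_SET_IDS)),
      combined = opt$score),
    transformer_val_score = if (is.null(tval) || !is.finite(tval))
      NA_real_ else tval)

  scores <- list(val = opt$score)
  predictions <- list()
  if (length(split$test)) {
    fs_test <- feat_for(split$test)
    test_pred <- ensemble_predict(bundle, fs_test)
    predictions$test <- test_pred
    scores$test <- score_of(test_pred, split$test)
  }
  structure(list(model = model, history = st1$history, bundle = bundle,
                 split = split, scores = scores, predictions = predictions,
                 mode = dataset$mode, call = cl),
            class = "lorax")
}

#' @export
print.lorax <- function(x, ...) {
  cat("LORAX fit (", x$mode, ")\n", sep = "")
  cat(sprintf("  stage-1 epochs run: %d (best epoch %s)\n",
              nrow(x$history),
              as.character(attr(x$history, "best_epoch"))))
  cat(sprintf("  transformer validation score: %.3f\n",
              x$bundle$transformer_val_score))
  cat("  ensemble weights:",
      paste(sprintf("%s=%.2f", .FEATURE_SET_IDS, x$bundle$weights$w),
            collapse = " "), "\n")
  cat(sprintf("  combined validation score: %.3f\n", x$scores$val))
  if (!is.null(x$scores$test))
    cat(sprintf("  test score: %.3f\n", x$scores$test))
  invisible(x)
}

#' @export
summary.lorax <- function(object, ...) {
  rep_ <- ensemble_report(object$bundle)
  out <- list(mode = object$mode,
              n_train = length(object$split$train),
              n_val = length(object$split$val),
              n_test = length(object$split$test),
              history = object$history,
              ensemble = rep_,
              scores = object$scores)
  class(out) <- "summary.lorax"
  out
}

#' @export
print.summary.lorax <- function(x, ...) {
  cat(sprintf("LORAX summary (%s): n_train=%d n_val=%d n_test=%d\n",
              x$mode, x$n_train, x$n_val, x$n_test))
  cat(sprintf("  transformer val score: %.3f; ensemble val score: %.3f\n",
              x$ensemble$transformer_val_score, x$scores$val))
  cat(sprintf("  ORIG-only weight: %.2f\n", x$ensemble$orig_weight))
  if (nrow(x$history)) {
    cat("  last epochs:\n")
    print(utils::tail(x$history, 3), row.names = FALSE)
  }
  invisible(x)
}

#' Predict from a fitted LORAX model
#'
#' @param object a `lorax` fit.
#' @param dataset the [interaction_dataset()] holding the pairs to predict
#'   (odorants/receptors may be new; tokens are encoded on the fly).
#' @param idx interaction rows to predict (default: all).
#' @param type `"ensemble"` (stage-2 weighted prediction, default) or
#'   `"transformer"` (stage-1 head output).
#' @param ... unused.
#' @return numeric predictions (probabilities in classification mode).
#' @export
predict.lorax <- function(object, dataset, idx = NULL,
                          type = c("ensemble", "transformer"), ...) {
  type <- match.arg(type)
  it <- dataset$interactions
  if (is.null(idx)) idx <- seq_len(nrow(it))
  if (type == "transformer")
    return(.predict_pairs(object$model, dataset, idx)$pred)
  orig <- .original_reps(object$model, dataset)
  cls <- extract_cls_features(object$model, dataset, idx)$values
  chem <- orig$chem$values[match(it$odorant_id[idx], orig$chem$item_ids), ,
                           drop = FALSE]
  prot <- orig$prot$values[match(it$receptor_id[idx], orig$prot$item_ids), ,
                           drop = FALSE]
  ensemble_predict(object$bundle, build_feature_sets(cls, chem, prot))
}

#' @export
residuals.lorax <- function(object, dataset = NULL, ...) {
  if (is.null(object$predictions$test))
    stop("fit had no test indices; call predict() with new data instead")
  if (is.null(dataset))
    stop("supply the dataset the model was fitted on")
  it <- dataset$interactions
  y <- if (object$mode == "regression") it$response else it$label
  y[object$split$test] - object$predictions$test
}

#' @export
plot.lorax <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  h <- x$history
  if (nrow(h)) {
    graphics::plot(h$epoch, h$val_metric, type = "b", pch = 16,
                   xlab = "epoch", ylab = "validation score",
                   main = "stage-1 training")
    graphics::abline(v = attr(h, "best_epoch"), lty = 2, col = "grey50")
  } else {
    graphics::plot.new(); graphics::title("no training history")
  }
  graphics::barplot(x$bundle$weights$w, names.arg = .FEATURE_SET_IDS,
                    ylab = "ensemble weight", main = "stage-2 weights",
                    ylim = c(0, 1))
  invisible(x)
}
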