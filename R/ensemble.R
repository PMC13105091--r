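# Stage-2 gradient-boosted-tree ensemble: three XGBoost models over fixed
# feature sets (the transformer's <cls> token, the original frozen encoder
# representations, and their concatenation), combined by simplex weights
# tuned on the validation set.

.FEATURE_SET_IDS <- c("CLS", "ORIG", "CLS_PLUS_ORIG")

#' Assemble the three ensemble feature sets
#'
#' `CLS` is the transformer's penultimate (`<cls>`) representation; `ORIG`
#' concatenates the original chemical and protein representations;
#' `CLS_PLUS_ORIG` concatenates all three. Rows must align to the same
#' interaction list.
#'
#' @param cls n x d_c matrix of `<cls>` vectors.
#' @param chem n x d_m matrix of per-pair chemical features.
#' @param prot n x d_p matrix of per-pair protein features.
#' @return named list of matrices `CLS`, `ORIG`, `CLS_PLUS_ORIG`.
#' @export
build_feature_sets <- function(cls, chem, prot) {
  cls <- as.matrix(cls); chem <- as.matrix(chem); prot <- as.matrix(prot)
  n <- nrow(cls)
  if (nrow(chem) != n || nrow(prot) != n)
    stop("row mismatch: cls ", n, ", chem ", nrow(chem), ", prot ", nrow(prot))
  list(CLS = cls, ORIG = cbind(chem, prot),
       CLS_PLUS_ORIG = cbind(cls, chem, prot))
}

.default_gbt_params <- function(task) {
  list(nrounds = 150, max_depth = 4, eta = 0.1, subsample = 1,
       colsample_bytree = 1,
       objective = if (task == "regression") "reg:squarederror"
                   else "binary:logistic")
}

#' Fit the three-tree-model ensemble
#'
#' One XGBoost model per feature set, all with identical hyperparameters and
#' seed; per-record training weights are honored.
#'
#' @param feature_sets output of [build_feature_sets()] (training rows).
#' @param y_train training responses (0/1 labels for classification).
#' @param weights_train optional non-negative record weights.
#' @param task `"regression"` or `"classification"`.
#' @param gbt_params list overriding the defaults (`nrounds`, `max_depth`,
#'   `eta`, ...).
#' @param seed xgboost seed (single-threaded fits; deterministic).
#' @return named list of three fitted models.
#' @export
fit_ensemble <- function(feature_sets, y_train, weights_train = NULL,
                         task = c("regression", "classification"),
                         gbt_params = list(), seed = 1L) {
  task <- match.arg(task)
  if (!identical(sort(names(feature_sets)), sort(.FEATURE_SET_IDS)))
    stop("feature_sets must be named ", paste(.FEATURE_SET_IDS, collapse = ", "))
  if (any(vapply(feature_sets, function(m) any(!is.finite(m)), logical(1))))
    stop("NaN/Inf in features")
  params <- utils::modifyList(.default_gbt_params(task), gbt_params)
  nrounds <- params$nrounds
  params$nrounds <- NULL
  .with_private_seed(seed, function()
    lapply(feature_sets[.FEATURE_SET_IDS], function(X) {
      dtrain <- xgboost::xgb.DMatrix(X, label = y_train,
                                     weight = weights_train)
      xgboost::xgb.train(params = c(params, list(nthread = 1)),
                         data = dtrain, nrounds = nrounds, verbose = 0)
    }))
}

# Enumerate all weight triples on the 2-simplex with the given step, in
# lexicographic order of (w1, w2, w3).
.simplex_grid <- function(step = 0.05) {
  m <- round(1 / step)
  if (abs(m * step - 1) > 1e-9) stop("grid_step must divide 1")
  out <- list()
  for (i in 0:m) for (j in 0:(m - i))
    out[[length(out) + 1L]] <- c(i, j, m - i - j) / m
  do.call(rbind, out)
}

#' Optimize ensemble weights on the validation set
#'
#' Exhaustive search over all weight triples on the 2-simplex at `grid_step`
#' (231 candidates at step 0.05). Returns the first candidate in
#' lexicographic order attaining the best validation metric (R-squared for
#' regression, MCC for classification), so ties resolve deterministically.
#' The simplex vertices are in the grid, hence the combined validation score
#' is never below the best single model's.
#'
#' @param val_preds list of 3 validation prediction vectors (CLS, ORIG,
#'   CLS_PLUS_ORIG order; probabilities in classification mode).
#' @param y_val validation responses.
#' @param metric `"r2"` or `"mcc"`.
#' @param grid_step simplex grid resolution (must divide 1).
#' @return list with `w` (length-3 weights summing to 1), `score`, and the
#'   number of `candidates` enumerated.
#' @export
optimize_weights <- function(val_preds, y_val, metric = c("r2", "mcc"),
                             grid_step = 0.05) {
  metric <- match.arg(metric)
  if (!length(y_val)) stop("empty validation set")
  stopifnot(length(val_preds) == 3)
  if (!all(lengths(val_preds) == length(y_val)))
    stop("prediction/response length mismatch")
  P <- do.call(cbind, val_preds)
  grid <- .simplex_grid(grid_step)
  score_fn <- if (metric == "r2") {
    function(p) .r_squared(y_val, p)
  } else {
    function(p) compute_metrics(y_val, p, "classification")$mcc
  }
  best <- -Inf; best_w <- grid[1, ]
  for (i in seq_len(nrow(grid))) {
    s <- score_fn(drop(P %*% grid[i, ]))
    if (s > best + 1e-12) { best <- s; best_w <- grid[i, ] }
  }
  list(w = best_w, score = best, candidates = nrow(grid))
}

#' Predict with a fitted ensemble bundle
#'
#' The final prediction is the weighted sum of the three tree models'
#' predictions (probabilities in classification mode; threshold downstream).
#'
#' @param bundle an `ensemble_bundle` (see [lorax()]), or a list with
#'   `models` and `weights$w`.
#' @param feature_sets output of [build_feature_sets()] for the rows to
#'   predict.
#' @return numeric prediction vector.
#' @export
ensemble_predict <- function(bundle, feature_sets) {
  preds <- lapply(.FEATURE_SET_IDS, function(id)
    stats::predict(bundle$models[[id]], feature_sets[[id]]))
  drop(do.call(cbind, preds) %*% bundle$weights$w)
}

.ensemble_bundle <- function(models, weights, validation_scores,
                             transformer_val_score) {
  structure(list(models = models, weights = weights,
                 validation_scores = validation_scores,
                 transformer_val_score = transformer_val_score),
            class = "ensemble_bundle")
}

#' Summarize an ensemble bundle
#'
#' Reports the simplex weights, each model's validation score, the combined
#' validation score, the standalone transformer validation score, and the
#' weight placed on the ORIG-only model -- the diagnostic for how much the
#' ensemble relies on the learned `<cls>` representation versus the frozen
#' original representations.
#'
#' @param bundle an `ensemble_bundle`.
#' @return list; serializes cleanly to JSON.
#' @export
ensemble_report <- function(bundle) {
  list(weights = as.list(stats::setNames(bundle$weights$w, .FEATURE_SET_IDS)),
       orig_weight = unname(bundle$weights$w[2]),
       validation_scores = bundle$validation_scores,
       transformer_val_score = bundle$transformer_val_score)
}

#' @export
print.ensemble_bundle <- function(x, ...) {
  cat("ensemble_bundle: weights",
      paste(sprintf("%s=%.2f", .FEATURE_SET_IDS, x$weights$w),
            collapse = " "), "\n")
  cat(sprintf("  combined val score %.3f; transformer val score %.3f\n",
              x$validation_scores$combined, x$transformer_val_score))
  invisible(x)
}
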