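# Feature-based benchmark models: per-receptor ridge on odorant features
# (molecule-only, MO) and a single ridge on concatenated odorant + receptor
# features (molecule + protein, MP).

#' Closed-form ridge regression
#'
#' Features are standardized internally (mean 0, SD 1; constant columns get a
#' unit scale guard and contribute nothing), the intercept is unpenalized, and
#' the coefficients solve `(X'X + lambda I) b = X'y` on the standardized
#' design. Predictions reverse the standardization.
#'
#' @param X numeric matrix (n x p).
#' @param y numeric response vector.
#' @param lambda ridge penalty >= 0. At `lambda = 0` the standardized design
#'   (with intercept) must be full column rank.
#' @return object of class `ridge_model`.
#' @export
ridge_fit <- function(X, y, lambda) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("nrow(X) != length(y)")
  if (nrow(X) < 2) stop("need at least 2 observations")
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda < 0)
    stop("lambda must be a single number >= 0")
  mu <- colMeans(X)
  sds <- sqrt(colMeans(sweep(X, 2, mu)^2))
  sds[sds == 0] <- 1  # constant-column guard: centered column is all-zero
  Xs <- sweep(sweep(X, 2, mu), 2, sds, "/")
  if (lambda == 0 && qr(cbind(1, Xs))$rank < ncol(Xs) + 1)
    stop("design is rank deficient; lambda = 0 requires full column rank")
  yc <- y - mean(y)
  A <- crossprod(Xs) + diag(lambda, ncol(Xs))
  beta <- drop(solve(A, crossprod(Xs, yc)))
  structure(list(coefficients = beta, intercept = mean(y), lambda = lambda,
                 feature_means = mu, feature_scales = sds),
            class = "ridge_model")
}

#' @export
predict.ridge_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  Xs <- sweep(sweep(X, 2, object$feature_means), 2, object$feature_scales, "/")
  drop(object$intercept + Xs %*% object$coefficients)
}

#' @export
print.ridge_model <- function(x, ...) {
  cat(sprintf("ridge_model: %d features, lambda = %g\n",
              length(x$coefficients), x$lambda))
  invisible(x)
}

# Default penalty grid: 13 log-spaced points over 1e-3 .. 1e3.
.default_lambda_grid <- function() 10^seq(-3, 3, length.out = 13)

# Select lambda by inner k-fold CV (minimum validation MSE; ties -> smallest).
.select_lambda <- function(X, y, lambda_grid, inner_k = 3L, seed = 1L) {
  n <- length(y)
  if (length(lambda_grid) == 1) return(lambda_grid)
  folds <- .with_private_seed(seed, function()
    sample(rep_len(seq_len(inner_k), n)))
  mse <- numeric(length(lambda_grid))
  for (li in seq_along(lambda_grid)) {
    errs <- 0
    for (f in seq_len(inner_k)) {
      tr <- folds != f
      if (sum(tr) < 2 || sum(!tr) < 1) next
      fit <- tryCatch(ridge_fit(X[tr, , drop = FALSE], y[tr], lambda_grid[li]),
                      error = function(e) NULL)
      if (is.null(fit)) { errs <- Inf; break }
      pred <- predict(fit, X[!tr, , drop = FALSE])
      errs <- errs + sum((y[!tr] - pred)^2)
    }
    mse[li] <- errs
  }
  lambda_grid[which.min(mse)]
}

.benchmark_result <- function(representation_name, model, per_fold_r2,
                              flags = character()) {
  structure(list(representation_name = representation_name, model = model,
                 per_fold_r2 = per_fold_r2,
                 mean_r2 = mean(per_fold_r2), sd_r2 = stats::sd(per_fold_r2),
                 flags = flags),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("%s [%s]: R2 = %.3f +/- %.3f over %d folds\n",
              x$model, x$representation_name, x$mean_r2, x$sd_r2,
              length(x$per_fold_r2)))
  if (length(x$flags)) cat("  flags:", length(x$flags), "\n")
  invisible(x)
}

# Join per-interaction feature rows out of item-level representations,
# erroring when an interaction's odorant/receptor has no representation row.
.pair_features <- function(dataset, chem_rep, prot_rep = NULL) {
  it <- dataset$interactions
  mo <- match(it$odorant_id, chem_rep$item_ids)
  if (anyNA(mo))
    stop("odorant(s) missing from chemical representation: ",
         paste(utils::head(unique(it$odorant_id[is.na(mo)]), 5), collapse = ", "))
  out <- chem_rep$values[mo, , drop = FALSE]
  if (!is.null(prot_rep)) {
    mr <- match(it$receptor_id, prot_rep$item_ids)
    if (anyNA(mr))
      stop("receptor(s) missing from protein representation: ",
           paste(utils::head(unique(it$receptor_id[is.na(mr)]), 5), collapse = ", "))
    out <- cbind(out, prot_rep$values[mr, , drop = FALSE])
  }
  rownames(out) <- NULL
  out
}

#' Molecule-only (MO) benchmark
#'
#' For each cross-validation fold, fits an independent ridge model per
#' receptor on that receptor's training interactions (penalty selected by
#' inner 3-fold CV over `lambda_grid`), predicts the receptor's test
#' interactions, and averages per-receptor R-squared values without
#' weighting. Tests whether chemical information alone predicts activation.
#'
#' @param dataset regression-mode [interaction_dataset()].
#' @param featurizer_name registered molecule featurizer, or a precomputed
#'   [representation_matrix()] over the dataset's odorants.
#' @param folds number of CV folds (default 5).
#' @param lambda_grid candidate ridge penalties.
#' @param seed fold-assignment seed.
#' @param registry optional featurizer registry.
#' @return a `benchmark_result`; receptors with constant training responses
#'   (predicting a constant) or degenerate test variance are recorded in
#'   `flags`.
#' @export
run_mo <- function(dataset, featurizer_name, folds = 5L,
                   lambda_grid = .default_lambda_grid(), seed = 1L,
                   registry = NULL) {
  if (dataset$mode != "regression") stop("MO requires a regression dataset")
  chem <- if (inherits(featurizer_name, "representation_matrix"))
    featurizer_name else featurize_molecules(featurizer_name, dataset$odorants,
                                             registry)
  rep_name <- chem$name
  X <- .pair_features(dataset, chem)
  y <- dataset$interactions$response
  rec <- dataset$interactions$receptor_id
  split <- make_splits(dataset, scenario = "random", k = folds, seed = seed,
                       val_fraction = 0)
  flags <- character()
  fold_scores <- numeric(folds)
  for (f in seq_len(folds)) {
    tr_idx <- c(split$folds[[f]]$train, split$folds[[f]]$val)
    te_idx <- split$folds[[f]]$test
    r2s <- c()
    for (r in unique(rec)) {
      tr <- tr_idx[rec[tr_idx] == r]
      te <- te_idx[rec[te_idx] == r]
      if (length(te) < 2) next
      if (length(tr) < 2 || stats::var(y[tr]) == 0) {
        pred <- rep(mean(y[tr]), length(te))
        flags <- c(flags, sprintf("fold %d receptor %s: constant training response", f, r))
      } else {
        lam <- .select_lambda(X[tr, , drop = FALSE], y[tr], lambda_grid,
                              seed = seed + f)
        fit <- ridge_fit(X[tr, , drop = FALSE], y[tr], lam)
        pred <- predict(fit, X[te, , drop = FALSE])
      }
      if (stats::var(y[te]) == 0) {
        flags <- c(flags, sprintf("fold %d receptor %s: zero test variance", f, r))
        next
      }
      r2s <- c(r2s, .r_squared(y[te], pred))
    }
    fold_scores[f] <- mean(r2s)
  }
  .benchmark_result(rep_name, "MO", fold_scores, flags)
}

#' Molecule + protein (MP) benchmark
#'
#' Fits, per cross-validation fold, a single ridge model on the horizontal
#' concatenation of odorant and receptor features across all interactions,
#' and reports R-squared on each fold's pooled test set. Tests whether adding
#' receptor identity information improves prediction.
#'
#' @inheritParams run_mo
#' @param chem_featurizer registered molecule featurizer name or a
#'   `representation_matrix` over the odorants.
#' @param prot_featurizer function from receptor records to a
#'   `representation_matrix` (e.g. [kmer_protein_featurizer()]), or a
#'   precomputed `representation_matrix` over the receptors.
#' @return a `benchmark_result`.
#' @export
run_mp <- function(dataset, chem_featurizer, prot_featurizer, folds = 5L,
                   lambda_grid = .default_lambda_grid(), seed = 1L,
                   registry = NULL) {
  if (dataset$mode != "regression") stop("MP requires a regression dataset")
  chem <- if (inherits(chem_featurizer, "representation_matrix"))
    chem_featurizer else featurize_molecules(chem_featurizer,
                                             dataset$odorants, registry)
  prot <- if (inherits(prot_featurizer, "representation_matrix"))
    prot_featurizer else prot_featurizer(dataset$receptors)
  X <- .pair_features(dataset, chem, prot)
  y <- dataset$interactions$response
  split <- make_splits(dataset, scenario = "random", k = folds, seed = seed,
                       val_fraction = 0)
  fold_scores <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- c(split$folds[[f]]$train, split$folds[[f]]$val)
    te <- split$folds[[f]]$test
    lam <- .select_lambda(X[tr, , drop = FALSE], y[tr], lambda_grid,
                          seed = seed + f)
    fit <- ridge_fit(X[tr, , drop = FALSE], y[tr], lam)
    fold_scores[f] <- .r_squared(y[te], predict(fit, X[te, , drop = FALSE]))
  }
  .benchmark_result(paste0(chem$name, "+", prot$name), "MP", fold_scores)
}
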