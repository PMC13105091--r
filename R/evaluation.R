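# Cross-validation splits, prediction metrics, the naive baseline, quality
# weighting, and statistical comparison of models across folds.

# R-squared with SStot about the test-set mean. Predicting the test mean
# scores exactly 0; worse-than-mean predictions go negative.
.r_squared <- function(y_true, y_pred, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(y_true))
  ss_res <- sum(weights * (y_true - y_pred)^2)
  mu <- sum(weights * y_true) / sum(weights)
  ss_tot <- sum(weights * (y_true - mu)^2)
  1 - ss_res / ss_tot
}

#' Construct cross-validation splits
#'
#' Three scenarios: `"random"` shuffles interactions into k folds;
#' `"unseen_odorant"` folds odorant IDs so that no odorant in a fold's test
#' set ever appears in its train or validation sets (interactions follow
#' their odorant); `"unseen_receptor"` is symmetric for receptors. Within
#' each fold a validation portion is carved from the training side at
#' `val_fraction` (entity-respecting under the entity scenarios).
#'
#' @param dataset an [interaction_dataset()].
#' @param scenario `"random"`, `"unseen_odorant"`, or `"unseen_receptor"`.
#' @param k number of folds (>= 2).
#' @param seed integer; identical seeds give identical splits.
#' @param val_fraction fraction of the training portion held out for
#'   validation (0 disables the validation set).
#' @return object of class `cv_split`: `folds` is a list of k lists with
#'   disjoint integer vectors `train`, `val`, `test` indexing
#'   `dataset$interactions`; test sets partition all interactions.
#' @export
make_splits <- function(dataset, scenario = c("random", "unseen_odorant",
                                              "unseen_receptor"),
                        k = 5L, seed = 1L, val_fraction = 0.15) {
  scenario <- match.arg(scenario)
  k <- as.integer(k)
  if (k < 2) stop("k must be >= 2")
  it <- dataset$interactions
  n <- nrow(it)
  folds <- vector("list", k)
  .with_private_seed(seed, function() {
    if (scenario == "random") {
      assign_fold <- sample(rep_len(seq_len(k), n))
      for (f in seq_len(k)) {
        test <- which(assign_fold == f)
        rest <- which(assign_fold != f)
        nval <- round(val_fraction * length(rest))
        val <- if (nval > 0) sample(rest, nval) else integer(0)
        folds[[f]] <<- list(train = setdiff(rest, val), val = val, test = test)
      }
    } else {
      ent_col <- if (scenario == "unseen_odorant") "odorant_id" else "receptor_id"
      entities <- unique(it[[ent_col]])
      if (length(entities) < k)
        stop("only ", length(entities), " distinct ",
             sub("_id", "", ent_col), "s for k = ", k, " folds")
      ent_fold <- sample(rep_len(seq_len(k), length(entities)))
      names(ent_fold) <- entities
      for (f in seq_len(k)) {
        test_ent <- entities[ent_fold == f]
        rest_ent <- entities[ent_fold != f]
        nval <- round(val_fraction * length(rest_ent))
        val_ent <- if (nval > 0) sample(rest_ent, nval) else character(0)
        train_ent <- setdiff(rest_ent, val_ent)
        folds[[f]] <<- list(train = which(it[[ent_col]] %in% train_ent),
                            val = which(it[[ent_col]] %in% val_ent),
                            test = which(it[[ent_col]] %in% test_ent))
      }
    }
  })
  structure(list(scenario = scenario, k = k, seed = seed,
                 val_fraction = val_fraction, folds = folds),
            class = "cv_split")
}

#' @export
print.cv_split <- function(x, ...) {
  sizes <- vapply(x$folds, function(f) lengths(f), integer(3))
  cat(sprintf("cv_split: %s, k = %d, seed = %d\n", x$scenario, x$k, x$seed))
  cat("  fold sizes (train/val/test):",
      paste(apply(sizes, 2, paste, collapse = "/"), collapse = "  "), "\n")
  invisible(x)
}

#' Compute prediction metrics
#'
#' Regression mode reports R-squared (SStot about the test mean).
#' Classification mode expects probabilities and reports AUROC (tie-averaged
#' rank statistic), average precision (step-interpolated precision-recall),
#' and threshold metrics (precision, recall, F-score, MCC) at `threshold`.
#' MCC returns 0 when any factor of its denominator is 0. With a single class
#' in `y_true`, AUROC and AveP are returned as `NA` and listed in the
#' `undefined` field rather than propagating NaN.
#'
#' @param y_true observed values (0/1 in classification mode).
#' @param y_pred predictions (probabilities in classification mode).
#' @param mode `"regression"` or `"classification"`.
#' @param threshold classification decision threshold (default 0.5).
#' @param weights optional non-negative record weights; applied to R-squared
#'   and to the confusion-matrix metrics, not to the ranking metrics.
#' @return object of class `metric_report` (a list of populated metrics).
#' @export
compute_metrics <- function(y_true, y_pred,
                            mode = c("regression", "classification"),
                            threshold = 0.5, weights = NULL) {
  mode <- match.arg(mode)
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (length(y_true) < 2) stop("need at least 2 observations")
  if (mode == "regression") {
    out <- list(r2 = .r_squared(y_true, y_pred, weights))
  } else {
    if (!all(y_true %in% c(0, 1))) stop("classification y_true must be 0/1")
    if (is.null(weights)) weights <- rep(1, length(y_true))
    undefined <- character()
    npos <- sum(y_true == 1); nneg <- sum(y_true == 0)
    if (npos == 0 || nneg == 0) {
      auroc <- NA_real_; avep <- NA_real_
      undefined <- c("auroc", "avep")
    } else {
      r <- rank(y_pred)  # ties averaged
      auroc <- (sum(r[y_true == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
      # step-interpolated PR curve, tie-aware: evaluate at distinct cutoffs
      ord <- order(y_pred, decreasing = TRUE)
      ys <- y_true[ord]; ps <- y_pred[ord]
      cum_tp <- cumsum(ys == 1)
      last <- which(diff(c(ps, -Inf)) != 0)  # end of each tie block
      prec <- cum_tp[last] / last
      rec <- cum_tp[last] / npos
      avep <- sum(prec * diff(c(0, rec)))
    }
    yhat <- as.integer(y_pred >= threshold)
    tp <- sum(weights * (yhat == 1 & y_true == 1))
    fp <- sum(weights * (yhat == 1 & y_true == 0))
    fn <- sum(weights * (yhat == 0 & y_true == 1))
    tn <- sum(weights * (yhat == 0 & y_true == 0))
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall <- if (tp + fn > 0) tp / (tp + fn) else 0
    f_score <- if (precision + recall > 0)
      2 * precision * recall / (precision + recall) else 0
    denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
    mcc <- if (denom > 0) (tp * tn - fp * fn) / sqrt(denom) else 0
    out <- list(auroc = auroc, avep = avep, precision = precision,
                recall = recall, f_score = f_score, mcc = mcc,
                undefined = undefined)
  }
  structure(out, class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  vals <- x[vapply(x, is.numeric, logical(1))]
  cat("metric_report:",
      paste(sprintf("%s = %.4f", names(vals), unlist(vals)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Naive mean-prediction baseline
#'
#' Predicts the mean of the training responses for every test record and
#' reports the resulting R-squared. Because SStot is taken about the test
#' mean, the score is typically at or below 0, and exactly 0 only when the
#' training and test means coincide.
#'
#' @param train_y training responses.
#' @param test_y test responses.
#' @return a `metric_report` with `r2` and the constant `prediction`.
#' @export
naive_baseline <- function(train_y, test_y) {
  if (length(train_y) < 1) stop("empty training set")
  pred <- rep(mean(train_y), length(test_y))
  rep_out <- compute_metrics(test_y, pred, mode = "regression")
  rep_out$prediction <- mean(train_y)
  rep_out
}

#' Apply quality-tier weights to a dataset
#'
#' Maps each interaction's quality tier (e.g. `"ec50"`, `"primary"`,
#' `"secondary"`) to a non-negative training weight. Weights flow into the
#' transformer loss, the tree-ensemble fit, and weighted metrics.
#'
#' @param dataset an [interaction_dataset()].
#' @param weighting named numeric vector or list, tier -> weight >= 0. Every
#'   tier present in the dataset must be mapped.
#' @return the dataset with `interactions$weight` set.
#' @export
apply_tier_weights <- function(dataset, weighting) {
  weighting <- unlist(weighting)
  if (any(weighting < 0) || any(!is.finite(weighting)))
    stop("tier weights must be finite and >= 0")
  tiers <- unique(dataset$interactions$tier)
  tiers <- tiers[!is.na(tiers)]
  unmapped <- setdiff(tiers, names(weighting))
  if (length(unmapped))
    stop("unmapped tier(s): ", paste(unmapped, collapse = ", "))
  if (anyNA(dataset$interactions$tier))
    stop("dataset has interactions with no tier; cannot apply tier weights")
  dataset$interactions$weight <-
    unname(weighting[dataset$interactions$tier])
  dataset
}

#' Compare models across cross-validation folds
#'
#' Given a models x folds score table (folds aligned across models), runs one
#' of three paired comparison procedures: pairwise paired t-tests
#' (`"paired_t"`), a Friedman omnibus test followed by pairwise paired
#' Wilcoxon tests with Benjamini-Hochberg correction (`"friedman_bh"`), or a
#' one-way ANOVA followed by Tukey HSD with an additional Bonferroni
#' correction (`"anova_tukey_bonferroni"`). Pairs with zero score variance
#' are flagged `degenerate` with `p = NA`.
#'
#' @param score_table numeric matrix, rows = models (rownames required),
#'   columns = folds.
#' @param test comparison procedure.
#' @param alpha significance level for the `different` flag (default 0.05).
#' @return list with the omnibus p-value (where applicable) and a `pairs`
#'   data.frame (`model_a`, `model_b`, `p`, `p_adj`, `different`).
#' @export
compare_models <- function(score_table,
                           test = c("paired_t", "friedman_bh",
                                    "anova_tukey_bonferroni"),
                           alpha = 0.05) {
  test <- match.arg(test)
  score_table <- as.matrix(score_table)
  if (nrow(score_table) < 2) stop("need at least 2 models")
  if (is.null(rownames(score_table)))
    rownames(score_table) <- paste0("model", seq_len(nrow(score_table)))
  models <- rownames(score_table)
  k <- ncol(score_table)
  cmb <- utils::combn(models, 2)
  omnibus <- NA_real_

  pair_p <- function(a, b, fun) {
    d <- score_table[a, ] - score_table[b, ]
    if (stats::sd(d) == 0) return(NA_real_)
    fun(score_table[a, ], score_table[b, ])
  }
  if (test == "paired_t") {
    p <- apply(cmb, 2, function(pr) pair_p(pr[1], pr[2], function(x, y)
      stats::t.test(x, y, paired = TRUE)$p.value))
    p_adj <- p
  } else if (test == "friedman_bh") {
    long <- data.frame(score = as.vector(score_table),
                       model = factor(rep(models, k)),
                       fold = factor(rep(seq_len(k), each = nrow(score_table))))
    omnibus <- stats::friedman.test(score ~ model | fold, data = long)$p.value
    p <- apply(cmb, 2, function(pr) pair_p(pr[1], pr[2], function(x, y)
      suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                          exact = FALSE)$p.value)))
    p_adj <- stats::p.adjust(p, method = "BH")
  } else {
    long <- data.frame(score = as.vector(score_table),
                       model = factor(rep(models, k)))
    fit <- stats::aov(score ~ model, data = long)
    omnibus <- summary(fit)[[1]][["Pr(>F)"]][1]
    tk <- stats::TukeyHSD(fit)$model
    # order Tukey rows to match our pair enumeration
    want <- apply(cmb, 2, function(pr) {
      rn <- rownames(tk)
      hit <- rn == paste(pr[2], pr[1], sep = "-") |
        rn == paste(pr[1], pr[2], sep = "-")
      tk[hit, "p adj"]
    })
    p <- unname(want)
    p_adj <- pmin(p * ncol(cmb), 1)  # extra Bonferroni over the pairs
  }
  pairs <- data.frame(model_a = cmb[1, ], model_b = cmb[2, ],
                      p = p, p_adj = p_adj,
                      different = !is.na(p_adj) & p_adj < alpha,
                      degenerate = is.na(p),
                      stringsAsFactors = FALSE)
  list(test = test, omnibus_p = omnibus, pairs = pairs, alpha = alpha)
}
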