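test_that("random splits partition interactions with carved validation sets", {
  panel <- gen_panel(10, 10, seed = 1)
  sp <- make_splits(panel$dataset, "random", k = 5, seed = 2)
  test_sizes <- vapply(sp$folds, function(f) length(f$test), integer(1))
  expect_true(all(test_sizes == 20))
  all_test <- sort(unlist(lapply(sp$folds, `[[`, "test")))
  expect_equal(all_test, 1:100)
  for (f in sp$folds) {
    expect_length(intersect(f$train, f$val), 0)
    expect_length(intersect(f$train, f$test), 0)
    expect_length(intersect(f$val, f$test), 0)
    expect_equal(sort(c(f$train, f$val, f$test)), 1:100)
  }
  sp2 <- make_splits(panel$dataset, "random", k = 5, seed = 2)
  expect_identical(sp, sp2)
})

test_that("entity scenarios keep test entities out of train and validation", {
  panel <- gen_panel(12, 8, seed = 3)
  it <- panel$dataset$interactions
  for (scen in c("unseen_odorant", "unseen_receptor")) {
    col <- if (scen == "unseen_odorant") "odorant_id" else "receptor_id"
    sp <- make_splits(panel$dataset, scen, k = 4, seed = 5)
    for (f in sp$folds) {
      expect_length(intersect(it[[col]][c(f$train, f$val)],
                              it[[col]][f$test]), 0)
    }
    all_test <- sort(unlist(lapply(sp$folds, `[[`, "test")))
    expect_equal(all_test, seq_len(nrow(it)))
  }
  expect_error(make_splits(panel$dataset, "unseen_receptor", k = 9),
               "distinct")
})

test_that("split invariants hold across 100 random configurations", {
  set.seed(77)
  for (trial in 1:100) {
    n_o <- sample(6:14, 1); n_r <- sample(4:10, 1)
    k <- sample(2:4, 1)
    scen <- sample(c("random", "unseen_odorant", "unseen_receptor"), 1)
    panel <- gen_panel(n_o, n_r, seed = trial)
    sp <- make_splits(panel$dataset, scen, k = k, seed = trial + 1,
                      val_fraction = runif(1, 0, 0.3))
    it <- panel$dataset$interactions
    got <- sort(unlist(lapply(sp$folds, `[[`, "test")))
    expect_equal(got, seq_len(nrow(it)))
    for (f in sp$folds) {
      expect_length(intersect(f$train, f$val), 0)
      expect_length(intersect(c(f$train, f$val), f$test), 0)
      if (scen != "random") {
        col <- if (scen == "unseen_odorant") "odorant_id" else "receptor_id"
        expect_length(intersect(it[[col]][c(f$train, f$val)],
                                it[[col]][f$test]), 0)
      }
    }
  }
})

test_that("regression and classification metrics match their definitions", {
  y <- c(0.2, 1.4, -0.3, 2.2)
  expect_equal(compute_metrics(y, y, "regression")$r2, 1)
  # perfect classification
  m <- compute_metrics(c(0, 1, 0, 1), c(0.1, 0.9, 0.2, 0.8),
                       "classification")
  expect_equal(m$mcc, 1)
  expect_equal(m$f_score, 1)
  expect_equal(m$auroc, 1)
  # balanced confusion (1,1,1,1) has zero MCC
  m2 <- compute_metrics(c(1, 0, 1, 0), c(0.9, 0.9, 0.1, 0.1),
                        "classification")
  expect_equal(m2$mcc, 0)
  # confusion (TP, FP, FN, TN) = (8, 2, 1, 9)
  y3 <- c(rep(1, 8), rep(0, 2), rep(1, 1), rep(0, 9))
  p3 <- c(rep(0.9, 10), rep(0.1, 10))
  m3 <- compute_metrics(y3, p3, "classification")
  expect_equal(m3$precision, 0.8)
  expect_equal(m3$recall, 8 / 9)
  expect_equal(m3$mcc, oracle_mcc(8, 2, 1, 9), tolerance = 1e-12)
  expect_equal(m3$mcc, 70 / sqrt(9900), tolerance = 1e-12)
  # single-class truth flags ranking metrics instead of NaN
  m4 <- compute_metrics(c(1, 1, 1), c(0.2, 0.5, 0.9), "classification")
  expect_true(is.na(m4$auroc))
  expect_setequal(m4$undefined, c("auroc", "avep"))
})

test_that("ranking metrics agree with enumeration oracles on random vectors", {
  set.seed(99)
  for (trial in 1:200) {
    n <- sample(10:40, 1)
    y <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(y)) < 2) next
    p <- round(runif(n), 2)  # coarse grid forces ties
    m <- compute_metrics(y, p, "classification")
    expect_equal(m$auroc, oracle_auroc(y, p), tolerance = 1e-8)
    expect_equal(m$avep, oracle_avep(y, p), tolerance = 1e-8)
  }
})

test_that("AUROC matches pROC on random data", {
  skip_if_not_installed("pROC")
  set.seed(4)
  y <- rbinom(60, 1, 0.4)
  p <- runif(60)
  m <- compute_metrics(y, p, "classification")
  expect_equal(m$auroc,
               as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE,
                                              direction = "<",
                                              levels = c(0, 1)))),
               tolerance = 1e-8)
})

test_that("the naive baseline scores by the test-mean R2 convention", {
  expect_equal(naive_baseline(c(2, 4), c(1, 5))$r2, 0)      # equal means
  expect_equal(naive_baseline(c(0, 0), c(1, -1))$r2, 0)
  expect_equal(naive_baseline(c(5, 5), c(0, 1, 2))$r2, -24)
  expect_error(naive_baseline(numeric(0), c(1, 2)), "empty")
  # predicting the test mean never beats zero under this convention
  set.seed(12)
  for (i in 1:20) {
    tr <- rnorm(10); te <- rnorm(8)
    expect_lte(naive_baseline(tr, te)$r2, 0 + 1e-12)
  }
})

test_that("tier weighting maps tiers to weights and neutral weights change nothing", {
  screen <- gen_sparse_screen(20, 15, density = 0.4, positive_rate = 0.3,
                              seed = 6)
  ds <- screen$dataset
  w <- apply_tier_weights(ds, c(ec50 = 1, primary = 0.3, secondary = 0.1))
  expect_equal(unique(w$interactions$weight[w$interactions$tier == "ec50"]), 1)
  expect_equal(unique(w$interactions$weight[w$interactions$tier == "primary"]),
               0.3)
  expect_error(apply_tier_weights(ds, c(ec50 = 1)), "unmapped tier")
  expect_error(apply_tier_weights(ds, c(ec50 = -1, primary = 1,
                                        secondary = 1)), ">= 0")
  # all-ones weighting reproduces the unweighted metrics exactly
  y <- ds$interactions$label
  set.seed(3)
  p <- runif(length(y))
  ones <- apply_tier_weights(ds, c(ec50 = 1, primary = 1, secondary = 1))
  m_w <- compute_metrics(y, p, "classification",
                         weights = ones$interactions$weight)
  m_u <- compute_metrics(y, p, "classification")
  expect_identical(m_w$mcc, m_u$mcc)
  expect_identical(m_w$f_score, m_u$f_score)
})

test_that("model comparison flags degenerate pairs and detects separation", {
  scores <- rbind(a = c(0.5, 0.6, 0.55, 0.62, 0.58),
                  b = c(0.5, 0.6, 0.55, 0.62, 0.58))
  cmp <- compare_models(scores, "paired_t")
  expect_true(cmp$pairs$degenerate[1])
  # a uniform gap with small jitter is significant and matches t.test
  set.seed(10)
  jit <- rnorm(5, sd = 0.01)
  scores2 <- rbind(good = c(10, 10.2, 9.9, 10.1, 10) + jit,
                   bad = c(0.1, 0.2, 0.15, 0.12, 0.18))
  cmp2 <- compare_models(scores2, "paired_t")
  expect_lt(cmp2$pairs$p[1], 0.05)
  expect_equal(cmp2$pairs$p[1],
               t.test(scores2[1, ], scores2[2, ], paired = TRUE)$p.value)
  expect_true(cmp2$pairs$different[1])
})

test_that("Friedman post-hoc ranks a uniformly worst model as most different", {
  set.seed(11)
  k <- 8
  base <- matrix(rnorm(2 * k, mean = 1, sd = 0.05), 2, k)
  worst <- rnorm(k, mean = 0, sd = 0.05)
  scores <- rbind(m1 = base[1, ], m2 = base[2, ], m3 = worst)
  cmp <- compare_models(scores, "friedman_bh")
  expect_lt(cmp$omnibus_p, 0.05)
  with_worst <- cmp$pairs$model_a == "m3" | cmp$pairs$model_b == "m3"
  expect_lt(min(cmp$pairs$p_adj[with_worst]),
            min(cmp$pairs$p_adj[!with_worst]))
})

test_that("ANOVA with Bonferroni-corrected Tukey post-hoc separates group means", {
  set.seed(14)
  k <- 6
  scores <- rbind(hi = rnorm(k, 1, 0.05),
                  mid = rnorm(k, 1, 0.05),
                  lo = rnorm(k, 0.2, 0.05))
  cmp <- compare_models(scores, "anova_tukey_bonferroni")
  expect_lt(cmp$omnibus_p, 0.01)
  hl <- cmp$pairs$model_a == "hi" & cmp$pairs$model_b == "lo"
  expect_true(cmp$pairs$different[hl])
  hm <- cmp$pairs$model_a == "hi" & cmp$pairs$model_b == "mid"
  expect_false(cmp$pairs$different[hm])
})
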