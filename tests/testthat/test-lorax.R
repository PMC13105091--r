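# Architectural identities and training contracts of the multi-modal model.

small_model <- function(mode = "regression", enabled = TRUE, r = 2,
                        seed = 5) {
  build_lorax_model(mode,
                    lora = lora_config(r = r, enabled = enabled),
                    fusion = fusion_config(model_dim = 8, n_heads = 2,
                                           feedforward_dim = 12),
                    encoder = encoder_config(n_layers = 2, max_len = 32),
                    seed = seed)
}

test_that("apply_lora computes W x + (alpha/r) B A x and respects zero init", {
  set.seed(1)
  W <- matrix(rnorm(12), 3, 4)
  A <- matrix(rnorm(8), 2, 4)
  B0 <- matrix(0, 3, 2)
  x <- rnorm(4)
  expect_equal(apply_lora(W, A, B0, alpha = 2, r = 2, x), drop(W %*% x))
  # identity algebra: W = I, A = I, B = I, r = 2, alpha = 2, x = (1,1) -> (2,2)
  expect_equal(apply_lora(diag(2), diag(2), diag(2), alpha = 2, r = 2,
                          c(1, 1)), c(2, 2))
  # rank of the update matrix is bounded by r
  A1 <- matrix(rnorm(5), 1, 5)
  B1 <- matrix(rnorm(5), 5, 1)
  expect_lte(qr((3 / 1) * B1 %*% A1)$rank, 1)
  expect_error(apply_lora(W, A, B0, 2, 2, rnorm(3)), "shape mismatch")
  expect_error(apply_lora(W, matrix(rnorm(6), 2, 3), B0, 2, 2, x),
               "shape mismatch")
})

test_that("LoRA parameter counts are r * (d_in + d_out) summed over targets", {
  cfg4 <- lora_config(r = 4, target_matrices = "Wq")
  expect_equal(lora_param_count(list(Wq = c(64, 64)), cfg4), 512L)
  cfg2 <- lora_config(r = 2, target_matrices = c("Wq", "Wv"))
  dims <- list("l1.Wq" = c(32, 32), "l1.Wv" = c(32, 32),
               "l2.Wq" = c(32, 32), "l2.Wv" = c(32, 32))
  expect_equal(lora_param_count(dims, cfg2), 512L)
  cfg4b <- lora_config(r = 4, target_matrices = c("Wq", "Wv"))
  expect_equal(lora_param_count(dims, cfg4b),
               2L * lora_param_count(dims, cfg2))
  expect_error(lora_param_count(list(Wq = c(8, 8)),
                                lora_config(r = 2, target_matrices =
                                              c("Wq", "Wv"))),
               "unknown target")
  # counting a built model's adapters agrees with the formula
  m <- small_model(r = 2)
  expect_equal(lora_param_count(m, m$lora),
               length(m$adapted) * 2L * (8L + 8L))
})

test_that("zero-initialized adapters leave the forward pass bit-identical", {
  panel <- gen_panel(6, 4, seed = 3)
  m_on <- small_model(enabled = TRUE)
  m_off <- small_model(enabled = FALSE)
  p_on <- predict_transformer(m_on, panel$dataset)
  p_off <- predict_transformer(m_off, panel$dataset)
  expect_identical(p_on, p_off)
  # B matrices are zero at initialization and A matrices random
  bs <- grep("^lora\\..*\\.B$", names(m_on$theta), value = TRUE)
  expect_true(all(vapply(bs, function(nm) all(m_on$theta[[nm]] == 0),
                         logical(1))))
})

test_that("hand-derived gradients match finite differences", {
  m <- small_model()
  panel <- gen_panel(4, 3, seed = 3)
  ds <- panel$dataset
  tok <- loraxr:::.token_tables(m, ds)
  oid <- ds$interactions$odorant_id[1]
  rid <- ds$interactions$receptor_id[1]
  y <- ds$interactions$response[1]
  pair_loss <- function(model) {
    ce <- loraxr:::.encode_fwd(model, "chem", tok$chem[[oid]])
    pe <- loraxr:::.encode_fwd(model, "prot", tok$prot[[rid]])
    (loraxr:::.fuse_fwd(model, ce$out, pe$out)$pred - y)^2
  }
  trainable <- loraxr:::.trainable_names(m, "lora_chem_and_protein")
  grads <- new.env(); want <- new.env()
  for (nm in trainable) assign(nm, TRUE, want)
  ce <- loraxr:::.encode_fwd(m, "chem", tok$chem[[oid]], training = TRUE)
  pe <- loraxr:::.encode_fwd(m, "prot", tok$prot[[rid]], training = TRUE)
  fw <- loraxr:::.fuse_fwd(m, ce$out, pe$out, training = TRUE)
  bw <- loraxr:::.fuse_bwd(m, 2 * (fw$pred - y), fw$cache, grads, want,
                           need_chem = TRUE, need_prot = TRUE)
  loraxr:::.encode_bwd(m, "chem", bw$dXc, ce$caches, grads, want)
  loraxr:::.encode_bwd(m, "prot", bw$dXp, pe$caches, grads, want)
  set.seed(2)
  eps <- 1e-5
  for (nm in sample(trainable, 15)) {
    g <- grads[[nm]]
    expect_false(is.null(g), info = nm)
    i <- sample(length(m$theta[[nm]]), 1)
    orig <- m$theta[[nm]]
    m$theta[[nm]][i] <- orig[i] + eps
    up <- pair_loss(m)
    m$theta[[nm]][i] <- orig[i] - eps
    dn <- pair_loss(m)
    m$theta[[nm]] <- orig
    num <- (up - dn) / (2 * eps)
    expect_lt(abs(num - g[i]) / max(1e-6, abs(num) + abs(g[i])), 1e-4)
  }
})

test_that("fuse_forward is deterministic, mask-invariant, and batch-consistent", {
  m <- small_model()
  set.seed(6)
  Xc <- matrix(rnorm(5 * 8), 5, 8)
  Xp <- matrix(rnorm(7 * 8), 7, 8)
  f1 <- fuse_forward(m, Xc, NULL, Xp, NULL)
  f2 <- fuse_forward(m, Xc, NULL, Xp, NULL)
  expect_identical(f1$prediction, f2$prediction)
  # appending padded protein positions leaves the output unchanged
  Xp_pad <- rbind(Xp, matrix(rnorm(3 * 8), 3, 8))
  mask <- c(rep(FALSE, 7), rep(TRUE, 3))
  f3 <- fuse_forward(m, Xc, NULL, Xp_pad, mask)
  expect_equal(f3$prediction, f1$prediction, tolerance = 1e-6)
  expect_equal(f3$cls_vector, f1$cls_vector, tolerance = 1e-6)
  # and changing the padded values does not move the output at all
  Xp_pad2 <- Xp_pad
  Xp_pad2[8:10, ] <- 99
  f4 <- fuse_forward(m, Xc, NULL, Xp_pad2, mask)
  expect_identical(f3$prediction, f4$prediction)
  # batch call equals stacked single calls
  Xc2 <- matrix(rnorm(4 * 8), 4, 8)
  fb <- fuse_forward(m, list(Xc, Xc2), NULL, list(Xp, Xp), NULL)
  s1 <- fuse_forward(m, Xc, NULL, Xp, NULL)
  s2 <- fuse_forward(m, Xc2, NULL, Xp, NULL)
  expect_equal(fb$prediction, c(s1$prediction, s2$prediction),
               tolerance = 1e-12)
  expect_error(fuse_forward(m, Xc, c(TRUE, FALSE), Xp, NULL),
               "mask length")
})

test_that("stage-1 training respects scope, freezing, and checkpointing", {
  panel <- gen_panel(10, 5, seed = 9)
  ds <- zscore_global(panel$dataset)$dataset
  sp <- make_splits(ds, "random", k = 3, seed = 2)$folds[[1]]
  split <- list(train = sp$train, val = sp$val)
  m <- small_model()
  # epochs = 0 returns an identical model and empty history
  st0 <- train_stage1(m, ds, split, train_config(epochs = 0))
  nms <- sort(names(m$theta))
  expect_identical(mget(nms, envir = st0$model$theta),
                   mget(nms, envir = m$theta))
  expect_equal(nrow(st0$history), 0)
  # head_and_fusion_only: adapter B matrices stay exactly zero
  st1 <- train_stage1(m, ds, split,
                      train_config(epochs = 2, seed = 3,
                                   trainable_scope = "head_and_fusion_only"))
  bs <- grep("^lora\\..*\\.B$", names(st1$model$theta), value = TRUE)
  expect_true(all(vapply(bs, function(nm)
    all(st1$model$theta[[nm]] == 0), logical(1))))
  # base encoder weights are frozen under every scope
  st2 <- train_stage1(m, ds, split,
                      train_config(epochs = 2, seed = 3))
  base <- grep("^(chem|prot)\\.", names(m$theta), value = TRUE)
  for (nm in base)
    expect_identical(st2$model$theta[[nm]], m$theta[[nm]])
  # adapters did move under lora_chem_only
  bs_chem <- grep("^lora\\.chem\\..*\\.B$", names(st2$model$theta),
                  value = TRUE)
  expect_gt(max(vapply(bs_chem, function(nm)
    max(abs(st2$model$theta[[nm]])), numeric(1))), 0)
  # history logs one validation score per epoch; the restored checkpoint
  # reproduces the best of them
  expect_equal(nrow(st2$history), 2)
  val_pred <- predict_transformer(st2$model, ds, sp$val)
  expect_equal(loraxr:::.r_squared(ds$interactions$response[sp$val],
                                   val_pred),
               max(st2$history$val_metric), tolerance = 1e-10)
  expect_error(train_stage1(m, ds, list(train = sp$train, val = integer(0)),
                            train_config(epochs = 1)),
               "non-empty")
})

test_that("identical seeds give identical training histories", {
  panel <- gen_panel(8, 4, seed = 13)
  ds <- zscore_global(panel$dataset)$dataset
  sp <- make_splits(ds, "random", k = 3, seed = 2)$folds[[1]]
  m <- small_model()
  h1 <- train_stage1(m, ds, sp, train_config(epochs = 2, seed = 4))$history
  h2 <- train_stage1(m, ds, sp, train_config(epochs = 2, seed = 4))$history
  expect_identical(h1$val_metric, h2$val_metric)
})

test_that("cls feature extraction is deterministic and adapter-consistent", {
  panel <- gen_panel(6, 3, seed = 21)
  ds <- panel$dataset
  m_on <- small_model(enabled = TRUE)
  m_off <- small_model(enabled = FALSE)
  cls <- extract_cls_features(m_on, ds)
  expect_equal(dim(cls$values), c(n_interactions(ds), 8))
  # identical pairs produce identical rows
  idx <- c(1, 1, 2)
  cls2 <- extract_cls_features(m_on, ds, idx = c(1, 2))
  expect_equal(unname(cls$values[1, ]), unname(cls2$values[1, ]))
  # enabled-with-B-zero equals disabled
  cls_off <- extract_cls_features(m_off, ds)
  expect_identical(unname(cls$values), unname(cls_off$values))
  chem_emb <- extract_cls_features(m_on, ds, type = "chem_mean")
  expect_equal(dim(chem_emb$values), c(6, 8))
})

test_that("classification mode trains on weighted BCE and yields probabilities", {
  scr <- gen_sparse_screen(15, 10, density = 0.6, positive_rate = 0.3,
                           seed = 23)
  ds <- apply_tier_weights(scr$dataset,
                           c(ec50 = 1, primary = 0.5, secondary = 0.2))
  sp <- make_splits(ds, "random", k = 3, seed = 2)$folds[[1]]
  m <- build_lorax_model("classification",
                         lora = lora_config(r = 2),
                         fusion = fusion_config(model_dim = 8, n_heads = 2,
                                                feedforward_dim = 12),
                         seed = 31)
  expect_equal(m$fusion$head, "classification_logit")
  st <- train_stage1(m, ds, sp, train_config(epochs = 2, seed = 3,
                                             batch_size = 32))
  expect_equal(nrow(st$history), 2)
  p <- predict_transformer(st$model, ds)
  expect_true(all(p >= 0 & p <= 1))
  # the logged validation metric is the MCC of the restored checkpoint
  vm <- compute_metrics(ds$interactions$label[sp$val],
                        predict_transformer(st$model, ds, sp$val),
                        "classification")$mcc
  expect_equal(vm, max(st$history$val_metric), tolerance = 1e-10)
})
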