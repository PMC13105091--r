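# The LORAX multi-modal architecture: a chemical and a protein token encoder
# (tiny 2-layer self-attention transformers built over SMILES characters and
# amino acids), LoRA adapters on the chemical (optionally protein) encoder's
# query/value projections, a cross-attention fusion stack, a learned <cls>
# readout token, and a scalar prediction head. Stage-1 training updates only
# the adapters, fusion, <cls> and head; base encoder weights stay frozen.

.PROT_VOCAB <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

#' LoRA adapter configuration
#'
#' A rank-`r` low-rank update `(alpha/r) * B A` added to a frozen weight
#' matrix `W`. `A` is random-normal initialized (SD `1/sqrt(d_in)`), `B` is
#' zero-initialized, so an untrained adapter leaves the forward pass exactly
#' equal to the frozen model.
#'
#' @param r adapter rank (>= 1, at most the smaller dimension of every
#'   target matrix).
#' @param alpha scaling numerator; the effective scale is `alpha / r`
#'   (default `alpha = r`, i.e. unit scale).
#' @param target_matrices names of encoder weight matrices to adapt
#'   (default: attention query and value projections).
#' @param dropout dropout rate on the adapter input during training.
#' @param enabled logical; a disabled adapter set reproduces the frozen
#'   feature-based model.
#' @return object of class `lora_config`.
#' @export
lora_config <- function(r = 4L, alpha = r, target_matrices = c("Wq", "Wv"),
                        dropout = 0, enabled = TRUE) {
  r <- as.integer(r)
  if (r < 1) stop("r must be >= 1")
  if (alpha <= 0) stop("alpha must be > 0")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  if (!all(target_matrices %in% c("Wq", "Wv")))
    stop("adaptable target_matrices are the attention query (Wq) and value (Wv) projections")
  structure(list(r = r, alpha = alpha, target_matrices = target_matrices,
                 dropout = dropout, enabled = isTRUE(enabled)),
            class = "lora_config")
}

#' Fusion / readout configuration
#'
#' @param model_dim shared token dimensionality (divisible by `n_heads`).
#' @param n_cross_attention_layers number of cross-attention fusion layers.
#' @param n_heads attention heads.
#' @param feedforward_dim hidden width of the per-block feed-forward nets.
#' @param head `"regression_linear"` (identity output) or
#'   `"classification_logit"` (sigmoid output).
#' @return object of class `fusion_config`.
#' @export
fusion_config <- function(model_dim = 16L, n_cross_attention_layers = 1L,
                          n_heads = 2L, feedforward_dim = 32L,
                          head = c("regression_linear",
                                   "classification_logit")) {
  head <- match.arg(head)
  if (model_dim %% n_heads != 0)
    stop("model_dim must be divisible by n_heads")
  structure(list(model_dim = as.integer(model_dim),
                 n_cross_attention_layers = as.integer(n_cross_attention_layers),
                 n_heads = as.integer(n_heads),
                 feedforward_dim = as.integer(feedforward_dim),
                 cls_mode = "learned_token", head = head),
            class = "fusion_config")
}

#' Stage-1 training configuration
#'
#' @param epochs training epochs (>= 0; 0 returns the model untouched).
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param seed RNG seed for batch order, adapter dropout, and initialization
#'   of optimizer state.
#' @param loss `"mse"` (regression) or `"weighted_bce"` (classification);
#'   `NULL` picks by dataset mode.
#' @param early_stop_patience epochs without validation improvement before
#'   stopping; the best-validation checkpoint is restored either way.
#' @param trainable_scope `"lora_chem_only"` (adapt the chemical encoder),
#'   `"lora_chem_and_protein"`, or `"head_and_fusion_only"` (the frozen
#'   feature-based comparator). Fusion, <cls> and head always train.
#' @return object of class `train_config`.
#' @export
train_config <- function(epochs = 25L, batch_size = 64L, learning_rate = 3e-3,
                         seed = 1L, loss = NULL, early_stop_patience = 6L,
                         trainable_scope = c("lora_chem_only",
                                             "lora_chem_and_protein",
                                             "head_and_fusion_only")) {
  trainable_scope <- match.arg(trainable_scope)
  epochs <- as.integer(epochs)
  if (epochs < 0) stop("epochs must be >= 0")
  if (!is.null(loss) && !loss %in% c("mse", "weighted_bce"))
    stop("loss must be mse or weighted_bce")
  structure(list(epochs = epochs, batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 loss = loss, early_stop_patience = as.integer(early_stop_patience),
                 trainable_scope = trainable_scope),
            class = "train_config")
}

#' Encoder configuration for the built-in tiny transformers
#'
#' @param n_layers self-attention layers per encoder.
#' @param max_len token-sequence truncation length.
#' @return object of class `encoder_config`.
#' @export
encoder_config <- function(n_layers = 2L, max_len = 64L) {
  structure(list(n_layers = as.integer(n_layers),
                 max_len = as.integer(max_len)),
            class = "encoder_config")
}

#' Apply a LoRA update to activations
#'
#' Computes `W x + (alpha/r) B (A x)` without modifying the frozen base
#' weight `W`. With `B = 0` (the initialization state) the output equals
#' `W x` exactly.
#'
#' @param W frozen base weight, `d_out x d_in`.
#' @param A adapter down-projection, `r x d_in`.
#' @param B adapter up-projection, `d_out x r` (zero at initialization).
#' @param alpha scaling numerator (effective scale `alpha / r`).
#' @param r adapter rank.
#' @param x input activations: a length-`d_in` vector or `d_in x n` matrix.
#' @return `W x + (alpha/r) B A x`, same shape as `W x`.
#' @export
apply_lora <- function(W, A, B, alpha, r, x) {
  x <- as.matrix(x)
  if (ncol(W) != nrow(x))
    stop("shape mismatch: W is ", nrow(W), "x", ncol(W), ", x has ",
         nrow(x), " rows")
  if (ncol(A) != ncol(W) || nrow(B) != nrow(W) || nrow(A) != r ||
      ncol(B) != r)
    stop("shape mismatch: A must be ", r, "x", ncol(W), " and B ",
         nrow(W), "x", r, "; got A ", nrow(A), "x", ncol(A), ", B ",
         nrow(B), "x", ncol(B))
  drop(W %*% x + (alpha / r) * (B %*% (A %*% x)))
}

#' Count LoRA adapter parameters
#'
#' Each adapted `d_out x d_in` matrix contributes `r * (d_in + d_out)`
#' parameters (its `A` and `B` factors).
#'
#' @param encoder_dims named list mapping target-matrix names to
#'   `c(d_out, d_in)` dimension pairs, or a `lorax_model` (counts its
#'   adapted matrices).
#' @param config a [lora_config()].
#' @return integer parameter count.
#' @export
lora_param_count <- function(encoder_dims, config) {
  if (inherits(encoder_dims, "lorax_model")) {
    model <- encoder_dims
    dims <- lapply(model$adapted, function(bn) {
      W <- model$theta[[bn]]
      c(ncol(W), nrow(W))
    })
    names(dims) <- model$adapted
    encoder_dims <- dims
  }
  suffix <- sub(".*\\.", "", names(encoder_dims))
  unmatched <- config$target_matrices[!config$target_matrices %in% suffix]
  if (length(unmatched))
    stop("unknown target matrix name(s): ", paste(unmatched, collapse = ", "))
  total <- 0L
  for (nm in names(encoder_dims)[suffix %in% config$target_matrices]) {
    dd <- encoder_dims[[nm]]
    if (config$r > min(dd))
      stop("rank r = ", config$r, " exceeds min dimension of `", nm, "`")
    total <- total + config$r * (dd[1] + dd[2])
  }
  as.integer(total)
}

# ---------------------------------------------------------------------------

.tokenize <- function(s, vocab, max_len, what = "string") {
  ch <- strsplit(s, "")[[1]]
  ids <- match(ch, vocab)
  if (anyNA(ids))
    stop("cannot tokenize ", what, " `", s, "`: unknown character `",
         ch[is.na(ids)][1], "`")
  utils::head(ids, max_len)
}

#' Build a LORAX model
#'
#' Assembles the full architecture with freshly initialized weights: two
#' tiny token encoders (SMILES characters / amino acids), LoRA adapters on
#' the configured target matrices of both encoders (whether a given
#' adapter set trains is decided by `trainable_scope` at training time),
#' `n_cross_attention_layers` fusion layers in which chemical tokens attend
#' to protein tokens and vice versa, a learned `<cls>` token prepended to
#' the fused sequence, one readout self-attention layer, and a scalar head.
#'
#' @param mode `"regression"` or `"classification"` (selects the head).
#' @param lora a [lora_config()].
#' @param fusion a [fusion_config()] (its `head` is overridden by `mode`).
#' @param encoder an [encoder_config()].
#' @param seed initialization seed.
#' @return object of class `lorax_model`.
#' @export
build_lorax_model <- function(mode = c("regression", "classification"),
                              lora = lora_config(), fusion = fusion_config(),
                              encoder = encoder_config(), seed = 1L) {
  mode <- match.arg(mode)
  fusion$head <- if (mode == "regression") "regression_linear"
                 else "classification_logit"
  d <- fusion$model_dim
  if (lora$r > d) stop("LoRA rank r = ", lora$r, " exceeds model_dim = ", d)
  th <- new.env(parent = emptyenv())
  block_names <- c("Wq", "Wk", "Wv", "Wo")
  .with_private_seed(seed, function() {
    init_block <- function(prefix) {
      for (w in block_names) th[[paste0(prefix, ".", w)]] <- .init_mat(d, d)
      th[[paste0(prefix, ".W1")]] <- .init_mat(d, fusion$feedforward_dim)
      th[[paste0(prefix, ".b1")]] <- numeric(fusion$feedforward_dim)
      th[[paste0(prefix, ".W2")]] <- .init_mat(fusion$feedforward_dim, d)
      th[[paste0(prefix, ".b2")]] <- numeric(d)
    }
    th[["chem.E"]] <- .init_mat(length(.SMILES_CHARSET), d) * sqrt(d)
    th[["prot.E"]] <- .init_mat(length(.PROT_VOCAB), d) * sqrt(d)
    for (l in seq_len(encoder$n_layers)) {
      init_block(paste0("chem.l", l))
      init_block(paste0("prot.l", l))
    }
    for (l in seq_len(fusion$n_cross_attention_layers)) {
      init_block(paste0("fus.l", l, ".c2p"))
      init_block(paste0("fus.l", l, ".p2c"))
    }
    init_block("out.l1")
    th[["cls"]] <- .init_mat(1, d)
    th[["head.w"]] <- .init_mat(d, 1)
    th[["head.b"]] <- 0
    # adapters: A random (SD 1/sqrt(d_in)), B zero
    if (lora$enabled) {
      for (enc in c("chem", "prot")) {
        for (l in seq_len(encoder$n_layers)) {
          for (tm in lora$target_matrices) {
            bn <- paste0(enc, ".l", l, ".", tm)
            th[[paste0("lora.", bn, ".A")]] <- .init_mat(d, lora$r)
            th[[paste0("lora.", bn, ".B")]] <- matrix(0, lora$r, d)
          }
        }
      }
    }
  })
  adapted <- if (lora$enabled) {
    as.vector(outer(
      as.vector(outer(c("chem", "prot"),
                      paste0("l", seq_len(encoder$n_layers)), paste, sep = ".")),
      lora$target_matrices, paste, sep = "."))
  } else character()
  structure(list(theta = th, mode = mode, lora = lora, fusion = fusion,
                 encoder = encoder,
                 chem_vocab = .SMILES_CHARSET, prot_vocab = .PROT_VOCAB,
                 pe = .sinusoidal_pe(encoder$max_len, d),
                 adapted = adapted, init_seed = seed),
            class = "lorax_model")
}

#' @export
print.lorax_model <- function(x, ...) {
  n_par <- sum(vapply(names(x$theta), function(nm) length(x$theta[[nm]]),
                      numeric(1)))
  cat(sprintf("lorax_model (%s): model_dim %d, %d encoder + %d fusion layers, %d heads\n",
              x$mode, x$fusion$model_dim, x$encoder$n_layers,
              x$fusion$n_cross_attention_layers, x$fusion$n_heads))
  cat(sprintf("  LoRA: %s, r = %d, alpha = %g, targets: %s\n",
              if (x$lora$enabled) "enabled" else "disabled",
              x$lora$r, x$lora$alpha,
              paste(x$lora$target_matrices, collapse = ", ")))
  cat(sprintf("  parameters: %d\n", as.integer(n_par)))
  invisible(x)
}

.clone_model <- function(model) {
  th <- new.env(parent = emptyenv())
  for (nm in names(model$theta)) assign(nm, model$theta[[nm]], envir = th)
  model$theta <- th
  model
}

# LoRA spec for a given base-weight name, or NULL when inactive.
.lora_for <- function(model, enc, layer, lora_scale = NULL) {
  if (!model$lora$enabled || !length(model$adapted)) return(NULL)
  s <- if (is.null(lora_scale)) model$lora$alpha / model$lora$r else lora_scale
  if (s == 0) return(NULL)
  nms <- list()
  for (tm in intersect(model$lora$target_matrices, c("Wq", "Wv"))) {
    bn <- paste0(enc, ".l", layer, ".", tm)
    if (bn %in% model$adapted) nms[[tm]] <- paste0("lora.", bn)
  }
  if (!length(nms)) return(NULL)
  list(names = nms, scale = s, dropout = model$lora$dropout)
}

# Encode a token-id sequence; returns the final token matrix plus caches.
.encode_fwd <- function(model, enc, ids, training = FALSE,
                        lora_scale = NULL) {
  th <- model$theta
  d <- model$fusion$model_dim
  X <- th[[paste0(enc, ".E")]][ids, , drop = FALSE] +
    model$pe[seq_along(ids), , drop = FALSE]
  caches <- vector("list", model$encoder$n_layers)
  for (l in seq_len(model$encoder$n_layers)) {
    bl <- .block_fwd(th, paste0(enc, ".l", l), X, X, model$fusion$n_heads,
                     lora = .lora_for(model, enc, l, lora_scale),
                     training = training)
    caches[[l]] <- bl$cache
    X <- bl$out
  }
  list(out = X, caches = caches)
}

.encode_bwd <- function(model, enc, dout, caches, grads, want) {
  th <- model$theta
  for (l in rev(seq_len(model$encoder$n_layers))) {
    bw <- .block_bwd(th, paste0(enc, ".l", l), dout, caches[[l]],
                     model$fusion$n_heads, grads, want)
    dout <- bw$dX
  }
  invisible()
}

# Fusion + readout over encoded token matrices.
.fuse_fwd <- function(model, Xc, Xp, training = FALSE) {
  th <- model$theta
  caches <- list()
  for (l in seq_len(model$fusion$n_cross_attention_layers)) {
    c2p <- .block_fwd(th, paste0("fus.l", l, ".c2p"), Xc, Xp,
                      model$fusion$n_heads, training = training)
    p2c <- .block_fwd(th, paste0("fus.l", l, ".p2c"), Xp, Xc,
                      model$fusion$n_heads, training = training)
    caches[[l]] <- list(c2p = c2p$cache, p2c = p2c$cache)
    Xc <- c2p$out
    Xp <- p2c$out
  }
  Z <- rbind(th[["cls"]], Xc, Xp)
  ro <- .block_fwd(th, "out.l1", Z, Z, model$fusion$n_heads,
                   training = training)
  cls_vec <- ro$out[1, ]
  z <- sum(cls_vec * th[["head.w"]]) + th[["head.b"]]
  pred <- if (model$fusion$head == "classification_logit")
    1 / (1 + exp(-z)) else z
  list(pred = pred, logit = z, cls = cls_vec,
       cache = list(fusion = caches, readout = ro$cache,
                    Tc = nrow(Xc), Tp = nrow(Xp), cls_out = cls_vec))
}

# Backward from d(logit); returns gradients w.r.t. the encoder outputs.
.fuse_bwd <- function(model, dz, cache, grads, want,
                      need_chem = TRUE, need_prot = FALSE) {
  th <- model$theta
  cls_vec <- cache$cls_out
  .gacc(grads, want, "head.w", matrix(dz * cls_vec, ncol = 1))
  .gacc(grads, want, "head.b", dz)
  Tc <- cache$Tc; Tp <- cache$Tp
  dZout <- matrix(0, 1 + Tc + Tp, model$fusion$model_dim)
  dZout[1, ] <- dz * drop(th[["head.w"]])
  bw <- .block_bwd(th, "out.l1", dZout, cache$readout,
                   model$fusion$n_heads, grads, want)
  dZ <- bw$dX
  .gacc(grads, want, "cls", dZ[1, , drop = FALSE])
  dXc <- dZ[2:(1 + Tc), , drop = FALSE]
  dXp <- dZ[(2 + Tc):(1 + Tc + Tp), , drop = FALSE]
  for (l in rev(seq_len(model$fusion$n_cross_attention_layers))) {
    cc <- cache$fusion[[l]]
    bw_c <- .block_bwd(th, paste0("fus.l", l, ".c2p"), dXc, cc$c2p,
                       model$fusion$n_heads, grads, want, need_dC = TRUE)
    bw_p <- .block_bwd(th, paste0("fus.l", l, ".p2c"), dXp, cc$p2c,
                       model$fusion$n_heads, grads, want, need_dC = TRUE)
    dXc <- bw_c$dX + bw_p$dC
    dXp <- bw_p$dX + bw_c$dC
  }
  list(dXc = if (need_chem) dXc else NULL,
       dXp = if (need_prot) dXp else NULL)
}

#' Fuse pre-encoded token sequences and predict
#'
#' Runs the cross-attention fusion stack, `<cls>` readout and head on token
#' matrices already projected to `model_dim`. Padding positions (marked
#' `TRUE` in the masks) are dropped before fusion, so padded values provably
#' cannot affect the output. Lists of matrices are treated as a batch and
#' give results identical to stacking single-pair calls.
#'
#' @param model a `lorax_model`.
#' @param chem_tokens `T_c x model_dim` matrix, or list of such matrices.
#' @param chem_mask logical vector (TRUE = padding), or list; `NULL` means
#'   no padding.
#' @param prot_tokens,prot_mask protein-side analogues.
#' @return list with `prediction` (numeric vector) and `cls_vector`
#'   (matrix, one row per pair).
#' @export
fuse_forward <- function(model, chem_tokens, chem_mask = NULL,
                         prot_tokens, prot_mask = NULL) {
  single <- is.matrix(chem_tokens)
  if (single) {
    chem_tokens <- list(chem_tokens); prot_tokens <- list(prot_tokens)
    chem_mask <- if (is.null(chem_mask)) list(NULL) else list(chem_mask)
    prot_mask <- if (is.null(prot_mask)) list(NULL) else list(prot_mask)
  } else {
    if (is.null(chem_mask)) chem_mask <- vector("list", length(chem_tokens))
    if (is.null(prot_mask)) prot_mask <- vector("list", length(prot_tokens))
  }
  strip <- function(tok, mask, side) {
    if (is.null(mask)) return(tok)
    if (length(mask) != nrow(tok))
      stop(side, " mask length ", length(mask), " != ", nrow(tok), " tokens")
    tok[!mask, , drop = FALSE]
  }
  n <- length(chem_tokens)
  preds <- numeric(n)
  cls <- matrix(0, n, model$fusion$model_dim)
  for (i in seq_len(n)) {
    Xc <- strip(chem_tokens[[i]], chem_mask[[i]], "chem")
    Xp <- strip(prot_tokens[[i]], prot_mask[[i]], "prot")
    fw <- .fuse_fwd(model, Xc, Xp, training = FALSE)
    preds[i] <- fw$pred
    cls[i, ] <- fw$cls
  }
  list(prediction = preds, cls_vector = cls)
}

# Token-id lists for every odorant / receptor in a dataset.
.token_tables <- function(model, dataset) {
  chem <- lapply(dataset$odorants$smiles, .tokenize,
                 vocab = model$chem_vocab, max_len = model$encoder$max_len,
                 what = "SMILES")
  names(chem) <- dataset$odorants$odorant_id
  prot <- lapply(dataset$receptors$sequence, .tokenize,
                 vocab = model$prot_vocab, max_len = model$encoder$max_len,
                 what = "sequence")
  names(prot) <- dataset$receptors$receptor_id
  list(chem = chem, prot = prot)
}

# Predictions for interaction rows `idx` (eval mode; unique-entity caching).
.predict_pairs <- function(model, dataset, idx = NULL, lora_scale = NULL,
                           return_cls = FALSE) {
  it <- dataset$interactions
  if (is.null(idx)) idx <- seq_len(nrow(it))
  tok <- .token_tables(model, dataset)
  ods <- unique(it$odorant_id[idx])
  rcs <- unique(it$receptor_id[idx])
  chem_out <- lapply(tok$chem[ods], function(ids)
    .encode_fwd(model, "chem", ids, lora_scale = lora_scale)$out)
  prot_out <- lapply(tok$prot[rcs], function(ids)
    .encode_fwd(model, "prot", ids, lora_scale = lora_scale)$out)
  n <- length(idx)
  preds <- numeric(n)
  cls <- if (return_cls) matrix(0, n, model$fusion$model_dim) else NULL
  for (i in seq_len(n)) {
    row <- idx[i]
    fw <- .fuse_fwd(model, chem_out[[it$odorant_id[row]]],
                    prot_out[[it$receptor_id[row]]])
    preds[i] <- fw$pred
    if (return_cls) cls[i, ] <- fw$cls
  }
  list(pred = preds, cls = cls)
}

.val_metric <- function(model, y, pred) {
  if (model$mode == "regression") .r_squared(y, pred)
  else compute_metrics(y, pred, "classification")$mcc
}

.trainable_names <- function(model, scope) {
  nms <- names(model$theta)
  base <- nms[grepl("^(fus\\.|out\\.|head\\.)", nms)]
  base <- c(base, "cls")
  if (scope == "lora_chem_only")
    base <- c(base, nms[grepl("^lora\\.chem\\.", nms)])
  if (scope == "lora_chem_and_protein")
    base <- c(base, nms[grepl("^lora\\.", nms)])
  intersect(base, nms)
}

#' Stage-1 training of the multi-modal transformer
#'
#' Trains the fusion stack, `<cls>` token, head, and the LoRA adapters named
#' by `train_cfg$trainable_scope` with Adam on minibatches; base encoder
#' weights are never updated. The validation metric (R-squared in
#' regression, MCC in classification) is logged every epoch and the
#' checkpoint with the best validation score is restored on return -- this
#' standalone transformer validation score is also what the stage-2 ensemble
#' reports for interpretability.
#'
#' @param model a `lorax_model` (left unmodified; a trained clone is
#'   returned).
#' @param dataset an [interaction_dataset()].
#' @param split list with integer vectors `train` and `val` indexing
#'   `dataset$interactions` (disjoint, both non-empty).
#' @param train_cfg a [train_config()].
#' @return list with `model` (trained clone) and `history` (data.frame with
#'   columns `epoch`, `train_loss`, `val_metric`).
#' @export
train_stage1 <- function(model, dataset, split, train_cfg = train_config()) {
  stopifnot(inherits(model, "lorax_model"))
  if (!length(split$train) || !length(split$val))
    stop("train and validation sets must both be non-empty")
  if (length(intersect(split$train, split$val)))
    stop("train and validation sets overlap")
  model <- .clone_model(model)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_metric = numeric())
  if (train_cfg$epochs == 0)
    return(list(model = model, history = history))

  th <- model$theta
  it <- dataset$interactions
  y <- if (model$mode == "regression") it$response else it$label
  w <- it$weight
  loss_kind <- train_cfg$loss
  if (is.null(loss_kind))
    loss_kind <- if (model$mode == "regression") "mse" else "weighted_bce"
  tok <- .token_tables(model, dataset)
  trainable <- .trainable_names(model, train_cfg$trainable_scope)
  want <- new.env(parent = emptyenv())
  for (nm in trainable) assign(nm, TRUE, envir = want)
  prot_trainable <- any(grepl("^lora\\.prot\\.", trainable))

  # frozen protein encoder outputs can be cached for the whole run
  prot_cache <- NULL
  if (!prot_trainable) {
    prot_cache <- lapply(tok$prot, function(ids)
      .encode_fwd(model, "prot", ids)$out)
  }
  opt <- .adam_init()
  best <- list(metric = -Inf, theta = NULL, epoch = 0L)
  patience_left <- train_cfg$early_stop_patience
  val_y <- y[split$val]

  .with_private_seed(train_cfg$seed, function() {
    for (epoch in seq_len(train_cfg$epochs)) {
      ord <- sample(split$train)
      nbatch <- ceiling(length(ord) / train_cfg$batch_size)
      epoch_loss <- 0
      for (b in seq_len(nbatch)) {
        rows <- ord[((b - 1) * train_cfg$batch_size + 1):
                      min(b * train_cfg$batch_size, length(ord))]
        grads <- new.env(parent = emptyenv())
        ods <- unique(it$odorant_id[rows])
        chem_enc <- lapply(tok$chem[ods], function(ids)
          .encode_fwd(model, "chem", ids, training = TRUE))
        d_chem <- lapply(chem_enc, function(e) e$out * 0)
        prot_enc <- NULL; d_prot <- NULL
        if (prot_trainable) {
          rcs <- unique(it$receptor_id[rows])
          prot_enc <- lapply(tok$prot[rcs], function(ids)
            .encode_fwd(model, "prot", ids, training = TRUE))
          d_prot <- lapply(prot_enc, function(e) e$out * 0)
        }
        wsum <- sum(w[rows])
        for (row in rows) {
          oid <- it$odorant_id[row]; rid <- it$receptor_id[row]
          Xp <- if (prot_trainable) prot_enc[[rid]]$out else prot_cache[[rid]]
          fw <- .fuse_fwd(model, chem_enc[[oid]]$out, Xp, training = TRUE)
          if (loss_kind == "mse") {
            err <- fw$pred - y[row]
            epoch_loss <- epoch_loss + w[row] * err^2
            dz <- 2 * w[row] * err / wsum
          } else {
            p <- fw$pred
            epoch_loss <- epoch_loss - w[row] *
              (y[row] * log(max(p, 1e-12)) +
                 (1 - y[row]) * log(max(1 - p, 1e-12)))
            dz <- w[row] * (p - y[row]) / wsum
          }
          bw <- .fuse_bwd(model, dz, fw$cache, grads, want,
                          need_chem = TRUE, need_prot = prot_trainable)
          d_chem[[oid]] <- d_chem[[oid]] + bw$dXc
          if (prot_trainable) d_prot[[rid]] <- d_prot[[rid]] + bw$dXp
        }
        for (oid in ods)
          .encode_bwd(model, "chem", d_chem[[oid]], chem_enc[[oid]]$caches,
                      grads, want)
        if (prot_trainable) {
          for (rid in names(prot_enc))
            .encode_bwd(model, "prot", d_prot[[rid]], prot_enc[[rid]]$caches,
                        grads, want)
        }
        opt <<- .adam_step(th, grads, opt, trainable,
                           train_cfg$learning_rate)
      }
      val_pred <- .predict_pairs(model, dataset, split$val)$pred
      vm <- .val_metric(model, val_y, val_pred)
      history[nrow(history) + 1L, ] <<- list(epoch, epoch_loss / wsum, vm)
      if (vm > best$metric) {
        best <<- list(metric = vm,
                      theta = mget(trainable, envir = th), epoch = epoch)
        patience_left <<- train_cfg$early_stop_patience
      } else {
        patience_left <<- patience_left - 1L
        if (patience_left <= 0) break
      }
    }
  })
  if (!is.null(best$theta))
    for (nm in names(best$theta)) assign(nm, best$theta[[nm]], envir = th)
  attr(history, "best_epoch") <- best$epoch
  attr(history, "best_val_metric") <- best$metric
  list(model = model, history = history)
}

#' Extract learned features from a trained model
#'
#' `type = "cls"` returns one `<cls>` vector per interaction pair (the
#' transformer's penultimate representation, used as stage-2 ensemble
#' features). `type = "chem_mean"` returns one vector per odorant: the mean
#' of the (LoRA-adapted) chemical encoder's token outputs -- the fine-tuned
#' odor space used in representation shape analyses. Both are deterministic
#' in eval mode.
#'
#' @param model a `lorax_model`.
#' @param dataset an [interaction_dataset()].
#' @param idx interaction rows to featurize (`type = "cls"`; default all).
#' @param type `"cls"` or `"chem_mean"`.
#' @param name representation name (defaults by type).
#' @return a [representation_matrix()].
#' @export
extract_cls_features <- function(model, dataset, idx = NULL,
                                 type = c("cls", "chem_mean"), name = NULL) {
  type <- match.arg(type)
  if (type == "cls") {
    it <- dataset$interactions
    if (is.null(idx)) idx <- seq_len(nrow(it))
    out <- .predict_pairs(model, dataset, idx, return_cls = TRUE)
    ids <- paste(it$odorant_id[idx], it$receptor_id[idx], sep = ":")
    representation_matrix(out$cls, item_ids = ids,
                          name = if (is.null(name)) "cls" else name)
  } else {
    tok <- .token_tables(model, dataset)
    m <- t(vapply(dataset$odorants$odorant_id, function(oid)
      colMeans(.encode_fwd(model, "chem", tok$chem[[oid]])$out),
      numeric(model$fusion$model_dim)))
    representation_matrix(m, item_ids = dataset$odorants$odorant_id,
                          name = if (is.null(name)) "lorax_chem" else name)
  }
}

#' Predict interaction values with the transformer alone
#'
#' Runs the stage-1 model (encoders, fusion, `<cls>` head) in eval mode on
#' interaction rows of a dataset; the stage-2 ensemble is not involved.
#'
#' @param model a `lorax_model`.
#' @param dataset an [interaction_dataset()].
#' @param idx interaction rows to predict (default all).
#' @return numeric predictions (probabilities in classification mode).
#' @export
predict_transformer <- function(model, dataset, idx = NULL) {
  .predict_pairs(model, dataset, idx)$pred
}

# Pooled frozen-encoder representations (adapter contribution disabled):
# the "original foundation model" features used by the stage-2 ensemble.
.original_reps <- function(model, dataset) {
  tok <- .token_tables(model, dataset)
  d <- model$fusion$model_dim
  chem <- t(vapply(dataset$odorants$odorant_id, function(oid)
    colMeans(.encode_fwd(model, "chem", tok$chem[[oid]], lora_scale = 0)$out),
    numeric(d)))
  prot <- t(vapply(dataset$receptors$receptor_id, function(rid)
    colMeans(.encode_fwd(model, "prot", tok$prot[[rid]], lora_scale = 0)$out),
    numeric(d)))
  list(chem = representation_matrix(chem, dataset$odorants$odorant_id,
                                    "chem_frozen"),
       prot = representation_matrix(prot, dataset$receptors$receptor_id,
                                    "prot_frozen"))
}
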