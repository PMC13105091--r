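# Internal neural-network primitives: parameter initialization, layer
# forward/backward passes, and Adam. All tensors are plain matrices with
# tokens as rows; parameters live in an environment keyed by dotted names
# ("chem.l1.Wq", "fus.l1.c2p.W1", "lora.chem.l1.Wq.A", ...). Backward passes
# are hand-derived and checked against finite differences in the test suite.

.LN_EPS <- 1e-5

.init_mat <- function(nr, nc) {
  matrix(stats::rnorm(nr * nc, sd = 1 / sqrt(nr)), nr, nc)
}

# Fixed sinusoidal positional encodings (maxlen x d).
.sinusoidal_pe <- function(maxlen, d) {
  pos <- seq_len(maxlen) - 1
  i <- seq_len(d) - 1
  angle <- outer(pos, 1 / 10000^((i - i %% 2) / d))
  pe <- matrix(0, maxlen, d)
  even <- (i %% 2) == 0
  pe[, even] <- sin(angle[, even, drop = FALSE])
  pe[, !even] <- cos(angle[, !even, drop = FALSE])
  pe
}

.ln_fwd <- function(X) {
  n <- nrow(X); d <- ncol(X)
  mu <- .rowMeans(X, n, d)
  Xc <- X - mu
  v <- .rowMeans(Xc * Xc, n, d)
  sig <- sqrt(v + .LN_EPS)
  list(Y = Xc / sig, sig = sig)
}

.ln_bwd <- function(dY, Y, sig) {
  n <- nrow(dY); d <- ncol(dY)
  (dY - .rowMeans(dY, n, d) - Y * .rowMeans(dY * Y, n, d)) / sig
}

# Gradient accumulation into env `grads`, restricted to names in env `want`.
.gacc <- function(grads, want, name, val) {
  if (!exists(name, envir = want, inherits = FALSE)) return(invisible())
  cur <- grads[[name]]
  if (is.null(cur)) assign(name, val, envir = grads)
  else assign(name, cur + val, envir = grads)
  invisible()
}

# One transformer block: multi-head attention (queries from X, keys/values
# from context C; C identical to X for self-attention) with optional LoRA on
# the query/value projections, residual + layer norm, then a 2-layer ReLU
# feed-forward with residual + layer norm (post-LN arrangement).
#
# `lora` is NULL or list(names = c(Wq = "lora.<base>.Wq", Wv = ...),
# scale, dropout); dropout masks the adapter input during training.
.block_fwd <- function(th, p, X, C, nheads, lora = NULL, training = FALSE) {
  Wq <- th[[paste0(p, ".Wq")]]; Wk <- th[[paste0(p, ".Wk")]]
  Wv <- th[[paste0(p, ".Wv")]]; Wo <- th[[paste0(p, ".Wo")]]
  W1 <- th[[paste0(p, ".W1")]]; b1 <- th[[paste0(p, ".b1")]]
  W2 <- th[[paste0(p, ".W2")]]; b2 <- th[[paste0(p, ".b2")]]
  d <- ncol(X); dk <- d / nheads
  Tq <- nrow(X); Tk <- nrow(C)

  Q <- X %*% Wq
  K <- C %*% Wk
  V <- C %*% Wv
  XAq <- XAv <- Xdrop_q <- Xdrop_v <- NULL
  if (!is.null(lora)) {
    s <- lora$scale
    mk_drop <- function(M) {
      if (training && lora$dropout > 0) {
        keep <- matrix(stats::runif(length(M)) >= lora$dropout,
                       nrow(M), ncol(M)) / (1 - lora$dropout)
        M * keep
      } else M
    }
    if (!is.null(lora$names[["Wq"]])) {
      Xdrop_q <- mk_drop(X)
      XAq <- Xdrop_q %*% th[[paste0(lora$names[["Wq"]], ".A")]]
      Q <- Q + s * (XAq %*% th[[paste0(lora$names[["Wq"]], ".B")]])
    }
    if (!is.null(lora$names[["Wv"]])) {
      Xdrop_v <- mk_drop(C)
      XAv <- Xdrop_v %*% th[[paste0(lora$names[["Wv"]], ".A")]]
      V <- V + s * (XAv %*% th[[paste0(lora$names[["Wv"]], ".B")]])
    }
  }

  Hcat <- matrix(0, Tq, d)
  Alist <- vector("list", nheads)
  for (h in seq_len(nheads)) {
    idx <- ((h - 1) * dk + 1):(h * dk)
    S <- tcrossprod(Q[, idx, drop = FALSE], K[, idx, drop = FALSE]) / sqrt(dk)
    S <- S - apply(S, 1, max)
    E <- exp(S)
    A <- E / .rowSums(E, Tq, Tk)
    Alist[[h]] <- A
    Hcat[, idx] <- A %*% V[, idx, drop = FALSE]
  }
  O <- Hcat %*% Wo
  ln1 <- .ln_fwd(X + O)
  U <- ln1$Y %*% W1 + rep(b1, each = Tq)
  Ur <- U * (U > 0)
  F_ <- Ur %*% W2 + rep(b2, each = Tq)
  ln2 <- .ln_fwd(ln1$Y + F_)

  list(out = ln2$Y,
       cache = list(X = X, C = C, Q = Q, K = K, V = V, Alist = Alist,
                    Hcat = Hcat, ln1 = ln1, U = U, Ur = Ur, ln2 = ln2,
                    XAq = XAq, XAv = XAv,
                    Xdrop_q = Xdrop_q, Xdrop_v = Xdrop_v, lora = lora))
}

# Backward through .block_fwd. Accumulates parameter gradients into `grads`
# (filtered by `want`) and returns gradients w.r.t. X and C.
.block_bwd <- function(th, p, dout, cache, nheads, grads, want,
                       need_dC = FALSE) {
  Wq <- th[[paste0(p, ".Wq")]]; Wk <- th[[paste0(p, ".Wk")]]
  Wv <- th[[paste0(p, ".Wv")]]; Wo <- th[[paste0(p, ".Wo")]]
  W1 <- th[[paste0(p, ".W1")]]; W2 <- th[[paste0(p, ".W2")]]
  X <- cache$X; C <- cache$C
  d <- ncol(X); dk <- d / nheads
  Tq <- nrow(X); Tk <- nrow(C)
  lora <- cache$lora
  self_attn <- identical(dim(X), dim(C)) && identical(X, C)

  dR2 <- .ln_bwd(dout, cache$ln2$Y, cache$ln2$sig)
  # feed-forward
  dUr <- dR2 %*% t(W2)
  .gacc(grads, want, paste0(p, ".W2"), crossprod(cache$Ur, dR2))
  .gacc(grads, want, paste0(p, ".b2"), colSums(dR2))
  dU <- dUr * (cache$U > 0)
  .gacc(grads, want, paste0(p, ".W1"), crossprod(cache$ln1$Y, dU))
  .gacc(grads, want, paste0(p, ".b1"), colSums(dU))
  dln1 <- dR2 + dU %*% t(W1)
  dR1 <- .ln_bwd(dln1, cache$ln1$Y, cache$ln1$sig)
  # attention
  dO <- dR1
  dHcat <- dO %*% t(Wo)
  .gacc(grads, want, paste0(p, ".Wo"), crossprod(cache$Hcat, dO))
  dQ <- matrix(0, Tq, d); dK <- matrix(0, Tk, d); dV <- matrix(0, Tk, d)
  for (h in seq_len(nheads)) {
    idx <- ((h - 1) * dk + 1):(h * dk)
    A <- cache$Alist[[h]]
    dH <- dHcat[, idx, drop = FALSE]
    dA <- tcrossprod(dH, cache$V[, idx, drop = FALSE])
    dV[, idx] <- crossprod(A, dH)
    dS <- A * (dA - .rowSums(dA * A, Tq, Tk))
    dQ[, idx] <- dS %*% cache$K[, idx, drop = FALSE] / sqrt(dk)
    dK[, idx] <- crossprod(dS, cache$Q[, idx, drop = FALSE]) / sqrt(dk)
  }
  dX <- dR1 + dQ %*% t(Wq)
  dC_ <- dK %*% t(Wk) + dV %*% t(Wv)
  .gacc(grads, want, paste0(p, ".Wq"), crossprod(X, dQ))
  .gacc(grads, want, paste0(p, ".Wk"), crossprod(C, dK))
  .gacc(grads, want, paste0(p, ".Wv"), crossprod(C, dV))
  if (!is.null(lora)) {
    s <- lora$scale
    if (!is.null(lora$names[["Wq"]])) {
      nmA <- paste0(lora$names[["Wq"]], ".A")
      nmB <- paste0(lora$names[["Wq"]], ".B")
      Bq <- th[[nmB]]
      .gacc(grads, want, nmB, s * crossprod(cache$XAq, dQ))
      dXAq <- s * (dQ %*% t(Bq))
      .gacc(grads, want, nmA, crossprod(cache$Xdrop_q, dXAq))
      dX <- dX + dXAq %*% t(th[[nmA]])
    }
    if (!is.null(lora$names[["Wv"]])) {
      nmA <- paste0(lora$names[["Wv"]], ".A")
      nmB <- paste0(lora$names[["Wv"]], ".B")
      Bv <- th[[nmB]]
      .gacc(grads, want, nmB, s * crossprod(cache$XAv, dV))
      dXAv <- s * (dV %*% t(Bv))
      .gacc(grads, want, nmA, crossprod(cache$Xdrop_v, dXAv))
      dC_ <- dC_ + dXAv %*% t(th[[nmA]])
    }
  }
  if (self_attn) {
    list(dX = dX + dC_, dC = NULL)
  } else {
    list(dX = dX, dC = if (need_dC) dC_ else NULL)
  }
}

# Adam with bias correction; state holds m/v environments and step counter.
.adam_init <- function() {
  list(m = new.env(parent = emptyenv()), v = new.env(parent = emptyenv()),
       t = 0L)
}

.adam_step <- function(theta, grads, state, trainable, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in trainable) {
    g <- grads[[nm]]
    if (is.null(g)) next
    m <- state$m[[nm]]; v <- state$v[[nm]]
    if (is.null(m)) { m <- g * 0; v <- g * 0 }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    assign(nm, m, envir = state$m)
    assign(nm, v, envir = state$v)
    theta[[nm]] <- theta[[nm]] - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  }
  state
}
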