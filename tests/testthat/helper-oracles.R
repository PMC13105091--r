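# Independent oracles used to cross-check package computations. These stay
# deliberately naive (enumeration, brute force, base fitting routines) and
# never share code with the implementation they verify.

# AUROC as the probability that a random positive outranks a random
# negative, by exhaustive pair enumeration (ties count 1/2).
oracle_auroc <- function(y, p) {
  pos <- p[y == 1]; neg <- p[y == 0]
  s <- 0
  for (a in pos) s <- s + sum(a > neg) + 0.5 * sum(a == neg)
  s / (length(pos) * length(neg))
}

# Average precision by explicit confusion-matrix evaluation at every
# distinct threshold, accumulating precision * recall increments.
oracle_avep <- function(y, p) {
  ths <- sort(unique(p), decreasing = TRUE)
  prev_recall <- 0
  npos <- sum(y == 1)
  ap <- 0
  for (t in ths) {
    yhat <- as.integer(p >= t)
    tp <- sum(yhat == 1 & y == 1)
    fp <- sum(yhat == 1 & y == 0)
    prec <- tp / (tp + fp)
    rec <- tp / npos
    ap <- ap + prec * (rec - prev_recall)
    prev_recall <- rec
  }
  ap
}

oracle_mcc <- function(tp, fp, fn, tn) {
  (tp * tn - fp * fn) /
    sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
}

oracle_r2 <- function(y, p) 1 - sum((y - p)^2) / sum((y - mean(y))^2)

# Brute-force angular Procrustes for d = 2: scan rotations and reflections.
oracle_procrustes_2d <- function(X, Y, ngrid = 20000) {
  X <- sweep(X, 2, colMeans(X)); Y <- sweep(Y, 2, colMeans(Y))
  Xn <- X / sqrt(sum(X^2)); Yn <- Y / sqrt(sum(Y^2))
  best <- -Inf
  for (th in seq(0, 2 * pi, length.out = ngrid)) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    for (Fm in list(diag(2), diag(c(1, -1)))) {
      best <- max(best, sum(Xn * (Yn %*% (R %*% Fm))))
    }
  }
  acos(min(max(best, 0), 1))
}

# Brute-force angular Procrustes for d = 3: optimize Euler angles (plus
# reflection) from many starts.
oracle_procrustes_3d <- function(X, Y, nstart = 24) {
  X <- sweep(X, 2, colMeans(X)); Y <- sweep(Y, 2, colMeans(Y))
  Xn <- X / sqrt(sum(X^2)); Yn <- Y / sqrt(sum(Y^2))
  rot <- function(a) {
    Rz <- matrix(c(cos(a[1]), sin(a[1]), 0, -sin(a[1]), cos(a[1]), 0,
                   0, 0, 1), 3, 3)
    Ry <- matrix(c(cos(a[2]), 0, -sin(a[2]), 0, 1, 0,
                   sin(a[2]), 0, cos(a[2])), 3, 3)
    Rx <- matrix(c(1, 0, 0, 0, cos(a[3]), sin(a[3]),
                   0, -sin(a[3]), cos(a[3])), 3, 3)
    Rz %*% Ry %*% Rx
  }
  best <- -Inf
  for (Fm in list(diag(3), diag(c(1, 1, -1)))) {
    for (s in seq_len(nstart)) {
      a0 <- runif(3, 0, 2 * pi)
      opt <- optim(a0, function(a)
        -sum(Xn * (Yn %*% (rot(a) %*% Fm))), method = "Nelder-Mead",
        control = list(maxit = 2000, reltol = 1e-14))
      best <- max(best, -opt$value)
    }
  }
  acos(min(max(best, 0), 1))
}

# Tiny full-factorial dataset built by hand.
tiny_panel <- function() {
  odorants <- data.frame(odorant_id = c("o1", "o2"),
                         smiles = c("CCO", "CCC"),
                         stringsAsFactors = FALSE)
  receptors <- data.frame(receptor_id = c("r1", "r2"),
                          sequence = c("MKTAY", "GGWLP"),
                          stringsAsFactors = FALSE)
  interactions <- data.frame(
    odorant_id = c("o1", "o1", "o2", "o2"),
    receptor_id = c("r1", "r2", "r1", "r2"),
    response = c(1, 2, 3, 4), stringsAsFactors = FALSE)
  interaction_dataset(odorants, receptors, interactions, "regression")
}

# Fake prediction models for ensemble algebra tests: predict() returns a
# stored vector regardless of features.
fake_model <- function(preds) structure(list(preds = preds),
                                        class = "fake_model")
predict.fake_model <- function(object, newdata, ...) {
  object$preds[seq_len(nrow(newdata))]
}
registerS3method("predict", "fake_model", predict.fake_model,
                 envir = asNamespace("stats"))

random_rotation <- function(d, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  qr_ <- qr(matrix(rnorm(d * d), d))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
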