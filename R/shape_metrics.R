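# Angular shape metrics between representation spaces.
#
# Both metrics operate on item-aligned, column-centered matrices and return
# an angle in [0, pi/2]: 0 for identical shapes, pi/2 for orthogonal ones.
# The Procrustes metric is invariant to orthogonal transforms and isotropic
# scaling; the CCA metric to any invertible linear map.

.as_rep <- function(x, name = "X") {
  if (inherits(x, "representation_matrix")) return(x)
  if (is.matrix(x)) {
    ids <- rownames(x)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(x)))
    return(representation_matrix(x, item_ids = ids, name = name))
  }
  stop("expected a representation_matrix or matrix")
}

#' Align two representations to a common item order and center them
#'
#' Rows of `y` are reordered to `x`'s item order, each column is
#' mean-centered, and both matrices are zero-padded on the right to a common
#' column count `max(d_x, d_y)` (zero-padding embeds the narrower space
#' isometrically in the wider ambient space, so distances are preserved).
#'
#' @param x,y `representation_matrix` objects (or plain matrices with
#'   rownames) over the same item set, n >= 3.
#' @return list with centered matrices `x`, `y` and the common `item_ids`.
#' @export
align_and_center <- function(x, y) {
  x <- .as_rep(x, "X"); y <- .as_rep(y, "Y")
  only_x <- setdiff(x$item_ids, y$item_ids)
  only_y <- setdiff(y$item_ids, x$item_ids)
  if (length(only_x) || length(only_y))
    stop("item sets differ; only in first: {",
         paste(utils::head(only_x, 5), collapse = ", "),
         "}; only in second: {", paste(utils::head(only_y, 5), collapse = ", "), "}")
  if (length(x$item_ids) < 3) stop("need at least 3 items")
  X <- x$values
  Y <- y$values[match(x$item_ids, y$item_ids), , drop = FALSE]
  X <- sweep(X, 2, colMeans(X))
  Y <- sweep(Y, 2, colMeans(Y))
  d <- max(ncol(X), ncol(Y))
  pad <- function(m) if (ncol(m) < d)
    cbind(m, matrix(0, nrow(m), d - ncol(m))) else m
  list(x = pad(X), y = pad(Y), item_ids = x$item_ids)
}

# Angle from an alignment cosine. acos() turns machine-epsilon error near
# cosine 1 into ~1e-8 angles, so cosines within 1e-12 of 1 are treated as
# exactly 1: self-distance is exactly 0 and symmetry is preserved.
.angle_from_cos <- function(cos_val) {
  cos_val <- min(max(cos_val, 0), 1)
  if (1 - cos_val < 1e-12) return(0)
  acos(cos_val)
}

.shape_distance <- function(value, metric, rank_x, rank_y,
                            rho = NULL, Q = NULL) {
  structure(list(value = value, metric = metric,
                 rank_x = rank_x, rank_y = rank_y, rho = rho, Q = Q),
            class = "shape_distance")
}

#' @export
print.shape_distance <- function(x, ...) {
  cat(sprintf("%s distance: %.6f rad (ranks %d, %d)\n",
              x$metric, x$value, x$rank_x, x$rank_y))
  if (!is.null(x$rho))
    cat("  canonical correlations:",
        paste(sprintf("%.3f", utils::head(x$rho, 8)), collapse = " "), "\n")
  invisible(x)
}

#' Angular orthogonal Procrustes distance
#'
#' After centering and scaling each matrix to unit Frobenius norm, the
#' distance is `arccos` of the nuclear norm of the cross-product
#' `C = Xn' Yn` -- the cosine of the angle between the two configurations
#' after optimal alignment by an orthogonal map. The optimal map
#' `Q = U V'` (from the SVD `C = U S V'`) is returned as a diagnostic.
#'
#' @param x,y representations over the same items (aligned and centered
#'   internally via [align_and_center()]).
#' @return a `shape_distance` with `value` in radians, the orthogonal map
#'   `Q`, and the matrix ranks.
#' @export
procrustes_distance <- function(x, y) {
  ac <- align_and_center(x, y)
  nx <- sqrt(sum(ac$x^2)); ny <- sqrt(sum(ac$y^2))
  if (nx == 0 || ny == 0) stop("zero matrix after centering")
  Xn <- ac$x / nx; Yn <- ac$y / ny
  C <- crossprod(Xn, Yn)
  sv <- svd(C)
  val <- .angle_from_cos(sum(sv$d))
  .shape_distance(val, "procrustes",
                  rank_x = qr(ac$x)$rank, rank_y = qr(ac$y)$rank,
                  Q = sv$u %*% t(sv$v))
}

# Whiten a centered matrix onto its retained principal subspace.
.whiten <- function(Xc, rank_tol) {
  S <- crossprod(Xc)
  e <- eigen(S, symmetric = TRUE)
  keep <- e$values > rank_tol * max(e$values, 0)
  k <- sum(keep)
  if (k == 0) stop("retained rank 0; matrix has no variance")
  W <- Xc %*% e$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(e$values[keep]), k)
  list(W = W, k = k)
}

#' Angular CCA distance
#'
#' Each matrix is whitened onto its retained principal subspace
#' (eigenvalues below `rank_tol` times the largest are dropped); the
#' canonical correlations `rho_i` are the singular values of `Xw' Yw`,
#' clipped to \[0, 1\]. The distance is
#' `arccos( sum(rho_i) / sqrt(k_x k_y) )` with `k` the retained ranks.
#' Invariant to any invertible linear transform of either input.
#'
#' @param x,y representations over the same items.
#' @param rank_tol relative eigenvalue cutoff for the retained rank.
#' @return a `shape_distance` with canonical correlations in `rho`.
#' @export
cca_distance <- function(x, y, rank_tol = 1e-9) {
  ac <- align_and_center(x, y)
  wx <- .whiten(ac$x, rank_tol)
  wy <- .whiten(ac$y, rank_tol)
  rho <- svd(crossprod(wx$W, wy$W))$d
  rho <- pmin(pmax(rho, 0), 1)
  rho <- sort(rho, decreasing = TRUE)
  val <- .angle_from_cos(sum(rho) / sqrt(wx$k * wy$k))
  .shape_distance(val, "cca", rank_x = wx$k, rank_y = wy$k, rho = rho)
}

#' Pairwise shape-distance matrix
#'
#' Assembles the symmetric, zero-diagonal matrix of shape distances between a
#' list of representations over a shared item set. Any representation --
#' including the measured neural representation from
#' [build_neural_representation()] -- participates like any other.
#'
#' @param reps list of `representation_matrix` objects (names taken from the
#'   representations if the list is unnamed).
#' @param metric `"procrustes"` or `"cca"`.
#' @param rank_tol passed to [cca_distance()].
#' @return object of class `distance_matrix`: list with `names` and the
#'   symmetric `values` matrix.
#' @export
pairwise_distances <- function(reps, metric = c("procrustes", "cca"),
                               rank_tol = 1e-9) {
  metric <- match.arg(metric)
  if (length(reps) < 2) stop("need at least 2 representations")
  nms <- names(reps)
  if (is.null(nms) || any(!nzchar(nms)))
    nms <- vapply(reps, function(r) r$name, character(1))
  n <- length(reps)
  m <- matrix(0, n, n, dimnames = list(nms, nms))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- tryCatch(
        if (metric == "procrustes") procrustes_distance(reps[[i]], reps[[j]])
        else cca_distance(reps[[i]], reps[[j]], rank_tol),
        error = function(e) stop("distance(", nms[i], ", ", nms[j], "): ",
                                 conditionMessage(e), call. = FALSE))
      m[i, j] <- m[j, i] <- d$value
    }
  }
  structure(list(names = nms, values = m), class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat("distance_matrix over", length(x$names), "representations\n")
  print(round(x$values, 3))
  invisible(x)
}

#' Write a distance matrix as a labeled square CSV
#' @param dm a `distance_matrix`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_distance_matrix <- function(dm, file) {
  df <- data.frame(representation = dm$names, dm$values,
                   check.names = FALSE)
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
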