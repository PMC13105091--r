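rep_of <- function(m, ids = NULL, name = "r") {
  if (is.null(ids)) ids <- paste0("i", seq_len(nrow(m)))
  representation_matrix(m, ids, name)
}

test_that("align_and_center reorders, centers, and zero-pads", {
  X <- rep_of(matrix(c(1, 2, 3, 4, 5, 6), 3, 2), c("a", "b", "c"))
  Y <- rep_of(matrix(c(10, 20, 30), 3, 1), c("c", "a", "b"))
  ac <- align_and_center(X, Y)
  expect_equal(ac$item_ids, c("a", "b", "c"))
  expect_equal(unname(ac$x[, 1]), c(-1, 0, 1))
  # Y reordered to (a, b, c) = (20, 30, 10), centered, padded to 2 columns
  expect_equal(ncol(ac$y), 2)
  expect_equal(unname(ac$y[, 1]), c(0, 10, -10))
  expect_true(all(ac$y[, 2] == 0))
  Z <- rep_of(matrix(1:6, 3, 2), c("a", "b", "d"))
  expect_error(align_and_center(X, Z), "item sets differ")
})

test_that("Procrustes distance is zero under rotation and isotropic scaling", {
  set.seed(42)
  X <- rep_of(matrix(rnorm(30), 10, 3))
  expect_equal(procrustes_distance(X, X)$value, 0)
  R <- random_rotation(3, seed = 7)
  Y <- rep_of(2.5 * X$values %*% R, X$item_ids)
  expect_lt(procrustes_distance(X, Y)$value, 1e-7)
  # but sensitive to anisotropic scaling
  Yan <- rep_of(X$values %*% diag(c(1, 10, 1)), X$item_ids)
  expect_gt(procrustes_distance(X, Yan)$value, 1e-3)
  # the optimal map is orthogonal
  d <- procrustes_distance(X, Y)
  expect_lt(max(abs(crossprod(d$Q) - diag(3))), 1e-8)
})

test_that("the worked Procrustes instance equals arccos(0.5)", {
  X <- matrix(c(1, 0, -1, 0, 0, 0), 3, 2, byrow = TRUE)
  Y <- matrix(c(1, 0, 0, 0, -1, 0), 3, 2, byrow = TRUE)
  d <- procrustes_distance(rep_of(X), rep_of(Y))
  expect_equal(d$value, acos(0.5), tolerance = 1e-8)
  expect_equal(d$value, pi / 3, tolerance = 1e-8)
  # brute-force oracle over rotations + reflections agrees
  expect_equal(oracle_procrustes_2d(X, Y), d$value, tolerance = 1e-6)
})

test_that("SVD Procrustes agrees with brute-force minimization in 2D and 3D", {
  set.seed(9)
  for (rep_i in 1:3) {
    X <- matrix(rnorm(16), 8, 2)
    Y <- matrix(rnorm(16), 8, 2)
    expect_equal(procrustes_distance(rep_of(X), rep_of(Y))$value,
                 oracle_procrustes_2d(X, Y), tolerance = 1e-6)
  }
  X <- matrix(rnorm(24), 8, 3)
  Y <- matrix(rnorm(24), 8, 3)
  expect_equal(procrustes_distance(rep_of(X), rep_of(Y))$value,
               oracle_procrustes_3d(X, Y), tolerance = 1e-5)
})

test_that("CCA distance is invariant to invertible maps and finds orthogonal spaces", {
  set.seed(5)
  X <- rep_of(matrix(rnorm(60), 15, 4))
  expect_equal(cca_distance(X, X)$value, 0)
  A <- matrix(rnorm(16), 4, 4) + diag(4)
  Y <- rep_of(X$values %*% A, X$item_ids)
  expect_lt(cca_distance(X, Y)$value, 1e-6)
  # Procrustes generically > 0 for the same pair
  expect_gt(procrustes_distance(X, Y)$value, 1e-3)

  # disjoint coordinate subspaces of a common ambient space: all rho = 0
  n <- 12
  B1 <- matrix(rnorm(n * 2), n, 2)
  B1 <- sweep(B1, 2, colMeans(B1))
  B2 <- matrix(rnorm(n * 2), n, 2)
  B2 <- sweep(B2, 2, colMeans(B2))
  # orthogonalize the second block against the first
  B2 <- B2 - B1 %*% solve(crossprod(B1), crossprod(B1, B2))
  Xo <- rep_of(cbind(B1, matrix(0, n, 2)))
  Yo <- rep_of(cbind(matrix(0, n, 2), B2), Xo$item_ids)
  d <- cca_distance(Xo, Yo)
  expect_equal(d$value, pi / 2, tolerance = 1e-6)
  expect_lt(max(d$rho), 1e-6)
})

test_that("canonical correlations match stats::cancor on a small instance", {
  set.seed(13)
  X <- matrix(rnorm(40), 20, 2)
  Y <- matrix(rnorm(60), 20, 3)
  d <- cca_distance(rep_of(X), rep_of(Y))
  cc <- cancor(sweep(X, 2, colMeans(X)), sweep(Y, 2, colMeans(Y)))
  expect_equal(d$rho[1:2], cc$cor, tolerance = 1e-6)
})

test_that("distance axioms hold: identity, symmetry, triangle inequality", {
  set.seed(21)
  for (trial in 1:200) {
    n <- sample(5:20, 1); d <- sample(2:6, 1)
    A <- rep_of(matrix(rnorm(n * d), n, d))
    B <- rep_of(matrix(rnorm(n * d), n, d), A$item_ids)
    C <- rep_of(matrix(rnorm(n * d), n, d), A$item_ids)
    for (metric in c("procrustes", "cca")) {
      fn <- if (metric == "procrustes") procrustes_distance else cca_distance
      dab <- fn(A, B)$value; dba <- fn(B, A)$value
      dac <- fn(A, C)$value; dbc <- fn(B, C)$value
      expect_gte(dab, 0)
      expect_lt(abs(dab - dba), 1e-8)
      expect_lte(dac, dab + dbc + 1e-6)
    }
  }
})

test_that("pairwise distance matrices are symmetric with zero diagonal", {
  set.seed(3)
  X <- rep_of(matrix(rnorm(36), 12, 3), name = "X")
  R <- random_rotation(3, seed = 2)
  XR <- rep_of(X$values %*% R, X$item_ids, name = "XR")
  Z <- rep_of(matrix(rnorm(48), 12, 4), X$item_ids, name = "Z")
  dm <- pairwise_distances(list(X, X), metric = "procrustes")
  expect_true(all(dm$values == 0))
  dm3 <- pairwise_distances(list(X, XR, Z), metric = "procrustes")
  expect_equal(dm3$values, t(dm3$values), tolerance = 1e-8)
  expect_true(all(diag(dm3$values) == 0))
  expect_lt(dm3$values["X", "XR"], 1e-7)
  expect_equal(dm3$values["X", "Z"], dm3$values["XR", "Z"],
               tolerance = 1e-7)
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  write_distance_matrix(dm3, f)
  back <- read.csv(f)
  expect_equal(back$representation, c("X", "XR", "Z"))
})
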