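random_unit_dictionary <- function(N, M, seed) {
  set.seed(seed)
  D <- matrix(rnorm(N * M), N)
  sweep(D, 2L, sqrt(colSums(D^2)), "/")
}

test_that("OMP recovers exact sparse combinations and respects its contracts", {
  # identity dictionary: one atom suffices
  code <- omp_encode(diag(3), c(0, 2, 0), T0 = 1L)
  expect_equal(code$alpha, c(0, 2, 0))
  expect_identical(code$support, 2L)
  expect_equal(code$residual_norm, 0)

  # signal in the span of 2 atoms of an incoherent dictionary
  D <- random_unit_dictionary(15L, 10L, seed = 3L)
  x <- 2 * D[, 4L] - 1.5 * D[, 7L]
  rec <- omp_encode(D, x, T0 = 2L)
  expect_lt(rec$residual_norm, 1e-10)
  expect_setequal(rec$support, c(4L, 7L))

  # zero signal: empty support, zero code
  z <- omp_encode(D, numeric(15L), T0 = 3L)
  expect_length(z$support, 0L)
  expect_equal(z$alpha, numeric(10L))

  expect_error(omp_encode(D * 2, x, 1L), "unit norm")
  expect_error(omp_encode(D, x[1:5], 1L), "dimension")
})

test_that("OMP with T0 = M reproduces the full least-squares residual", {
  set.seed(19)
  for (case in 1:3) {
    D <- random_unit_dictionary(12L, 6L, seed = 100L + case)
    x <- rnorm(12L)
    got <- omp_encode(D, x, T0 = 6L)
    ls_res <- sqrt(sum(stats::lm.fit(D, x)$residuals^2))
    expect_equal(got$residual_norm, ls_res, tolerance = 1e-10)
  }
})

test_that("OMP residuals decrease with the sparsity budget and supports stay within it", {
  D <- random_unit_dictionary(20L, 12L, seed = 8L)
  set.seed(9)
  for (i in 1:5) {
    x <- rnorm(20L)
    res <- vapply(1:8, function(t0) {
      cd <- omp_encode(D, x, T0 = t0)
      expect_lte(length(cd$support), t0)
      cd$residual_norm
    }, 0)
    expect_true(all(diff(res) <= 1e-10))
  }
})

test_that("the K-SVD atom update is the Eckart-Young optimum of the restricted residual", {
  # rank-1 exact case: a single signal 5*d_k coded only by atom k
  D <- random_unit_dictionary(8L, 4L, seed = 5L)
  Y <- matrix(5 * D[, 2L], ncol = 1L)
  X <- matrix(0, 4L, 1L); X[2L, 1L] <- 1
  upd <- ksvd_atom_update(Y, D, X, 2L)
  flip <- sign(sum(upd$d * D[, 2L]))
  expect_equal(flip * upd$d, D[, 2L], tolerance = 1e-10)
  expect_equal(abs(upd$x_r), 5, tolerance = 1e-10)
  # sign convention: the largest-magnitude entry is positive
  expect_gt(upd$d[[which.max(abs(upd$d))]], 0)

  # random cases: the update never increases the restricted residual
  set.seed(33)
  for (i in 1:10) {
    D <- random_unit_dictionary(10L, 6L, seed = 200L + i)
    Y <- matrix(rnorm(10L * 15L), 10L)
    X <- matrix(0, 6L, 15L)
    for (s in 1:15) X[sample(6L, 3L), s] <- rnorm(3L)
    k <- sample(6L, 1L)
    omega <- which(X[k, ] != 0)
    Ek <- Y[, omega, drop = FALSE] -
      D[, -k, drop = FALSE] %*% X[-k, omega, drop = FALSE]
    before <- norm(Ek - D[, k] %*% t(X[k, omega]), "F")
    upd <- ksvd_atom_update(Y, D, X, k)
    after <- norm(Ek - upd$d %*% t(upd$x_r), "F")
    expect_lte(after, before + 1e-12)
  }

  # exactly rank-1 restricted residual: the update zeroes it
  d_true <- random_unit_dictionary(8L, 1L, seed = 77L)[, 1L]
  coefs <- c(1.5, -2, 0.5)
  D0 <- random_unit_dictionary(8L, 3L, seed = 78L)
  Y1 <- d_true %*% t(coefs)
  X1 <- rbind(coefs, matrix(0, 2L, 3L))
  upd1 <- ksvd_atom_update(Y1, D0, X1, 1L)
  expect_lt(norm(Y1 - upd1$d %*% t(upd1$x_r), "F"), 1e-10)

  # unused atom: flagged by NULL
  expect_null(ksvd_atom_update(Y1, D0, X1 * 0, 1L))
})

test_that("K-SVD keeps its initialization at zero iterations and learns planted dictionaries", {
  set.seed(44)
  Y <- matrix(rnorm(10L * 30L), 10L)
  d0 <- ksvd_learn(Y, M = 5L, T0 = 2L, max_iters = 0L, seed = 9L)
  set.seed(9L)
  norms <- sqrt(colSums(Y^2))
  init <- which(norms > 0)[sample.int(30L, 5L)]
  expect_equal(d0$D, sweep(Y[, init], 2L, norms[init], "/"),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_length(d0$error_trace, 0L)
  expect_error(ksvd_learn(Y, M = 40L, T0 = 2L), "at least M")

  # small planted case: 3-sparse data over a 20 x 8 dictionary
  Dtrue <- random_unit_dictionary(20L, 8L, seed = 91L)
  set.seed(92)
  Yp <- vapply(1:100, function(i) {
    Dtrue[, sample(8L, 3L)] %*% rnorm(3L, sd = 1)
  }, numeric(20L))
  dict <- ksvd_learn(Yp, M = 8L, T0 = 3L, seed = 4L)
  code <- omp_encode(dict, Yp, T0 = 3L)
  rel <- norm(Yp - dict$D %*% code$alpha, "F") / norm(Yp, "F")
  expect_lt(rel, 0.05)
})

test_that("fusion routes produce the documented dimensions and behaviors", {
  set.seed(70)
  mk_fm <- function(rows) {
    vals <- matrix(rnorm(length(rows) * 80L), length(rows))
    vals[, 1:10] <- vals[, 1:10] + rep(rows, 10L)
    feature_matrix(vals, rep(paste0("ch", 1:16), each = 5L),
                   rep(paste0("f", 1:5), 16L), rows,
                   rep("S1", length(rows)))
  }
  tr <- mk_fm(rep_len(c(0L, 1L), 60L))
  te <- mk_fm(rep_len(c(0L, 1L), 20L))

  fs <- fuse_sparse(tr, te, M = 20L, T0 = 5L, seed = 2L)
  expect_identical(dim(fs$train), c(60L, 20L))
  expect_identical(dim(fs$test), c(20L, 20L))
  expect_identical(fs$dictionary$M, 20L)

  # a test row identical to a train row gets the identical code
  te2 <- te
  te2$values[1L, ] <- tr$values[5L, ]
  fs2 <- fuse_sparse(tr, te2, M = 20L, T0 = 5L, seed = 2L)
  expect_equal(fs2$test[1L, ], fs2$train[5L, ], tolerance = 1e-12)

  # overcomplete limit: M = n_train atoms, T0 = M reconstructs exactly
  tr_small <- mk_fm(rep_len(c(0L, 1L), 10L))
  fsx <- fuse_sparse(tr_small, tr_small, M = 10L, T0 = 10L,
                     max_iters = 0L, seed = 1L)
  dict <- fsx$dictionary
  st <- eegfatigue:::standardize_pair(tr_small, tr_small)
  code <- omp_encode(dict, t(st$train), T0 = 10L)
  expect_lt(max(abs(t(st$train) - dict$D %*% code$alpha)), 1e-8)

  # concatenation: standardized pass-through, train columns centered
  fc <- fuse_concat(tr, te)
  expect_identical(dim(fc$train), c(60L, 80L))
  expect_lt(max(abs(colMeans(fc$train))), 1e-12)
  tr_const <- tr
  tr_const$values[, 3L] <- 7
  expect_warning(fcc <- fuse_concat(tr_const, te), "constant")
  expect_identical(ncol(fcc$train), 79L)

  # PCA: orthogonal scores, ordered variances, exact full-rank limit
  fp <- fuse_pca(tr, te, n_components = 20L)
  expect_identical(dim(fp$train), c(60L, 20L))
  gram <- crossprod(fp$train)
  expect_lt(max(abs(gram[upper.tri(gram)])), 1e-8)
  v <- apply(fp$train, 2L, var)
  expect_true(all(diff(v) <= 1e-10))
  fp_full <- fuse_pca(tr_small, tr_small, n_components = 9L)
  st_small <- eegfatigue:::standardize_pair(tr_small, tr_small)
  rebuilt <- fp_full$train %*% t(fp_full$rotation)
  centered <- sweep(st_small$train, 2L, colMeans(st_small$train))
  expect_equal(rebuilt, centered, tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(fuse_pca(tr_small, tr_small, n_components = 50L),
               "exceeds")

  # shared-column contract
  te_bad <- te
  te_bad$channels[1L] <- "chX"
  te_bad$values <- te$values
  expect_error(fuse_sparse(tr, te_bad), "column index")
})

test_that("K-SVD training error is non-increasing across alternations", {
  for (s in 1:20) {
    set.seed(300L + s)
    Y <- matrix(rnorm(30L * 60L), 30L)
    dict <- ksvd_learn(Y, M = 10L, T0 = 3L, max_iters = 12L, tol = 0,
                       seed = s)
    expect_true(all(diff(dict$error_trace) <= 1e-8),
                info = paste("seed", s))
  }
})

test_that("dictionaries round-trip through CSV + metadata", {
  D <- random_unit_dictionary(6L, 4L, seed = 13L)
  dict <- sparse_dictionary(D, T0 = 2L, error_trace = c(3, 2, 1.5),
                            seed = 13L)
  path <- tempfile(fileext = ".csv")
  write_dictionary(dict, path)
  back <- read_dictionary(path)
  expect_equal(back$D, D, tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(back$T0, 2L)
  expect_equal(back$error_trace, c(3, 2, 1.5))
})
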