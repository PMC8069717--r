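test_that("the elementary diff follows the discrete/continuous definitions", {
  expect_identical(relief_diff(3, 3, is_discrete = TRUE), 0)
  expect_identical(relief_diff(3, 5, is_discrete = TRUE), 1)
  expect_equal(relief_diff(3, 7, 0, 10), 0.4)
  expect_identical(relief_diff(2, 9, 4, 4), 0)
  expect_error(relief_diff(1, 2, 5, 3), "feature_max")
})

test_that("Relief matches a brute-force implementation exactly on small tables", {
  set.seed(101)
  for (case in 1:3) {
    n <- sample(8:20, 1L)
    X <- cbind(matrix(rnorm(n * 3L), n), sample(0:1, n, TRUE))
    y <- rep_len(c(0L, 1L), n)
    X[, 1L] <- X[, 1L] + 2 * y          # informative
    got <- relief_weights(X, y)
    expect_equal(got$w, oracle_relief(X, y), tolerance = 1e-12)
  }
})

test_that("Relief rewards a separating column and zeroes a constant one", {
  y <- c(0L, 0L, 0L, 1L, 1L, 1L)
  X <- cbind(sep = c(0, 0, 0, 1, 1, 1), const = rep(2, 6),
             noise = c(0.1, 0.9, 0.4, 0.8, 0.2, 0.6))
  w <- relief_weights(X, y)
  expect_gt(w$w[[1L]], 0)
  expect_identical(w$w[[2L]], 0)
  expect_equal(w$w, oracle_relief(X, y), tolerance = 1e-12)
  # duplicated informative column: exchangeable, equal weights
  Xd <- cbind(X[, 1L], X[, 1L], X[, 3L])
  wd <- relief_weights(Xd, y)
  expect_equal(wd$w[[1L]], wd$w[[2L]], tolerance = 1e-12)
  expect_error(relief_weights(X, rep(0L, 6L)), "2 classes")
  expect_error(relief_weights(X[1:4, ], c(0L, 0L, 0L, 1L)), "at least 2 samples")
})

test_that("ReliefF matches the brute-force multi-class oracle", {
  # 3-class toy table, 9 samples x 2 features
  X9 <- matrix(c(0.1, 0.2, 0.15, 1.1, 1.2, 1.05, 2.0, 2.2, 2.1,
                 0.5, 0.52, 0.47, 0.51, 0.49, 0.5, 0.52, 0.5, 0.48), 9L)
  y9 <- rep(1:3, each = 3L)
  got <- relieff_weights(X9, y9, relief_config(k = 2L))
  expect_equal(got$w, oracle_relieff(X9, y9, 2L), tolerance = 1e-12)
  # random 2- and 3-class tables
  set.seed(55)
  for (nc in 2:3) {
    n <- nc * 6L
    X <- matrix(rnorm(n * 4L), n)
    y <- rep(seq_len(nc), each = 6L)
    X[, 2L] <- X[, 2L] + y
    k <- 3L
    expect_equal(relieff_weights(X, y, relief_config(k = k))$w,
                 oracle_relieff(X, y, k), tolerance = 1e-12)
  }
  expect_error(relieff_weights(X9[1:4, ], c(1L, 1L, 1L, 2L),
                               relief_config(k = 2L)), "class 2")
})

test_that("ReliefF with k = 1 on two classes reduces to Relief", {
  set.seed(77)
  X <- matrix(rnorm(60), 15L)
  y <- rep_len(c(0L, 1L), 15L)
  X[, 1L] <- X[, 1L] + 1.5 * y
  expect_equal(relieff_weights(X, y, relief_config(k = 1L))$w,
               relief_weights(X, y)$w, tolerance = 1e-12)
})

test_that("label-permuted data yields weights centered on zero", {
  set.seed(13)
  X <- matrix(rnorm(30L * 5L), 30L)
  y <- rep_len(c(0L, 1L), 30L)
  perm_w <- t(vapply(1:100, function(i) {
    relieff_weights(X, sample(y), relief_config(k = 3L))$w
  }, numeric(5L)))
  ci <- 3 * apply(perm_w, 2L, sd) / sqrt(nrow(perm_w))
  expect_true(all(abs(colMeans(perm_w)) <= ci + 1e-8))
})

test_that("weights are invariant to positive rescaling of a column and to seeds on full passes", {
  fm <- make_toy_feature_table(40L, 6L, 2L, 2, seed = 6L)
  base <- relieff_weights(fm)
  scaled <- fm$values
  scaled[, 3L] <- scaled[, 3L] * 1000
  expect_equal(relieff_weights(scaled, fm$labels)$w, base$w,
               tolerance = 1e-12)
  # full pass ignores the seed entirely
  expect_identical(relieff_weights(fm, cfg = relief_config(seed = 1L))$w,
                   relieff_weights(fm, cfg = relief_config(seed = 99L))$w)
})

test_that("threshold selection and per-channel aggregation follow their definitions", {
  w <- feature_weights(c(0.3, 0.1, 0.25), paste0("c", 1:3), rep("f", 3L))
  expect_identical(threshold_select(w, 0.2), c(1L, 3L))
  expect_identical(threshold_select(w, -Inf), 1:3)
  expect_warning(empty <- threshold_select(w, Inf), "no feature")
  expect_length(empty, 0L)

  cw <- feature_weights(c(0.2, 0.4), c("Cz", "Cz"), c("f1", "f2"))
  expect_equal(channel_weights(cw), c(Cz = 0.3))
  one <- feature_weights(c(0.7, -0.1), c("a", "b"), c("f", "f"))
  expect_equal(channel_weights(one), c(a = 0.7, b = -0.1))

  set.seed(14)
  w16 <- rnorm(80L)
  chans <- rep(paste0("ch", 1:16), each = 5L)
  feats <- rep(paste0("f", 1:5), 16L)
  fw <- feature_weights(w16, chans, feats)
  expect_equal(channel_weights(fw),
               c(tapply(w16, factor(chans, levels = unique(chans)), mean)))
  ragged <- feature_weights(c(1, 2, 3), c("a", "a", "b"), c("f1", "f2", "f1"))
  expect_error(channel_weights(ragged), "ragged")
})
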