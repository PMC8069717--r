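toy_fm_for_channels <- function(seed = 1L, n = 200L) {
  set.seed(seed)
  y <- rep_len(c(0L, 1L), n)
  vals <- cbind(y + rnorm(n, sd = 0.1),      # (chA, f1): near-perfect
                rnorm(n),                    # (chA, f2): noise
                rnorm(n),                    # (chB, f1): noise
                rnorm(n))                    # (chB, f2): noise
  feature_matrix(vals, c("chA", "chA", "chB", "chB"),
                 c("f1", "f2", "f1", "f2"), y, rep("S1", n))
}

test_that("single-channel accuracy is 1 for separating columns and chance for noise", {
  fm <- toy_fm_for_channels()
  # column equal to the label: perfect under any fold count
  lab_fm <- feature_matrix(cbind(as.numeric(fm$labels), rnorm(200L)),
                           c("a", "b"), c("f", "f"), fm$labels,
                           fm$subject_ids)
  expect_identical(single_channel_accuracy(lab_fm, "a", "f", cv_folds = 5L), 1)
  expect_identical(single_channel_accuracy(lab_fm, "a", "f", cv_folds = 2L), 1)
  expect_gte(single_channel_accuracy(fm, "chA", "f1"), 0.9)
  chance <- vapply(1:50, function(s)
    single_channel_accuracy(fm, "chB", "f1", seed = s), 0)
  expect_gt(mean(chance), 0.4)
  expect_lt(mean(chance), 0.6)
  expect_error(single_channel_accuracy(fm, "chC", "f1"), "no column")
})

test_that("weight-addition common channels normalize per subject then sum", {
  # two subjects whose normalized channel weights are [0, 1] and [1, 0]
  W <- array(0, dim = c(2L, 2L, 1L))
  W[1L, , 1L] <- c(1, 2)
  W[2L, , 1L] <- c(2, 1)
  tab2 <- channel_weight_table(W, NULL, c("c1", "c2"), c("s1", "s2"), "f")
  expect_equal(common_weights_addition(tab2), c(c1 = 1, c2 = 1))

  W3 <- array(0, dim = c(2L, 3L, 1L))
  W3[1L, , 1L] <- c(1, 2, 3)       # min-max: 0, 0.5, 1
  W3[2L, , 1L] <- c(5, 1, 3)       # min-max: 1, 0, 0.5
  tab3 <- channel_weight_table(W3, NULL, c("c1", "c2", "c3"),
                               c("s1", "s2"), "f")
  expect_equal(common_weights_addition(tab3), c(c1 = 1, c2 = 0.5, c3 = 1.5))

  # single subject: ranking is that subject's own per-channel ranking
  tab1 <- channel_weight_table(W3[1L, , , drop = FALSE], NULL,
                               c("c1", "c2", "c3"), "s1", "f")
  expect_identical(order(-common_weights_addition(tab1)),
                   order(-apply(W3[1L, , , drop = FALSE], 2L, mean)))

  # degenerate subject: all-equal weights become 0.5 with a warning
  Wd <- array(1, dim = c(1L, 3L, 2L))
  tabd <- channel_weight_table(Wd, NULL, c("c1", "c2", "c3"), "s1",
                               c("f1", "f2"))
  expect_warning(wd <- common_weights_addition(tabd), "all-equal")
  expect_equal(unname(wd), rep(0.5, 3L))
})

test_that("normalize-then-sum matches an independent oracle on random tables", {
  set.seed(99)
  W <- array(rnorm(3L * 5L * 4L), dim = c(3L, 5L, 4L))
  tab <- channel_weight_table(W, NULL, paste0("c", 1:5), paste0("s", 1:3),
                              paste0("f", 1:4))
  got <- common_weights_addition(tab)
  want <- numeric(5L)
  for (j in 1:3) {
    wj <- vapply(1:5, function(l) mean(W[j, l, ]), 0)
    wj <- (wj - min(wj)) / (max(wj) - min(wj))
    want <- want + wj
  }
  expect_equal(unname(got), want, tolerance = 1e-12)
})

test_that("accuracy-weighted common channels are the exact weight-accuracy double sum", {
  # single subject, single feature: products
  W <- array(c(0.2, 0.4), dim = c(1L, 2L, 1L))
  A <- array(c(0.5, 1.0), dim = c(1L, 2L, 1L))
  tab <- channel_weight_table(W, A, c("c1", "c2"), "s1", "f")
  expect_equal(common_weights_accuracy(tab), c(c1 = 0.1, c2 = 0.4))

  set.seed(31)
  W <- array(rnorm(2L * 4L * 3L), dim = c(2L, 4L, 3L))
  A <- array(runif(2L * 4L * 3L), dim = c(2L, 4L, 3L))
  tab <- channel_weight_table(W, A, paste0("c", 1:4), c("s1", "s2"),
                              paste0("f", 1:3))
  got <- common_weights_accuracy(tab)
  want <- numeric(4L)
  for (l in 1:4) for (j in 1:2) for (i in 1:3)
    want[[l]] <- want[[l]] + W[j, l, i] * A[j, l, i]
  expect_equal(unname(got), want, tolerance = 1e-12)

  # all accuracies 1: reduces to the plain weight sum
  A1 <- array(1, dim = dim(W))
  tab1 <- channel_weight_table(W, A1, paste0("c", 1:4), c("s1", "s2"),
                               paste0("f", 1:3))
  expect_equal(unname(common_weights_accuracy(tab1)),
               vapply(1:4, function(l) sum(W[, l, ]), 0), tolerance = 1e-12)
  tab_noacc <- channel_weight_table(W, NULL, paste0("c", 1:4),
                                    c("s1", "s2"), paste0("f", 1:3))
  expect_error(common_weights_accuracy(tab_noacc), "not populated")
})

test_that("both aggregation schemes ignore subject order", {
  set.seed(47)
  W <- array(rnorm(4L * 6L * 2L), dim = c(4L, 6L, 2L))
  A <- array(runif(4L * 6L * 2L), dim = c(4L, 6L, 2L))
  perm <- c(3L, 1L, 4L, 2L)
  t1 <- channel_weight_table(W, A, paste0("c", 1:6), paste0("s", 1:4),
                             c("f1", "f2"))
  t2 <- channel_weight_table(W[perm, , ], A[perm, , ], paste0("c", 1:6),
                             paste0("s", 1:4)[perm], c("f1", "f2"))
  expect_equal(common_weights_accuracy(t1), common_weights_accuracy(t2),
               tolerance = 1e-12)
  expect_equal(common_weights_addition(t1), common_weights_addition(t2),
               tolerance = 1e-12)
})

test_that("top-half selection sorts descending with ties to the earlier channel", {
  w16 <- stats::setNames(seq(0.1, 1.6, by = 0.1), paste0("ch", 1:16))
  sel <- select_common_channels(w16)
  expect_length(sel, 8L)
  expect_identical(sel, paste0("ch", 16:9))
  # tie at the cut: the lower-index channel wins
  wt <- c(a = 1, b = 0.5, c = 0.5, d = 0.2)
  expect_identical(select_common_channels(wt, 2L), c("a", "b"))
  expect_identical(select_common_channels(wt, 3L), c("a", "b", "c"))
  expect_error(select_common_channels(wt, 9L), "exceeds")
})
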