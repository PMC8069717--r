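# Multi-feature fusion: the per-epoch feature vectors (all channels x all
# feature types) are z-scored with training statistics and then either
# sparse-coded against a K-SVD dictionary learned on the training samples
# (the method of interest), projected by PCA, or passed through unchanged
# (the two baselines).

check_fusion_inputs <- function(train, test) {
  stopifnot(inherits(train, "feature_matrix"), inherits(test, "feature_matrix"))
  if (!identical(train$channels, test$channels) ||
      !identical(train$features, test$features))
    stop("train and test feature matrices must share their column index")
  if (length(unique(train$labels)) < 2L)
    stop("training data must contain both classes")
}

# z-score with training statistics; constant training columns are dropped
standardize_pair <- function(train, test) {
  mu <- colMeans(train$values)
  sdev <- apply(train$values, 2L, stats::sd)
  keep <- sdev > 0
  if (!all(keep))
    warning(sum(!keep), " constant feature column(s) dropped before fusion")
  tr <- sweep(sweep(train$values[, keep, drop = FALSE], 2L, mu[keep]),
              2L, sdev[keep], "/")
  te <- sweep(sweep(test$values[, keep, drop = FALSE], 2L, mu[keep]),
              2L, sdev[keep], "/")
  list(train = tr, test = te, keep = keep, mu = mu[keep], sd = sdev[keep])
}

fusion_result <- function(train_codes, test_codes, train_fm, test_fm,
                          method, dictionary = NULL, extra = list()) {
  structure(c(list(train = train_codes, test = test_codes,
                   train_labels = train_fm$labels,
                   test_labels = test_fm$labels, method = method,
                   dictionary = dictionary), extra),
            class = "fusion_result")
}

#' @export
print.fusion_result <- function(x, ...) {
  cat(sprintf("<fusion_result> method %s: train %d x %d, test %d x %d\n",
              x$method, nrow(x$train), ncol(x$train), nrow(x$test),
              ncol(x$test)))
  invisible(x)
}

#' Sparse multi-feature fusion via K-SVD + OMP
#'
#' Learns an undercomplete dictionary on the z-scored training feature
#' vectors (signals = samples, so `N` = number of feature columns) and
#' returns the OMP sparse codes of every train and test sample as the
#' fused features: with `M` atoms the fused dimension is `M` (80 -> 20 in
#' the reference configuration).
#'
#' @param train,test [feature_matrix()] objects sharing the same columns.
#' @param M Number of atoms (fused dimension, default 20).
#' @param T0 OMP sparsity level (default 5).
#' @param max_iters,tol,seed K-SVD learning controls (see [ksvd_learn()]).
#' @return A `fusion_result` with `train`/`test` code matrices `[n x M]`,
#'   the learned [sparse_dictionary()], and residual norms.
#' @export
fuse_sparse <- function(train, test, M = 20L, T0 = 5L, max_iters = 50L,
                        tol = 1e-4, seed = 1L) {
  check_fusion_inputs(train, test)
  st <- standardize_pair(train, test)
  dict <- ksvd_learn(t(st$train), M = M, T0 = T0, max_iters = max_iters,
                     tol = tol, seed = seed)
  ctr <- omp_encode(dict, t(st$train), T0 = T0)
  cte <- omp_encode(dict, t(st$test), T0 = T0)
  fusion_result(t(ctr$alpha), t(cte$alpha), train, test, "sparse", dict,
                extra = list(train_residuals = ctr$residual_norm,
                             test_residuals = cte$residual_norm))
}

#' Concatenation baseline: standardized pass-through
#'
#' @param train,test [feature_matrix()] objects sharing the same columns.
#' @return A `fusion_result` with the full-dimensional z-scored features.
#' @export
fuse_concat <- function(train, test) {
  check_fusion_inputs(train, test)
  st <- standardize_pair(train, test)
  fusion_result(st$train, st$test, train, test, "concat")
}

#' PCA fusion baseline
#'
#' PCA fit on the standardized training features; train and test are
#' projected onto the leading components. If the training data has lower
#' rank than requested, the available components are kept with a warning.
#'
#' @param train,test [feature_matrix()] objects sharing the same columns.
#' @param n_components Projection dimension (default 20).
#' @return A `fusion_result` with the projected features and the rotation.
#' @export
fuse_pca <- function(train, test, n_components = 20L) {
  check_fusion_inputs(train, test)
  st <- standardize_pair(train, test)
  if (n_components > min(nrow(st$train), ncol(st$train)))
    stop("n_components exceeds min(n_train, n_features)")
  pc <- stats::prcomp(st$train, center = TRUE, scale. = FALSE)
  avail <- sum(pc$sdev > max(pc$sdev) * 1e-10)
  if (avail < n_components) {
    warning("training data has rank ", avail, " < ", n_components,
            " requested components; keeping ", avail)
    n_components <- avail
  }
  rot <- pc$rotation[, seq_len(n_components), drop = FALSE]
  ctr <- sweep(st$train, 2L, pc$center) %*% rot
  cte <- sweep(st$test, 2L, pc$center) %*% rot
  fusion_result(ctr, cte, train, test, "pca",
                extra = list(rotation = rot, sdev = pc$sdev))
}

#' Persist a sparse dictionary as CSV + JSON metadata
#'
#' @param dict A [sparse_dictionary()].
#' @param path CSV path (atoms as columns); metadata goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_dictionary <- function(dict, path) {
  stopifnot(inherits(dict, "sparse_dictionary"))
  utils::write.table(dict$D, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(list(M = dict$M, N = dict$N, T0 = dict$T0,
                            seed = dict$seed, n_iters = dict$n_iters,
                            error_trace = dict$error_trace),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a dictionary written by [write_dictionary()]
#'
#' @param path CSV path (expects `<path>.json` sidecar).
#' @return A [sparse_dictionary()].
#' @export
read_dictionary <- function(path) {
  D <- as.matrix(utils::read.csv(path, header = FALSE))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  sparse_dictionary(D, meta$T0, as.numeric(meta$error_trace), meta$seed,
                    meta$n_iters)
}
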