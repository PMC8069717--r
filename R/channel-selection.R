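#' Per-subject channel weight and accuracy table
#'
#' Holds, for every subject, the ReliefF weight and the single-channel
#' classification accuracy of each (channel, feature) pair; the raw
#' material of both common-channel aggregation schemes.
#'
#' @param weights Array `[n_subjects x n_channels x n_features]` of
#'   ReliefF weights.
#' @param acc Array of the same shape with single-channel accuracies in
#'   `[0, 1]` (may be `NULL` if only the weight-addition scheme is used).
#' @param channel_labels,subject_ids,feature_names Dimension labels.
#' @return A `channel_weight_table`.
#' @export
channel_weight_table <- function(weights, acc = NULL, channel_labels,
                                 subject_ids, feature_names) {
  stopifnot(is.array(weights), length(dim(weights)) == 3L)
  d <- dim(weights)
  if (!is.null(acc)) {
    if (!identical(dim(acc), d)) stop("weight and accuracy arrays must agree in shape")
    if (any(acc < 0 | acc > 1)) stop("accuracies must lie in [0, 1]")
  }
  if (length(subject_ids) != d[[1L]] || length(channel_labels) != d[[2L]] ||
      length(feature_names) != d[[3L]])
    stop("dimension labels do not match the array shape")
  dimnames(weights) <- list(subject_ids, channel_labels, feature_names)
  if (!is.null(acc)) dimnames(acc) <- dimnames(weights)
  structure(list(weights = weights, acc = acc,
                 channel_labels = as.character(channel_labels),
                 subject_ids = as.character(subject_ids),
                 feature_names = as.character(feature_names)),
            class = "channel_weight_table")
}

#' @export
print.channel_weight_table <- function(x, ...) {
  d <- dim(x$weights)
  cat(sprintf("<channel_weight_table> %d subjects x %d channels x %d features (%s accuracies)\n",
              d[1L], d[2L], d[3L], if (is.null(x$acc)) "without" else "with"))
  invisible(x)
}

#' Single-channel, single-feature classification accuracy
#'
#' Accuracy of the SRDA classifier on one (channel, feature) column under
#' seeded stratified k-fold cross-validation.
#'
#' @param X A [feature_matrix()].
#' @param channel,feature Column identity.
#' @param cv_folds Number of folds (default 5).
#' @param seed RNG seed for the fold assignment.
#' @param reg_alpha Ridge penalty passed to [srda_fit()].
#' @return Mean fold accuracy in `[0, 1]`.
#' @export
single_channel_accuracy <- function(X, channel, feature, cv_folds = 5L,
                                    seed = 1L, reg_alpha = 0.01) {
  stopifnot(inherits(X, "feature_matrix"))
  col <- which(X$channels == channel & X$features == feature)
  if (length(col) != 1L)
    stop("no column for channel ", channel, ", feature ", feature)
  cv_column_accuracy(X$values[, col, drop = FALSE], X$labels, cv_folds,
                     seed, reg_alpha)
}

# stratified k-fold CV accuracy of SRDA on a (possibly 1-D) feature block
cv_column_accuracy <- function(vals, y, cv_folds = 5L, seed = 1L,
                               reg_alpha = 0.01) {
  folds <- stratified_folds(y, cv_folds, seed)
  mean(vapply(seq_len(cv_folds), function(f) {
    tr <- folds != f
    model <- srda_fit(vals[tr, , drop = FALSE], y[tr], reg_alpha)
    mean(srda_predict(model, vals[!tr, , drop = FALSE]) == y[!tr])
  }, 0))
}

# seeded stratified fold assignment, one fold id per sample
stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  folds <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Build the channel weight/accuracy table from per-subject features
#'
#' Runs [relieff_weights()] and (optionally) [single_channel_accuracy()]
#' on each subject's feature matrix.
#'
#' @param feature_matrices List of [feature_matrix()], one per subject.
#' @param cfg A [relief_config()].
#' @param with_acc Also compute single-channel CV accuracies (default TRUE).
#' @param cv_folds,seed Cross-validation settings for the accuracy array.
#' @param reg_alpha Ridge penalty for the single-channel SRDA fits.
#' @return A [channel_weight_table()].
#' @export
compute_channel_weight_table <- function(feature_matrices,
                                         cfg = relief_config(),
                                         with_acc = TRUE, cv_folds = 5L,
                                         seed = 1L, reg_alpha = 0.01) {
  stopifnot(length(feature_matrices) >= 1L)
  ref <- feature_matrices[[1L]]
  chans <- unique(ref$channels)
  feats <- unique(ref$features)
  ns <- length(feature_matrices)
  W <- array(0, dim = c(ns, length(chans), length(feats)))
  A <- if (with_acc) array(0, dim = dim(W)) else NULL
  sids <- character(ns)
  for (j in seq_len(ns)) {
    fm <- feature_matrices[[j]]
    sids[[j]] <- fm$subject_ids[[1L]]
    fw <- relieff_weights(fm, cfg = cfg)
    for (ci in seq_along(chans)) for (fi in seq_along(feats)) {
      col <- which(fw$channels == chans[[ci]] & fw$features == feats[[fi]])
      if (length(col) != 1L) stop("missing (channel, feature) column")
      W[j, ci, fi] <- fw$w[[col]]
      if (with_acc)
        A[j, ci, fi] <- single_channel_accuracy(fm, chans[[ci]], feats[[fi]],
                                                cv_folds, seed, reg_alpha)
    }
  }
  channel_weight_table(W, A, chans, sids, feats)
}

#' Common channel weights by normalized weight addition
#'
#' Per subject, the per-channel weights (mean over features) are min-max
#' normalized across that subject's channels to `[0, 1]` and then summed
#' across subjects. A subject with all-equal channel weights contributes
#' 0.5 everywhere (degenerate min-max), with a warning.
#'
#' @param table A [channel_weight_table()].
#' @param normalize `"minmax"` (default) or `"sum"` (divide by the total).
#' @return Named per-channel weights.
#' @export
common_weights_addition <- function(table, normalize = c("minmax", "sum")) {
  stopifnot(inherits(table, "channel_weight_table"))
  normalize <- match.arg(normalize)
  per_subject <- apply(table$weights, c(1L, 2L), mean)   # Eq-8 channel means
  out <- numeric(length(table$channel_labels))
  for (j in seq_len(nrow(per_subject))) {
    wj <- per_subject[j, ]
    if (normalize == "minmax") {
      rng <- max(wj) - min(wj)
      if (rng == 0) {
        warning("subject ", table$subject_ids[[j]],
                " has all-equal channel weights; using 0.5")
        wj <- rep(0.5, length(wj))
      } else {
        wj <- (wj - min(wj)) / rng
      }
    } else {
      tot <- sum(wj)
      wj <- if (tot == 0) rep(1 / length(wj), length(wj)) else wj / tot
    }
    out <- out + wj
  }
  names(out) <- table$channel_labels
  out
}

#' Common channel weights by accuracy weighting
#'
#' `W(Cl) = sum_j sum_i W(Cl, Fi, Sj) * Acc(Cl, Fi, Sj)`: every subject's
#' per-(channel, feature) weight is multiplied by that column's
#' single-channel classification accuracy before summation.
#'
#' @param table A [channel_weight_table()] with accuracies populated.
#' @return Named per-channel weights.
#' @export
common_weights_accuracy <- function(table) {
  stopifnot(inherits(table, "channel_weight_table"))
  if (is.null(table$acc))
    stop("accuracy array is not populated; see compute_channel_weight_table()")
  out <- apply(table$weights * table$acc, 2L, sum)
  names(out) <- table$channel_labels
  out
}

#' Select the top channels by weight
#'
#' Channels sorted by weight descending (ties broken by original channel
#' order); the first `n_keep` are returned. The default keeps the top half,
#' halving a 16-channel montage to 8 channels.
#'
#' @param weights Named per-channel weights.
#' @param n_keep Number of channels to keep (default `floor(n/2)`).
#' @return Character vector of selected channel labels, best first.
#' @export
select_common_channels <- function(weights,
                                   n_keep = floor(length(weights) / 2)) {
  if (n_keep > length(weights)) stop("n_keep exceeds the number of channels")
  ord <- order(-weights, seq_along(weights))
  names(weights)[ord][seq_len(n_keep)]
}
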