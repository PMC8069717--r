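#' Configuration for Relief / ReliefF weighting
#'
#' @param m_iter Number of sampled instances. `NULL` (default) runs one
#'   deterministic full pass over all training samples in index order.
#' @param k Neighbor count for ReliefF. `NULL` (default) uses 10, clipped
#'   to the smallest class size minus one; an explicit `k` is enforced
#'   strictly (a class smaller than `k + 1` is an error).
#' @param delta Feature-weight threshold used by [threshold_select()].
#' @param seed RNG seed for random sampling (only used when `m_iter` is
#'   given).
#' @param sample_without_replacement Sample instances without replacement
#'   when `m_iter` is given (default TRUE).
#' @return A `relief_config` list.
#' @export
relief_config <- function(m_iter = NULL, k = NULL, delta = 0, seed = 1L,
                          sample_without_replacement = TRUE) {
  if (!is.null(m_iter) && m_iter < 1L) stop("m_iter must be >= 1")
  if (!is.null(k) && k < 1L) stop("k must be >= 1")
  structure(list(m_iter = m_iter, k = k, delta = delta,
                 seed = as.integer(seed),
                 sample_without_replacement = sample_without_replacement),
            class = "relief_config")
}

#' Feature weights aligned to a feature matrix
#'
#' @param w Numeric weight vector.
#' @param channels,features Column identity of each weight.
#' @return A `feature_weights` object.
#' @export
feature_weights <- function(w, channels, features) {
  if (!all(is.finite(w))) stop("weights must be finite")
  if (length(channels) != length(w) || length(features) != length(w))
    stop("channels/features must align with w")
  structure(list(w = as.numeric(w), channels = as.character(channels),
                 features = as.character(features)),
            class = "feature_weights")
}

#' @export
print.feature_weights <- function(x, ...) {
  cat(sprintf("<feature_weights> %d columns; range [%.4g, %.4g]\n",
              length(x$w), min(x$w), max(x$w)))
  invisible(x)
}

#' Elementary Relief feature difference
#'
#' Discrete features: 0 if equal else 1. Continuous features:
#' `|a - b| / (max - min)`, and 0 when the range is degenerate.
#'
#' @param value_a,value_b Feature values.
#' @param feature_min,feature_max Observed range of the feature (training
#'   split), ignored for discrete features.
#' @param is_discrete Treat the feature as discrete (default FALSE).
#' @return A scalar in `[0, 1]`.
#' @export
relief_diff <- function(value_a, value_b, feature_min = NULL,
                        feature_max = NULL, is_discrete = FALSE) {
  if (is_discrete) return(as.numeric(value_a != value_b))
  if (is.null(feature_min) || is.null(feature_max))
    stop("continuous diff needs feature_min and feature_max")
  if (feature_max < feature_min) stop("feature_max must be >= feature_min")
  rng <- feature_max - feature_min
  if (rng == 0) return(0)
  abs(value_a - value_b) / rng
}

# range-normalize columns; degenerate (constant) columns map to all-zero so
# they contribute nothing to distances or weight updates
relief_normalize <- function(X) {
  lo <- apply(X, 2L, min)
  hi <- apply(X, 2L, max)
  rng <- hi - lo
  rng[rng == 0] <- Inf
  sweep(sweep(X, 2L, lo, "-"), 2L, rng, "/")
}

relief_sample_indices <- function(n, cfg) {
  if (is.null(cfg$m_iter)) return(seq_len(n))
  set.seed(cfg$seed)
  sample.int(n, size = min(cfg$m_iter, if (cfg$sample_without_replacement) n
                           else cfg$m_iter),
             replace = !cfg$sample_without_replacement)
}

# k nearest neighbors of i within candidate indices, Manhattan distance on
# the normalized features, ties broken by lowest sample index
nearest_k <- function(Xn, i, candidates, k) {
  d <- colSums(abs(t(Xn[candidates, , drop = FALSE]) - Xn[i, ]))
  candidates[order(d, candidates)[seq_len(min(k, length(candidates)))]]
}

#' Relief feature weights (binary classes, single nearest hit/miss)
#'
#' For each sampled instance the single nearest same-class hit and
#' nearest other-class miss are found (Manhattan distance on
#' range-normalized features) and each feature weight is updated by
#' `W <- W - diff(hit)/m + diff(miss)/m`, starting from zero.
#'
#' @param X A [feature_matrix()] (or plain numeric matrix).
#' @param y Binary labels (ignored when `X` is a feature_matrix).
#' @param cfg A [relief_config()].
#' @return A [feature_weights()].
#' @export
relief_weights <- function(X, y = NULL, cfg = relief_config()) {
  p <- as_relief_input(X, y)
  classes <- sort(unique(p$y))
  if (length(classes) != 2L)
    stop("Relief requires exactly 2 classes, got ", length(classes))
  if (any(table(p$y) < 2L)) stop("each class needs at least 2 samples")
  Xn <- relief_normalize(p$X)
  n <- nrow(Xn); a <- ncol(Xn)
  idx <- relief_sample_indices(n, cfg)
  m <- length(idx)
  w <- numeric(a)
  for (i in idx) {
    same <- setdiff(which(p$y == p$y[[i]]), i)
    other <- which(p$y != p$y[[i]])
    h <- nearest_k(Xn, i, same, 1L)
    mm <- nearest_k(Xn, i, other, 1L)
    w <- w - abs(Xn[i, ] - Xn[h, ]) / m + abs(Xn[i, ] - Xn[mm, ]) / m
  }
  feature_weights(w, p$channels, p$features)
}

#' ReliefF feature weights (multi-class, k neighbors)
#'
#' For each sampled instance, the k nearest same-class hits decrease the
#' weight and, for every other class `C`, the k nearest misses in `C`
#' increase it with prior weight `p(C) / (1 - p(class(i)))`, all terms
#' averaged by `1 / (m k)`. Class priors are the empirical proportions.
#'
#' @inheritParams relief_weights
#' @return A [feature_weights()].
#' @export
relieff_weights <- function(X, y = NULL, cfg = relief_config()) {
  p <- as_relief_input(X, y)
  classes <- sort(unique(p$y))
  if (length(classes) < 2L) stop("ReliefF requires at least 2 classes")
  sizes <- table(p$y)
  k <- cfg$k
  if (is.null(k)) {
    k <- max(1L, min(10L, min(sizes) - 1L))
  } else if (any(sizes < k + 1L)) {
    bad <- names(sizes)[sizes < k + 1L][[1L]]
    stop("class ", bad, " has fewer than k + 1 = ", k + 1L, " samples")
  }
  priors <- as.numeric(sizes) / nrow(p$X)
  names(priors) <- names(sizes)
  Xn <- relief_normalize(p$X)
  idx <- relief_sample_indices(nrow(Xn), cfg)
  m <- length(idx)
  w <- numeric(ncol(Xn))
  for (i in idx) {
    ci <- as.character(p$y[[i]])
    same <- setdiff(which(p$y == p$y[[i]]), i)
    hits <- nearest_k(Xn, i, same, k)
    w <- w - colSums(abs(Xn[hits, , drop = FALSE] -
                         rep(Xn[i, ], each = length(hits)))) / (m * k)
    for (cl in setdiff(names(priors), ci)) {
      miss_cand <- which(p$y == as_class(p$y, cl))
      misses <- nearest_k(Xn, i, miss_cand, k)
      pw <- priors[[cl]] / (1 - priors[[ci]])
      w <- w + pw * colSums(abs(Xn[misses, , drop = FALSE] -
                                rep(Xn[i, ], each = length(misses)))) / (m * k)
    }
  }
  feature_weights(w, p$channels, p$features)
}

as_class <- function(y, label) {
  u <- unique(y)
  u[as.character(u) == label][[1L]]
}

as_relief_input <- function(X, y) {
  if (inherits(X, "feature_matrix")) {
    list(X = X$values, y = X$labels, channels = X$channels,
         features = X$features)
  } else {
    X <- as.matrix(X)
    if (is.null(y)) stop("y is required when X is a plain matrix")
    if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
    cn <- colnames(X)
    if (is.null(cn)) cn <- paste0("V", seq_len(ncol(X)))
    list(X = X, y = y, channels = cn, features = rep("feature", ncol(X)))
  }
}

#' Select features whose weight reaches a threshold
#'
#' @param w A [feature_weights()].
#' @param delta Threshold; columns with `W >= delta` are kept in their
#'   original order.
#' @return Integer indices of the selected columns (possibly empty, with a
#'   warning).
#' @export
threshold_select <- function(w, delta) {
  stopifnot(inherits(w, "feature_weights"))
  sel <- which(w$w >= delta)
  if (length(sel) == 0L) warning("no feature weight reaches delta = ", delta)
  sel
}

#' Aggregate feature weights into per-channel weights
#'
#' The channel weight is the arithmetic mean of that channel's feature
#' weights; every channel must carry the same feature set.
#'
#' @param w A [feature_weights()].
#' @return Named numeric vector of channel weights, channels in order of
#'   first appearance.
#' @export
channel_weights <- function(w) {
  stopifnot(inherits(w, "feature_weights"))
  chans <- unique(w$channels)
  featsets <- split(w$features, factor(w$channels, levels = chans))
  ref <- sort(featsets[[1L]])
  if (!all(vapply(featsets, function(f) identical(sort(f), ref), TRUE)))
    stop("ragged coverage: channels carry different feature sets")
  out <- vapply(chans, function(cl) mean(w$w[w$channels == cl]), 0)
  names(out) <- chans
  out
}
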