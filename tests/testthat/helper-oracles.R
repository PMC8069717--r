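# Independent brute-force oracles, written as plain loops so they share no
# code path with the package implementations they check.

# range-normalized per-feature difference used by both Relief oracles
oracle_diff_fun <- function(X) {
  lo <- apply(X, 2L, min)
  hi <- apply(X, 2L, max)
  rng <- hi - lo
  function(i, j, f) if (rng[[f]] == 0) 0 else abs(X[i, f] - X[j, f]) / rng[[f]]
}

# Relief: full pass in index order, single nearest hit/miss, Manhattan
# distance on range-normalized features, distance ties to lowest index
oracle_relief <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X); a <- ncol(X)
  dif <- oracle_diff_fun(X)
  dst <- function(i, j) sum(vapply(seq_len(a), function(f) dif(i, j, f), 0))
  w <- numeric(a)
  for (i in seq_len(n)) {
    hits <- setdiff(which(y == y[[i]]), i)
    miss <- which(y != y[[i]])
    dh <- vapply(hits, function(j) dst(i, j), 0)
    dm <- vapply(miss, function(j) dst(i, j), 0)
    h <- hits[order(dh, hits)][[1L]]
    mm <- miss[order(dm, miss)][[1L]]
    for (f in seq_len(a))
      w[[f]] <- w[[f]] - dif(i, h, f) / n + dif(i, mm, f) / n
  }
  w
}

# ReliefF: full pass, k nearest hits, per-class k nearest misses with
# prior weights p(C) / (1 - p(class(i)))
oracle_relieff <- function(X, y, k) {
  X <- as.matrix(X)
  n <- nrow(X); a <- ncol(X)
  dif <- oracle_diff_fun(X)
  dst <- function(i, j) sum(vapply(seq_len(a), function(f) dif(i, j, f), 0))
  pri <- table(y) / n
  w <- numeric(a)
  for (i in seq_len(n)) {
    same <- setdiff(which(y == y[[i]]), i)
    ds <- vapply(same, function(j) dst(i, j), 0)
    hits <- same[order(ds, same)][seq_len(k)]
    for (f in seq_len(a))
      w[[f]] <- w[[f]] - sum(vapply(hits, function(j) dif(i, j, f), 0)) / (n * k)
    for (cl in setdiff(names(pri), as.character(y[[i]]))) {
      cand <- which(as.character(y) == cl)
      dc <- vapply(cand, function(j) dst(i, j), 0)
      misses <- cand[order(dc, cand)][seq_len(k)]
      pw <- pri[[cl]] / (1 - pri[[as.character(y[[i]])]])
      for (f in seq_len(a))
        w[[f]] <- w[[f]] +
          pw * sum(vapply(misses, function(j) dif(i, j, f), 0)) / (n * k)
    }
  }
  w
}

# sample entropy by explicit embedding matrices and pairwise Chebyshev
# distances (Richman-Moorman: the n - m templates with a continuation)
oracle_sampen <- function(x, m, r) {
  n <- length(x)
  count_pairs <- function(mm) {
    idx <- seq_len(n - m)          # template starts, same set for m and m+1
    cnt <- 0L
    for (i in idx) for (j in idx) {
      if (j <= i) next
      if (max(abs(x[i:(i + mm - 1L)] - x[j:(j + mm - 1L)])) <= r)
        cnt <- cnt + 1L
    }
    cnt
  }
  B <- count_pairs(m)
  A <- count_pairs(m + 1L)
  if (B == 0L) return(0)
  if (A == 0L) return(-log(1 / (B + 1)))
  -log(A / B)
}
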