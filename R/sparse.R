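#' Sparse dictionary learned by K-SVD
#'
#' Column-normalized atom matrix `D` (`N x M`, undercomplete when
#' `M < N`, so sparse codes also reduce dimensionality) with its learning
#' metadata.
#'
#' @param D Atom matrix with unit-norm columns.
#' @param T0 Sparsity level used during learning.
#' @param error_trace Per-iteration Frobenius reconstruction error.
#' @param seed,n_iters Learning metadata.
#' @return A `sparse_dictionary`.
#' @export
sparse_dictionary <- function(D, T0, error_trace = numeric(), seed = NA_integer_,
                              n_iters = length(error_trace)) {
  D <- as.matrix(D)
  nrm <- sqrt(colSums(D^2))
  if (any(abs(nrm - 1) > 1e-6)) stop("dictionary atoms must have unit norm")
  structure(list(D = D, N = nrow(D), M = ncol(D), T0 = as.integer(T0),
                 error_trace = error_trace, seed = seed,
                 n_iters = as.integer(n_iters)),
            class = "sparse_dictionary")
}

#' @export
print.sparse_dictionary <- function(x, ...) {
  cat(sprintf("<sparse_dictionary> %d x %d (%s), T0 = %d, %d iteration(s)\n",
              x$N, x$M, if (x$M < x$N) "undercomplete" else "overcomplete",
              x$T0, x$n_iters))
  if (length(x$error_trace))
    cat(sprintf("  final ||Y - DX||_F = %.6g\n",
                x$error_trace[[length(x$error_trace)]]))
  invisible(x)
}

dict_matrix <- function(D) {
  if (inherits(D, "sparse_dictionary")) D$D else as.matrix(D)
}

#' Orthogonal matching pursuit sparse coding
#'
#' Greedy selection of the atom with maximal absolute correlation with the
#' residual (ties to the lowest atom index), least-squares refit on the
#' support after each selection, stopping at `T0` atoms or residual norm
#' `<= tol`. A zero input yields an empty support.
#'
#' @param D A [sparse_dictionary()] or unit-norm atom matrix.
#' @param x Signal vector of length `N`, or an `N x n` matrix of signals.
#' @param T0 Maximum number of nonzero coefficients.
#' @param tol Residual-norm stopping tolerance (default 0).
#' @return For a vector input, a `sparse_code` (fields `alpha`, `support`,
#'   `residual_norm`); for a matrix input, a list with the `M x n`
#'   coefficient matrix `alpha` and `residual_norm` per signal.
#' @export
omp_encode <- function(D, x, T0, tol = 0) {
  Dm <- dict_matrix(D)
  nrm <- sqrt(colSums(Dm^2))
  if (any(abs(nrm - 1) > 1e-6)) stop("dictionary atoms must have unit norm")
  if (T0 < 1L) stop("T0 must be >= 1")
  single <- is.null(dim(x))
  X <- if (single) matrix(x, ncol = 1L) else as.matrix(x)
  if (nrow(X) != nrow(Dm)) stop("signal dimension does not match the dictionary")
  out <- omp_encode_cpp(Dm, X, as.integer(min(T0, ncol(Dm))), tol)
  if (single) {
    alpha <- out$alpha[, 1L]
    structure(list(alpha = alpha, support = which(alpha != 0),
                   residual_norm = out$residual_norm[[1L]]),
              class = "sparse_code")
  } else {
    out
  }
}

#' Single K-SVD atom update
#'
#' Restricted residual `E_Rk` of atom `k` over the signals that use it,
#' replaced by its best rank-1 approximation: the updated atom is the
#' first left singular vector and the updated coefficients are the first
#' right singular vector scaled by the leading singular value. The sign is
#' fixed by making the largest-magnitude atom entry positive.
#'
#' @param Y Signal matrix `[N x n]`.
#' @param D Current dictionary `[N x M]`.
#' @param X Current coefficient matrix `[M x n]`.
#' @param k Atom index to update.
#' @return List with `d` (updated atom), `x_r` (updated coefficients over
#'   `omega`), and `omega` (indices of signals using atom `k`); or
#'   `NULL` if no signal uses the atom.
#' @export
ksvd_atom_update <- function(Y, D, X, k) {
  omega <- which(X[k, ] != 0)
  if (length(omega) == 0L) return(NULL)
  Ek <- Y[, omega, drop = FALSE] -
    D[, -k, drop = FALSE] %*% X[-k, omega, drop = FALSE]
  sv <- svd(Ek, nu = 1L, nv = 1L)
  d <- sv$u[, 1L]
  xr <- sv$v[, 1L] * sv$d[[1L]]
  if (d[[which.max(abs(d))]] < 0) { d <- -d; xr <- -xr }
  list(d = d, x_r = xr, omega = omega)
}

#' Learn an undercomplete dictionary by K-SVD
#'
#' Alternates OMP sparse coding of all training signals with
#' column-by-column rank-1 SVD atom updates. The dictionary is initialized
#' from `M` distinct random training columns (seeded, normalized); unused
#' or duplicate atoms are replaced by the worst-reconstructed training
#' signal. Iteration stops at `max_iters` or when the relative Frobenius
#' error improvement falls below `tol`.
#'
#' The coding stage is monotone: greedy OMP can occasionally pick a worse
#' support for a signal than the one it already has, so a signal's previous
#' coefficients are kept whenever they give a smaller residual under the
#' current dictionary. Together with the Eckart-Young atom updates this
#' makes the recorded error trace non-increasing.
#'
#' Like other alternating minimizations (k-means being the familiar
#' example), K-SVD is sensitive to its random initialization when the
#' training set is modest: `n_restarts` seeded initializations are run and
#' the dictionary with the smallest final training error is returned.
#'
#' @param Y Training signal matrix `[N x n_train]`, `n_train >= M`.
#' @param M Number of atoms.
#' @param T0 OMP sparsity level (default 5).
#' @param max_iters Maximum alternations (default 50).
#' @param tol Relative-improvement stopping threshold (default 1e-4).
#' @param seed RNG seed for the initialization.
#' @param n_restarts Number of seeded initializations; the best final
#'   training error wins (default 5).
#' @return A [sparse_dictionary()].
#' @export
ksvd_learn <- function(Y, M, T0 = 5L, max_iters = 50L, tol = 1e-4,
                       seed = 1L, n_restarts = 5L) {
  best <- NULL
  for (r in seq_len(max(1L, n_restarts))) {
    dict <- ksvd_learn_once(Y, M, T0, max_iters, tol,
                            seed + (r - 1L) * 7919L)
    err <- if (length(dict$error_trace))
      dict$error_trace[[length(dict$error_trace)]] else Inf
    if (is.null(best) || err < best$final_err) {
      best <- dict
      best$final_err <- err
    }
    if (max_iters == 0L) break   # all restarts return their initialization
  }
  best$final_err <- NULL
  best$seed <- seed
  best
}

ksvd_learn_once <- function(Y, M, T0, max_iters, tol, seed) {
  Y <- as.matrix(Y)
  n <- ncol(Y)
  if (n < M) stop("need at least M training signals (", n, " < ", M, ")")
  set.seed(seed)
  norms <- sqrt(colSums(Y^2))
  cand <- which(norms > 0)
  if (length(cand) < M) stop("fewer than M nonzero training signals")
  init <- cand[sample.int(length(cand), M)]
  D <- sweep(Y[, init, drop = FALSE], 2L, norms[init], "/")
  trace <- numeric()
  X <- NULL
  prev_resid <- NULL
  for (it in seq_len(max_iters)) {
    code <- omp_encode_cpp(D, Y, as.integer(min(T0, M)), 0)
    new_resid <- code$residual_norm
    if (!is.null(prev_resid)) {
      # monotone coding: keep a signal's previous code when re-coding with
      # the same dictionary worsens its residual
      keep <- prev_resid < new_resid - 1e-12
      if (any(keep)) {
        code$alpha[, keep] <- X[, keep]
        new_resid[keep] <- prev_resid[keep]
      }
    }
    X <- code$alpha
    resid2 <- new_resid^2
    for (k in seq_len(M)) {
      upd <- ksvd_atom_update(Y, D, X, k)
      if (is.null(upd) || is_duplicate_atom(D, k)) {
        # replace an unused/duplicate atom with the worst-reconstructed
        # signal; its coefficient row stays zero, so the objective is
        # unchanged by the replacement itself
        worst <- which.max(resid2)
        w <- Y[, worst]
        D[, k] <- w / sqrt(sum(w^2))
        X[k, ] <- 0
      } else {
        D[, k] <- upd$d
        X[k, upd$omega] <- upd$x_r
      }
    }
    R <- Y - D %*% X
    prev_resid <- sqrt(colSums(R^2))
    err <- sqrt(sum(prev_resid^2))
    trace <- c(trace, err)
    if (it >= 2L) {
      prev <- trace[[it - 1L]]
      if (prev <= .Machine$double.eps || (prev - err) / prev < tol) break
    }
  }
  sparse_dictionary(D, T0, trace, seed, n_iters = length(trace))
}

is_duplicate_atom <- function(D, k) {
  if (k == 1L) return(FALSE)
  any(abs(crossprod(D[, seq_len(k - 1L), drop = FALSE], D[, k])) > 1 - 1e-10)
}
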