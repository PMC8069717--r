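#' Fit a spectral regression discriminant analysis (SRDA) classifier
#'
#' SRDA solves the LDA graph embedding by regression: the `c - 1`
#' orthogonalized class-indicator vectors are taken as spectral targets and
#' each is fit by ridge regression on the centered features. Prediction is
#' by nearest class centroid in the projected space.
#'
#' @param X Numeric matrix `[n x d]` (or a [feature_matrix()], in which
#'   case `y` defaults to its labels).
#' @param y Class labels (at least 2 classes).
#' @param reg_alpha Ridge penalty (default 0.01).
#' @return An object of class `srda_model`.
#' @export
srda_fit <- function(X, y = NULL, reg_alpha = 0.01) {
  if (inherits(X, "feature_matrix")) {
    if (is.null(y)) y <- X$labels
    X <- X$values
  }
  X <- as.matrix(X)
  classes <- sort(unique(y))
  nc <- length(classes)
  if (nc < 2L) stop("SRDA requires at least 2 classes")
  if (nrow(X) < nc) stop("need at least as many samples as classes")
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  train_mean <- colMeans(X)
  Xc <- sweep(X, 2L, train_mean)
  # orthonormal spectral targets: span of the class indicators, with the
  # constant vector removed
  E <- outer(y, classes, FUN = function(a, b) as.numeric(a == b))
  Q <- qr.Q(qr(cbind(1, E)))
  R <- Q[, 2L:nc, drop = FALSE]
  G <- crossprod(Xc) + diag(reg_alpha, ncol(Xc))
  W <- solve(G, crossprod(Xc, R))
  Z <- Xc %*% W
  centroids <- do.call(rbind, lapply(classes, function(cl)
    colMeans(Z[y == cl, , drop = FALSE])))
  rownames(centroids) <- as.character(classes)
  structure(list(projection = W, centroids = centroids, classes = classes,
                 reg_alpha = reg_alpha, train_mean = train_mean),
            class = "srda_model")
}

#' @export
print.srda_model <- function(x, ...) {
  cat(sprintf("<srda_model> %d features -> %d projection(s), %d classes, ridge alpha = %g\n",
              nrow(x$projection), ncol(x$projection), length(x$classes),
              x$reg_alpha))
  invisible(x)
}

#' Predict class labels with a fitted SRDA model
#'
#' @param model An [srda_fit()] result.
#' @param X Numeric matrix with the training dimensionality (or a
#'   [feature_matrix()]).
#' @return Vector of predicted labels; centroid-distance ties go to the
#'   lower class label.
#' @export
srda_predict <- function(model, X) {
  stopifnot(inherits(model, "srda_model"))
  if (inherits(X, "feature_matrix")) X <- X$values
  X <- as.matrix(X)
  if (ncol(X) != nrow(model$projection))
    stop("feature dimension ", ncol(X), " does not match training dimension ",
         nrow(model$projection))
  Z <- sweep(X, 2L, model$train_mean) %*% model$projection
  d2 <- outer(rowSums(Z^2), rowSums(model$centroids^2), "+") -
    2 * tcrossprod(Z, model$centroids)
  # classes are stored sorted, so which.min's first-minimum rule breaks
  # ties toward the lower label
  model$classes[apply(round(d2, 12L), 1L, which.min)]
}

#' Classification metrics for binary fatigue detection
#'
#' Accuracy, precision and F1 for the positive (fatigue = 1) class, or
#' macro-averaged over classes.
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @param positive The positive class (default 1).
#' @param macro Macro-average precision/F1 over all classes (default FALSE).
#' @return Named list `accuracy`, `precision`, `f1`.
#' @export
evaluate_predictions <- function(y_true, y_pred, positive = 1L,
                                 macro = FALSE) {
  if (length(y_true) == 0L) stop("empty input")
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  acc <- mean(y_true == y_pred)
  one_class <- function(pos) {
    tp <- sum(y_true == pos & y_pred == pos)
    fp <- sum(y_true != pos & y_pred == pos)
    fn <- sum(y_true == pos & y_pred != pos)
    prec <- if (tp + fp == 0) {
      warning("no predictions for class ", pos, "; precision reported as 0")
      0
    } else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    c(precision = prec, f1 = f1)
  }
  if (macro) {
    per <- vapply(sort(unique(y_true)), one_class, c(precision = 0, f1 = 0))
    list(accuracy = acc, precision = mean(per["precision", ]),
         f1 = mean(per["f1", ]))
  } else {
    m <- one_class(positive)
    list(accuracy = acc, precision = unname(m[["precision"]]),
         f1 = unname(m[["f1"]]))
  }
}

#' Serialize an SRDA model to JSON
#'
#' @param model An `srda_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_srda_model <- function(model, path) {
  stopifnot(inherits(model, "srda_model"))
  jsonlite::write_json(list(projection = model$projection,
                            centroids = model$centroids,
                            classes = model$classes,
                            reg_alpha = model$reg_alpha,
                            train_mean = model$train_mean),
                       path, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' Read an SRDA model written by [write_srda_model()]
#'
#' @param path JSON path.
#' @return An `srda_model`.
#' @export
read_srda_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(projection = as.matrix(j$projection),
                 centroids = as.matrix(j$centroids),
                 classes = j$classes, reg_alpha = j$reg_alpha,
                 train_mean = j$train_mean),
            class = "srda_model")
}
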