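#' Epochs-by-features table
#'
#' Each column of the table is one (channel, feature-type) pair; this is
#' the unit that ReliefF weighs and the classifier consumes. With 16
#' channels and all five feature types the table has 80 columns.
#'
#' @param values Numeric matrix `[n_epochs x n_columns]`, all finite.
#' @param channels Character vector: channel label of each column.
#' @param features Character vector: feature name of each column.
#' @param labels Binary epoch labels.
#' @param subject_ids Subject id of each epoch.
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, channels, features, labels, subject_ids) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!all(is.finite(values))) stop("feature values must all be finite")
  channels <- as.character(channels); features <- as.character(features)
  if (length(channels) != ncol(values) || length(features) != ncol(values))
    stop("channels/features must have one entry per column")
  if (anyDuplicated(paste(channels, features, sep = "\r")))
    stop("duplicate (channel, feature) columns")
  labels <- as.integer(labels)
  if (length(labels) != nrow(values) || length(subject_ids) != nrow(values))
    stop("labels/subject_ids must have one entry per row")
  colnames(values) <- paste(channels, features, sep = ".")
  structure(list(values = values, channels = channels, features = features,
                 labels = labels, subject_ids = as.character(subject_ids)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d epochs x %d columns (%d channels x %d feature types)\n",
              nrow(x$values), ncol(x$values), length(unique(x$channels)),
              length(unique(x$features))))
  cat("  features:", paste(unique(x$features), collapse = ", "), "\n")
  cat(sprintf("  labels: %d pre-fatigue, %d fatigue; subjects: %s\n",
              sum(x$labels == 0L), sum(x$labels == 1L),
              paste(unique(x$subject_ids), collapse = ", ")))
  invisible(x)
}

#' Restrict a feature matrix to given channels and/or features
#'
#' @param x A [feature_matrix()].
#' @param channels,features Labels to keep (default: all).
#' @param rows Optional epoch (row) indices to keep.
#' @return A [feature_matrix()] with the selected columns/rows.
#' @export
subset_features <- function(x, channels = NULL, features = NULL, rows = NULL) {
  stopifnot(inherits(x, "feature_matrix"))
  keep <- rep(TRUE, ncol(x$values))
  if (!is.null(channels)) keep <- keep & x$channels %in% channels
  if (!is.null(features)) keep <- keep & x$features %in% features
  if (!any(keep)) stop("no columns left after subsetting")
  if (is.null(rows)) rows <- seq_len(nrow(x$values))
  feature_matrix(x$values[rows, keep, drop = FALSE], x$channels[keep],
                 x$features[keep], x$labels[rows], x$subject_ids[rows])
}

#' Write a feature matrix as CSV plus JSON sidecar
#'
#' The CSV has a two-row header (channel labels, then feature names); the
#' sidecar stores epoch labels and subject ids.
#'
#' @param x A [feature_matrix()].
#' @param path CSV path; the sidecar is written next to it as `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(x, path) {
  stopifnot(inherits(x, "feature_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(x$channels, collapse = ","), con)
  writeLines(paste(x$features, collapse = ","), con)
  for (i in seq_len(nrow(x$values)))
    writeLines(paste(formatC(x$values[i, ], format = "g", digits = 17),
                     collapse = ","), con)
  jsonlite::write_json(list(labels = x$labels, subject_ids = x$subject_ids),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path CSV path (expects `<path>.json` sidecar).
#' @return A [feature_matrix()].
#' @export
read_feature_matrix <- function(path) {
  lines <- readLines(path)
  channels <- trimws(strsplit(lines[[1L]], ",", fixed = TRUE)[[1L]])
  features <- trimws(strsplit(lines[[2L]], ",", fixed = TRUE)[[1L]])
  vals <- do.call(rbind, lapply(lines[-(1:2)], function(r)
    as.numeric(strsplit(r, ",", fixed = TRUE)[[1L]])))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  feature_matrix(vals, channels, features, meta$labels, meta$subject_ids)
}
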