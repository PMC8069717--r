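#' Set of fixed-length labeled epochs
#'
#' @param epochs Numeric array `[n_epochs x n_channels x epoch_samples]`.
#' @param labels Integer vector of binary state labels, one per epoch.
#' @param subject_ids Character vector, one per epoch.
#' @param fs Sampling rate in Hz.
#' @param epoch_len Epoch length in seconds.
#' @param overlap Overlap between consecutive epochs in seconds.
#' @param channel_labels Channel names.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(epochs, labels, subject_ids, fs, epoch_len, overlap,
                      channel_labels) {
  stopifnot(is.array(epochs), length(dim(epochs)) == 3L)
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary {0,1}")
  if (length(labels) != dim(epochs)[[1L]] ||
      length(subject_ids) != dim(epochs)[[1L]])
    stop("labels/subject_ids must have one entry per epoch")
  if (dim(epochs)[[3L]] != round(epoch_len * fs))
    stop("epoch_samples must equal round(epoch_len * fs)")
  if (length(channel_labels) != dim(epochs)[[2L]])
    stop("channel_labels must have one entry per channel")
  structure(list(epochs = epochs, labels = labels,
                 subject_ids = as.character(subject_ids), fs = fs,
                 epoch_len = epoch_len, overlap = overlap,
                 channel_labels = as.character(channel_labels)),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$epochs)
  cat(sprintf("<epoch_set> %d epochs x %d channels x %d samples @ %g Hz\n",
              d[1L], d[2L], d[3L], x$fs))
  cat(sprintf("  epoch_len %g s, overlap %g s; labels: %d pre-fatigue, %d fatigue\n",
              x$epoch_len, x$overlap, sum(x$labels == 0L), sum(x$labels == 1L)))
  invisible(x)
}

#' Cut a recording into fixed-length epochs
#'
#' Sliding windows with step `epoch_len - overlap`; a trailing partial
#' window is dropped. Every epoch inherits the recording's state label and
#' subject id. With `overlap = 0` the windows partition the used portion of
#' the signal.
#'
#' @param recording An [eeg_recording()].
#' @param epoch_len Window length in seconds (default 1).
#' @param overlap Overlap in seconds, `0 <= overlap < epoch_len`.
#' @return An [epoch_set()].
#' @export
segment <- function(recording, epoch_len = 1, overlap = 0) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (overlap < 0 || overlap >= epoch_len)
    stop("overlap must satisfy 0 <= overlap < epoch_len")
  fs <- recording$fs
  epoch_samples <- round(epoch_len * fs)
  step <- round((epoch_len - overlap) * fs)
  if (step < 1L) stop("epoch step must be at least one sample")
  n <- ncol(recording$signal)
  if (n < epoch_samples)
    stop("recording (", n / fs, " s) is shorter than one epoch (",
         epoch_len, " s)")
  starts <- seq.int(1L, n - epoch_samples + 1L, by = step)
  n_ep <- length(starts)
  n_ch <- nrow(recording$signal)
  ep <- array(0, dim = c(n_ep, n_ch, epoch_samples))
  for (i in seq_len(n_ep))
    ep[i, , ] <- recording$signal[, starts[[i]]:(starts[[i]] + epoch_samples - 1L)]
  epoch_set(ep, rep(recording$state, n_ep),
            rep(recording$subject_id, n_ep), fs, epoch_len, overlap,
            recording$channel_labels)
}

#' Concatenate epoch sets
#'
#' All sets must share sampling rate, epoch geometry, and channel labels.
#'
#' @param ... `epoch_set` objects (or a single list of them).
#' @return A combined [epoch_set()].
#' @export
bind_epoch_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && !inherits(sets[[1L]], "epoch_set"))
    sets <- sets[[1L]]
  stopifnot(length(sets) >= 1L, all(vapply(sets, inherits, TRUE, "epoch_set")))
  ref <- sets[[1L]]
  for (s in sets[-1L]) {
    if (s$fs != ref$fs || s$epoch_len != ref$epoch_len ||
        !identical(s$channel_labels, ref$channel_labels))
      stop("epoch sets are not compatible (fs/epoch_len/channels differ)")
  }
  n_tot <- sum(vapply(sets, function(s) dim(s$epochs)[[1L]], 0L))
  d <- dim(ref$epochs)
  ep <- array(0, dim = c(n_tot, d[2L], d[3L]))
  at <- 0L
  for (s in sets) {
    k <- dim(s$epochs)[[1L]]
    if (k > 0L) ep[at + seq_len(k), , ] <- s$epochs
    at <- at + k
  }
  epoch_set(ep, unlist(lapply(sets, `[[`, "labels")),
            unlist(lapply(sets, `[[`, "subject_ids")), ref$fs,
            ref$epoch_len, ref$overlap, ref$channel_labels)
}

#' Serialize an epoch set to a directory
#'
#' One CSV per channel (epochs as rows) plus a JSON metadata sidecar with
#' labels, subject ids and epoch geometry.
#'
#' @param epochs An [epoch_set()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_epoch_set <- function(epochs, dir) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (c in seq_along(epochs$channel_labels)) {
    utils::write.table(matrix(epochs$epochs[, c, ], nrow = dim(epochs$epochs)[[1L]]),
                       file.path(dir, sprintf("channel_%03d.csv", c)),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  meta <- list(labels = epochs$labels, subject_ids = epochs$subject_ids,
               fs = epochs$fs, epoch_len = epochs$epoch_len,
               overlap = epochs$overlap,
               channel_labels = epochs$channel_labels)
  jsonlite::write_json(meta, file.path(dir, "epochs.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read an epoch set written by [write_epoch_set()]
#'
#' @param dir Directory containing `channel_*.csv` and `epochs.json`.
#' @return An [epoch_set()].
#' @export
read_epoch_set <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "epochs.json"),
                              simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^channel_\\d+\\.csv$",
                           full.names = TRUE))
  if (length(files) != length(meta$channel_labels))
    stop("epoch set directory is incomplete")
  mats <- lapply(files, function(f)
    as.matrix(utils::read.csv(f, header = FALSE)))
  n_ep <- nrow(mats[[1L]]); n_sp <- ncol(mats[[1L]])
  ep <- array(0, dim = c(n_ep, length(mats), n_sp))
  for (c in seq_along(mats)) ep[, c, ] <- mats[[c]]
  epoch_set(ep, meta$labels, meta$subject_ids, meta$fs, meta$epoch_len,
            meta$overlap, meta$channel_labels)
}
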