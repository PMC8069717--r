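#' Multichannel EEG recording
#'
#' Container for one continuous recording of a single subject in a single
#' fatigue state. The signal is stored as a channels x samples matrix in
#' microvolts together with the sampling rate and ordered channel labels.
#'
#' @param signal Numeric matrix, channels x samples (microvolts).
#' @param fs Sampling rate in Hz (positive scalar).
#' @param channel_labels Character vector of unique channel names, one per
#'   row of `signal`. Defaults to `Ch1..Chn`.
#' @param subject_id Subject identifier.
#' @param state Binary state label: 0 = pre-fatigue, 1 = fatigue.
#'
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(signal, fs, channel_labels = NULL,
                          subject_id = "S1", state = 0L) {
  signal <- as.matrix(signal)
  storage.mode(signal) <- "double"
  if (nrow(signal) < 1L) stop("recording must have at least one channel")
  if (!all(is.finite(signal))) stop("signal contains non-finite values")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a positive finite scalar")
  if (is.null(channel_labels)) channel_labels <- paste0("Ch", seq_len(nrow(signal)))
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(signal))
    stop("channel_labels length must equal the number of channels")
  if (anyDuplicated(channel_labels))
    stop("channel_labels must be unique")
  state <- as.integer(state)
  if (!state %in% c(0L, 1L)) stop("state must be 0 (pre-fatigue) or 1 (fatigue)")
  structure(list(signal = signal, fs = fs, channel_labels = channel_labels,
                 subject_id = as.character(subject_id), state = state),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject %s, state %d (%s)\n", x$subject_id,
              x$state, if (x$state == 1L) "fatigue" else "pre-fatigue"))
  cat(sprintf("  %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$signal), ncol(x$signal), x$fs, ncol(x$signal) / x$fs))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  invisible(x)
}

#' Read an EEG recording from disk
#'
#' Supported formats: EDF (European Data Format, 16-bit) and a plain CSV
#' dialect for fixtures. The CSV dialect is: first line `fs=<Hz>`, second
#' line the comma-separated channel labels, and one row of samples per
#' channel thereafter. Values are returned unchanged (no filtering).
#'
#' @param path File path.
#' @param format `"edf"`, `"csv"`, or `"auto"` (by file extension).
#' @param subject_id,state Metadata attached to the returned recording.
#' @return An [eeg_recording()].
#' @export
load_recording <- function(path, format = c("auto", "csv", "edf"),
                           subject_id = "S1", state = 0L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read recording: no such file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "edf") "edf" else "csv"
  }
  if (format == "csv") {
    parsed <- read_recording_csv(path)
  } else {
    parsed <- read_edf(path)
  }
  eeg_recording(parsed$signal, parsed$fs, parsed$channel_labels,
                subject_id = subject_id, state = state)
}

read_recording_csv <- function(path) {
  header <- readLines(path, n = 2L)
  if (length(header) < 2L || !grepl("^\\s*fs\\s*=", header[[1L]]))
    stop("CSV recording format error: first line must be 'fs=<Hz>'")
  fs <- suppressWarnings(as.numeric(sub("^\\s*fs\\s*=", "", header[[1L]])))
  if (is.na(fs) || fs <= 0)
    stop("CSV recording format error: invalid sampling rate in header")
  labels <- trimws(strsplit(header[[2L]], ",", fixed = TRUE)[[1L]])
  rows <- readLines(path)[-(1:2)]
  rows <- rows[nzchar(trimws(rows))]
  if (length(rows) != length(labels))
    stop("CSV recording format error: ", length(labels),
         " channel labels but ", length(rows), " channel rows")
  sig <- lapply(rows, function(r) {
    v <- suppressWarnings(as.numeric(strsplit(r, ",", fixed = TRUE)[[1L]]))
    if (anyNA(v)) stop("CSV recording format error: non-numeric cell")
    v
  })
  if (length(unique(lengths(sig))) != 1L)
    stop("CSV recording format error: channels have unequal lengths")
  list(signal = do.call(rbind, sig), fs = fs, channel_labels = labels)
}

#' Write an EEG recording to disk
#'
#' @param recording An [eeg_recording()].
#' @param path Output file path.
#' @param format `"csv"` (lossless) or `"edf"` (16-bit quantized).
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path, format = c("csv", "edf")) {
  stopifnot(inherits(recording, "eeg_recording"))
  format <- match.arg(format)
  if (format == "csv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("fs=%.10g", recording$fs), con)
    writeLines(paste(recording$channel_labels, collapse = ","), con)
    for (i in seq_len(nrow(recording$signal)))
      writeLines(paste(formatC(recording$signal[i, ], format = "g",
                               digits = 17),
                       collapse = ","), con)
  } else {
    write_edf(recording, path)
  }
  invisible(path)
}
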