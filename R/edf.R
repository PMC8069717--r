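# Minimal EDF (European Data Format) support: 16-bit integer storage with
# per-signal physical/digital scaling, one-second data records. Covers the
# subset of the format produced by standard EEG acquisition software;
# signals with differing per-channel sampling rates are rejected because a
# recording matrix requires a common rate.

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = width, flag = "-")
}

write_edf <- function(recording, path) {
  sig <- recording$signal
  fs <- recording$fs
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF writer supports integer sampling rates only")
  fs <- as.integer(round(fs))
  ns <- nrow(sig)
  spr <- fs                      # one-second data records
  n_rec <- ceiling(ncol(sig) / spr)
  if (n_rec * spr > ncol(sig)) { # pad the trailing partial record
    pad <- n_rec * spr - ncol(sig)
    sig <- cbind(sig, sig[, rep(ncol(sig), pad), drop = FALSE])
  }
  pmin <- apply(sig, 1L, min)
  pmax <- apply(sig, 1L, max)
  flat <- pmax <= pmin
  pmax[flat] <- pmin[flat] + 1
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr_bytes <- 256L + 256L * ns
  writeChar(paste0(
    edf_pad("0", 8L),
    edf_pad(recording$subject_id, 80L),
    edf_pad(sprintf("state %d", recording$state), 80L),
    edf_pad("01.01.26", 8L),
    edf_pad("00.00.00", 8L),
    edf_pad(hdr_bytes, 8L),
    edf_pad("", 44L),
    edf_pad(n_rec, 8L),
    edf_pad("1", 8L),
    edf_pad(ns, 4L)), con, eos = NULL)
  fields <- list(
    c(recording$channel_labels, 16L),
    c(rep("", ns), 80L),
    c(rep("uV", ns), 8L),
    c(formatC(pmin, format = "g", digits = 7), 8L),
    c(formatC(pmax, format = "g", digits = 7), 8L),
    c(rep(dmin, ns), 8L),
    c(rep(dmax, ns), 8L),
    c(rep("", ns), 80L),
    c(rep(spr, ns), 8L),
    c(rep("", ns), 32L))
  for (f in fields) {
    width <- as.integer(f[[length(f)]])
    vals <- f[-length(f)]
    writeChar(paste(edf_pad(vals, width), collapse = ""), con, eos = NULL)
  }
  # re-read the physical min/max exactly as a reader will parse them, so
  # quantization error is bounded by the digital step
  pmin_r <- as.numeric(formatC(pmin, format = "g", digits = 7))
  pmax_r <- as.numeric(formatC(pmax, format = "g", digits = 7))
  scale <- (dmax - dmin) / (pmax_r - pmin_r)
  dig <- round((sig - pmin_r) * scale) + dmin
  dig[dig > dmax] <- dmax
  dig[dig < dmin] <- dmin
  storage.mode(dig) <- "integer"
  for (rec in seq_len(n_rec)) {
    cols <- ((rec - 1L) * spr + 1L):(rec * spr)
    writeBin(as.integer(t(dig[, cols, drop = FALSE])[seq_len(spr * ns)]),
             con, size = 2L, endian = "little")
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  num <- function(s) {
    v <- suppressWarnings(as.numeric(trimws(s)))
    if (is.na(v)) stop("EDF format error: non-numeric header field")
    v
  }
  rd(8L)                               # version
  rd(80L); rd(80L); rd(8L); rd(8L)     # ids, date, time
  rd(8L)                               # header bytes
  rd(44L)
  n_rec <- as.integer(num(rd(8L)))
  rec_dur <- num(rd(8L))
  ns <- as.integer(num(rd(4L)))
  if (ns < 1L) stop("EDF format error: no signals")
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16L), ""))
  for (i in seq_len(ns)) rd(80L)       # transducer
  for (i in seq_len(ns)) rd(8L)        # physical dimension
  pmin <- vapply(seq_len(ns), function(i) num(rd(8L)), 0)
  pmax <- vapply(seq_len(ns), function(i) num(rd(8L)), 0)
  dmin <- vapply(seq_len(ns), function(i) num(rd(8L)), 0)
  dmax <- vapply(seq_len(ns), function(i) num(rd(8L)), 0)
  for (i in seq_len(ns)) rd(80L)       # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(num(rd(8L))), 0L)
  for (i in seq_len(ns)) rd(32L)
  if (length(unique(spr)) != 1L)
    stop("EDF format error: mismatched per-channel sampling rates (",
         paste(unique(spr), collapse = ", "), " samples/record)")
  spr <- spr[[1L]]
  if (rec_dur <= 0) stop("EDF format error: non-positive record duration")
  fs <- spr / rec_dur
  sig <- matrix(0, ns, n_rec * spr)
  scale <- (pmax - pmin) / (dmax - dmin)
  for (rec in seq_len(n_rec)) {
    raw <- readBin(con, "integer", n = spr * ns, size = 2L, signed = TRUE,
                   endian = "little")
    if (length(raw) < spr * ns) stop("EDF format error: truncated data record")
    block <- matrix(raw, nrow = spr, ncol = ns)
    cols <- ((rec - 1L) * spr + 1L):(rec * spr)
    sig[, cols] <- t(block) * scale + (pmin - dmin * scale)
  }
  list(signal = sig, fs = fs, channel_labels = labels)
}
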