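# The five per-channel epoch features: Welch band power in the four
# canonical EEG bands (beta 12-30, alpha 8-12, theta 4-8, delta 0.5-4 Hz,
# log10 scale) and sample entropy.

feature_names_canonical <- function() {
  c("psd_beta", "psd_alpha", "psd_theta", "psd_delta", "sampen")
}

feature_band <- function(name) {
  switch(name,
         psd_beta  = c(12, 30),
         psd_alpha = c(8, 12),
         psd_theta = c(4, 8),
         psd_delta = c(0.5, 4),
         stop("unknown PSD feature: ", name))
}

#' Welch power spectral density estimate
#'
#' Hamming-windowed, linearly detrended segments of length
#' `min(length(x), fs)` with 50% overlap, averaged one-sided periodograms.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate in Hz.
#' @param seg_len Segment length in samples (default `min(length(x), fs)`).
#' @param overlap Fractional segment overlap in `[0, 1)` (default 0.5).
#' @param detrend Remove a linear trend per segment (default TRUE).
#' @return List with `freq` (Hz) and `psd` (power per Hz).
#' @export
welch_psd <- function(x, fs, seg_len = NULL, overlap = 0.5, detrend = TRUE) {
  out <- welch_psd_matrix(matrix(x, nrow = 1L), fs, seg_len, overlap, detrend)
  list(freq = out$freq, psd = out$psd[1L, ])
}

# Welch PSD for many equal-length series at once (rows of X); the batch
# path feature extraction uses. Returns psd as [nrow(X) x n_freq].
welch_psd_matrix <- function(X, fs, seg_len = NULL, overlap = 0.5,
                             detrend = TRUE) {
  n <- ncol(X)
  if (is.null(seg_len)) seg_len <- min(n, round(fs))
  seg_len <- as.integer(seg_len)
  if (seg_len < 8L) stop("Welch segment too short (", seg_len, " samples)")
  if (n < seg_len) stop("series shorter than one Welch segment")
  step <- max(1L, as.integer(floor(seg_len * (1 - overlap))))
  starts <- seq.int(1L, n - seg_len + 1L, by = step)
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(seg_len) - 1L) / (seg_len - 1L))
  u <- sum(w^2)
  half <- floor(seg_len / 2L)
  freq <- (0:half) * fs / seg_len
  tc <- seq_len(seg_len) - (seg_len + 1) / 2
  stt <- sum(tc^2)
  acc <- matrix(0, nrow(X), half + 1L)
  for (s in starts) {
    S <- X[, s:(s + seg_len - 1L), drop = FALSE]
    if (detrend) {
      slope <- (S %*% tc) / stt
      S <- S - rowMeans(S) - slope %*% t(tc)
    }
    Fc <- stats::mvfft(t(S * rep(w, each = nrow(S))))
    P <- (Mod(Fc[seq_len(half + 1L), , drop = FALSE])^2) / (fs * u)
    P[2:(half + 1L - (seg_len %% 2L == 0L)), ] <-
      2 * P[2:(half + 1L - (seg_len %% 2L == 0L)), , drop = FALSE]
    acc <- acc + t(P)
  }
  list(freq = freq, psd = acc / length(starts))
}

# trapezoid integral of psd over the grid points inside [lo, hi]
band_integral <- function(freq, psd_row, lo, hi) {
  sel <- which(freq >= lo - 1e-9 & freq <= hi + 1e-9)
  if (length(sel) < 2L)
    stop("band [", lo, ", ", hi, "] Hz is narrower than the frequency resolution")
  f <- freq[sel]
  if (is.matrix(psd_row)) {
    p1 <- psd_row[, sel[-1L], drop = FALSE]
    p0 <- psd_row[, sel[-length(sel)], drop = FALSE]
    as.numeric((p1 + p0) %*% (diff(f) / 2))
  } else {
    sum(diff(f) * (psd_row[sel][-1L] + psd_row[sel][-length(sel)]) / 2)
  }
}

#' Band power of a series (log10 scale)
#'
#' Welch PSD integrated over `[f_lo, f_hi]` by the trapezoid rule on the
#' frequency grid, returned as `log10(power + 1e-12)`.
#'
#' @param series Numeric vector.
#' @param fs Sampling rate in Hz.
#' @param band Length-2 numeric `c(f_lo, f_hi)` in Hz, `f_hi <= fs/2`.
#' @param ... Passed to [welch_psd()].
#' @return Scalar log10 band power.
#' @export
band_psd <- function(series, fs, band, ...) {
  if (length(band) != 2L || band[[1L]] < 0 || band[[2L]] <= band[[1L]])
    stop("band must be c(f_lo, f_hi) with 0 <= f_lo < f_hi")
  if (band[[2L]] > fs / 2 + 1e-9)
    stop("band upper edge ", band[[2L]], " Hz exceeds the Nyquist frequency ",
         fs / 2, " Hz")
  out <- welch_psd(series, fs, ...)
  log10(band_integral(out$freq, out$psd, band[[1L]], band[[2L]]) + 1e-12)
}

#' Sample entropy of a series
#'
#' Richman-Moorman sample entropy: `-ln(A/B)` where `B` counts pairs of
#' length-`m` templates within Chebyshev distance `r` (self-matches
#' excluded) and `A` counts those pairs that still match when extended to
#' length `m + 1`. If no extended match exists (`A = 0`) the finite
#' surrogate `-ln(1/(B+1))` is returned instead of infinity.
#'
#' @param series Numeric vector, length at least `m + 2`.
#' @param m Embedding dimension (default 2).
#' @param r Tolerance, in the units of `series` (default `0.2 * sd(series)`).
#' @param warn Warn when the `A = 0` fallback is used (default TRUE).
#' @return Scalar sample entropy.
#' @export
sample_entropy <- function(series, m = 2L, r = 0.2 * stats::sd(series),
                           warn = TRUE) {
  series <- as.numeric(series)
  if (length(series) < m + 2L)
    stop("series too short for sample entropy (need at least m + 2 samples)")
  if (!is.finite(r) || r <= 0) stop("tolerance r must be positive")
  cnt <- sampen_counts(series, as.integer(m), r)
  if (cnt$B == 0) return(0)
  if (cnt$A == 0) {
    if (warn) warning("no (m+1)-template matches; returning -ln(1/(B+1))")
    return(-log(1 / (cnt$B + 1)))
  }
  -log(cnt$A / cnt$B)
}

#' Extract per-channel epoch features
#'
#' One column per (channel, feature) pair, channels-major, with the
#' feature order fixed as beta, alpha, theta, delta band power then sample
#' entropy. Epoch labels and subject ids are carried through.
#'
#' @param epochs An [epoch_set()].
#' @param features Subset of
#'   `c("psd_beta", "psd_alpha", "psd_theta", "psd_delta", "sampen")`.
#' @param m,r_factor Sample-entropy embedding dimension and tolerance
#'   factor (`r = r_factor * sd(epoch)` per epoch and channel).
#' @param seg_len,overlap Welch parameters (see [welch_psd()]).
#' @return A [feature_matrix()].
#' @export
extract_features <- function(epochs, features = feature_names_canonical(),
                             m = 2L, r_factor = 0.2,
                             seg_len = NULL, overlap = 0.5) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (length(features) == 0L) stop("feature_spec must be non-empty")
  unknown <- setdiff(features, feature_names_canonical())
  if (length(unknown))
    stop("unknown feature name(s): ", paste(unknown, collapse = ", "))
  features <- intersect(feature_names_canonical(), features)
  n_ep <- dim(epochs$epochs)[[1L]]
  n_ch <- dim(epochs$epochs)[[2L]]
  psd_feats <- setdiff(features, "sampen")
  cols <- list(); chs <- character(); fts <- character()
  for (ch in seq_len(n_ch)) {
    E <- matrix(epochs$epochs[, ch, ], nrow = n_ep)
    psd <- if (length(psd_feats))
      welch_psd_matrix(E, epochs$fs, seg_len, overlap) else NULL
    for (f in features) {
      v <- if (f == "sampen") {
        vapply(seq_len(n_ep), function(i) {
          x <- E[i, ]
          s <- stats::sd(x)
          if (s == 0) 0 else sample_entropy(x, m = m, r = r_factor * s,
                                            warn = FALSE)
        }, 0)
      } else {
        b <- feature_band(f)
        log10(band_integral(psd$freq, psd$psd, b[[1L]], b[[2L]]) + 1e-12)
      }
      cols[[length(cols) + 1L]] <- v
      chs <- c(chs, epochs$channel_labels[[ch]])
      fts <- c(fts, f)
    }
  }
  feature_matrix(do.call(cbind, cols), chs, fts, epochs$labels,
                 epochs$subject_ids)
}
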