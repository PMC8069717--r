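#' Configuration for the synthetic EEG cohort generator
#'
#' The generator emulates the study design the package targets: a cohort of
#' subjects each recorded for two minutes in a pre-fatigue and a fatigue
#' state at 500 Hz over 16 channels, with a known subset of channels
#' carrying state-dependent band-power and signal-complexity differences.
#' In the fatigue state the informative channels gain alpha and theta power
#' and lose beta power (the classical drowsiness signature), and an AR(1)
#' smoothing of their broadband noise lowers sample entropy without
#' changing the noise variance. Non-informative channels are drawn from the
#' same distribution in both states.
#'
#' @param n_subjects Number of subjects (default 8).
#' @param n_channels Number of channels (default 16).
#' @param fs Sampling rate in Hz (default 500).
#' @param duration_per_state Seconds of signal per state (default 120).
#' @param informative_channels Indices (1-based) of channels carrying the
#'   state effect (default `1:6`).
#' @param band_effects Named multiplicative power changes applied to the
#'   informative channels' band components in the fatigue state.
#' @param entropy_effect Additive increase of the broadband-noise AR(1)
#'   coefficient on informative channels in the fatigue state
#'   (default 0.1: 0.3 in pre-fatigue, 0.4 in fatigue, calibrated so that
#'   sample entropy alone separates the states about as well as the best
#'   single features reported for real fatigue EEG rather than perfectly).
#' @param subject_variability SD of the per-subject lognormal jitter
#'   applied to the (log) effect sizes (default 0.1).
#' @param seed Integer RNG seed.
#' @return A `synth_cohort_config` list.
#' @export
synth_cohort_config <- function(n_subjects = 8L, n_channels = 16L, fs = 500,
                                duration_per_state = 120,
                                informative_channels = 1:6,
                                band_effects = c(delta = 1.0, theta = 1.5,
                                                 alpha = 1.8, beta = 0.6),
                                entropy_effect = 0.1,
                                subject_variability = 0.1, seed = 1L) {
  if (!all(informative_channels %in% seq_len(n_channels)))
    stop("informative_channels must be a subset of 1..n_channels")
  bands <- c("delta", "theta", "alpha", "beta")
  eff <- c(delta = 1.0, theta = 1.0, alpha = 1.0, beta = 1.0)
  eff[names(band_effects)] <- band_effects
  if (any(eff <= 0)) stop("band_effects multipliers must be positive")
  if (!setequal(names(eff), bands)) stop("unknown band in band_effects")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_channels = as.integer(n_channels), fs = fs,
                 duration_per_state = duration_per_state,
                 informative_channels = as.integer(informative_channels),
                 band_effects = eff[bands], entropy_effect = entropy_effect,
                 subject_variability = subject_variability,
                 seed = as.integer(seed)),
            class = "synth_cohort_config")
}

# canonical EEG band edges in Hz
eeg_bands <- function() {
  list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 12), beta = c(12, 30))
}

# band-limited Gaussian noise: white noise through an order-501 Hamming FIR
# bandpass (FFT convolution), burn-in dropped, rescaled to unit sd.
# Generates n_ch independent channels at once (columns).
band_noise <- function(n, fs, band, n_ch = 1L, order = 501L) {
  burn <- order + 100L
  b <- signal::fir1(order, band / (fs / 2), type = "pass")
  fft_filter(matrix(stats::rnorm((n + burn) * n_ch), ncol = n_ch), b,
             burn, n)
}

# overlap-free FFT convolution of every column of W with coefficients b;
# rows burn+1..burn+n of the filter() -style output, unit-sd columns
fft_filter <- function(W, b, burn, n) {
  ntot <- nrow(W)
  nfft <- stats::nextn(ntot + length(b) - 1L, 2L)
  B <- stats::fft(c(b, numeric(nfft - length(b))))
  Wp <- rbind(W, matrix(0, nfft - ntot, ncol(W)))
  Y <- Re(stats::mvfft(stats::mvfft(Wp) * B, inverse = TRUE)) / nfft
  Y <- Y[(burn + 1L):(burn + n), , drop = FALSE]
  sweep(Y, 2L, apply(Y, 2L, stats::sd), "/")
}

# pink (1/f power) noise via frequency-domain shaping, unit-sd columns
pink_noise <- function(n, fs, n_ch = 1L, f_floor = 1.0) {
  W <- matrix(stats::rnorm(n * n_ch), ncol = n_ch)
  X <- stats::mvfft(W)
  f <- (seq_len(n) - 1L) * fs / n
  f_fold <- pmin(f, fs - f)         # two-sided frequency axis
  amp <- 1 / sqrt(pmax(f_fold, f_floor))
  amp[1L] <- 0                      # no DC
  Y <- Re(stats::mvfft(X * amp, inverse = TRUE)) / n
  sweep(Y, 2L, apply(Y, 2L, stats::sd), "/")
}

# first-order autoregressive smoothing, variance-renormalized
ar1_smooth <- function(x, phi) {
  if (phi <= 0) return(x / stats::sd(x))
  y <- as.numeric(stats::filter(x, phi, method = "recursive"))
  y / stats::sd(y)
}

#' Generate a synthetic EEG cohort with known informative channels
#'
#' Each channel is a sum of four band-limited Gaussian processes (delta,
#' theta, alpha, beta) plus AR(1)-smoothed pink broadband noise. See
#' [synth_cohort_config()] for the state manipulation. Fully reproducible
#' from the config seed.
#'
#' @param config A [synth_cohort_config()].
#' @return A list with `recordings` (two [eeg_recording()]s per subject:
#'   state 0 then state 1) and `ground_truth` (informative channel indices
#'   and labels, plus the config).
#' @export
generate_cohort <- function(config = synth_cohort_config()) {
  stopifnot(inherits(config, "synth_cohort_config"))
  set.seed(config$seed)
  bands <- eeg_bands()
  # resting scalp EEG scale, microvolts: alpha/delta prominent, beta weakest
  base_sd <- c(delta = 10, theta = 7, alpha = 10, beta = 5)
  noise_sd <- 4
  phi_pre <- 0.3
  n <- round(config$fs * config$duration_per_state)
  ch_labels <- default_channel_labels(config$n_channels)

  # per-subject effect jitter on the log scale, so null effects stay null
  sv <- config$subject_variability
  mult <- matrix(1, config$n_subjects, 4L,
                 dimnames = list(NULL, names(bands)))
  ent <- numeric(config$n_subjects)
  for (j in seq_len(config$n_subjects)) {
    mult[j, ] <- exp(log(config$band_effects) * exp(stats::rnorm(4L, 0, sv)))
    ent[[j]] <- config$entropy_effect * exp(stats::rnorm(1L, 0, sv))
  }

  recordings <- list()
  for (j in seq_len(config$n_subjects)) {
    sid <- sprintf("S%02d", j)
    for (state in c(0L, 1L)) {
      informative <- seq_len(config$n_channels) %in% config$informative_channels
      acc <- matrix(0, n, config$n_channels)
      for (b in names(bands)) {
        sd_b <- rep(base_sd[[b]], config$n_channels)
        if (state == 1L) sd_b[informative] <- sd_b[informative] * sqrt(mult[j, b])
        comp <- band_noise(n, config$fs, bands[[b]], config$n_channels)
        acc <- acc + sweep(comp, 2L, sd_b, "*")
      }
      pn <- pink_noise(n, config$fs, config$n_channels)
      for (ch in seq_len(config$n_channels)) {
        phi <- if (informative[[ch]] && state == 1L)
          min(0.95, phi_pre + ent[[j]]) else phi_pre
        acc[, ch] <- acc[, ch] + noise_sd * ar1_smooth(pn[, ch], phi)
      }
      recordings[[length(recordings) + 1L]] <-
        eeg_recording(t(acc), config$fs, ch_labels, subject_id = sid,
                      state = state)
    }
  }
  list(recordings = recordings,
       ground_truth = list(
         informative_channels = config$informative_channels,
         informative_labels = ch_labels[config$informative_channels],
         config = config))
}

# the 16-channel montage used for default labels; generic names beyond 16
default_channel_labels <- function(n) {
  std <- c("Cz", "FCz", "F3", "F4", "C3", "C4", "P3", "P4", "FZ", "O",
           "F7", "F8", "T3", "T4", "T5", "T6")
  if (n <= length(std)) std[seq_len(n)] else
    c(std, paste0("X", seq_len(n - length(std))))
}

#' Two-class Gaussian toy feature table
#'
#' Fixture generator for feature-weighting and classifier tests: balanced
#' binary labels, `n_informative` columns whose class means are separated
#' by `class_sep` standard deviations, remaining columns pure noise.
#'
#' @param n_samples,n_features Table dimensions.
#' @param n_informative Number of informative columns (the first ones).
#' @param class_sep Class-mean separation in units of the column sd.
#' @param seed Integer RNG seed.
#' @return A [feature_matrix()] with feature name `"toy"` and channel
#'   labels `V1..Vp`.
#' @export
make_toy_feature_table <- function(n_samples = 200L, n_features = 20L,
                                   n_informative = 5L, class_sep = 3,
                                   seed = 1L) {
  if (n_informative > n_features)
    stop("n_informative must not exceed n_features")
  set.seed(seed)
  y <- rep_len(c(0L, 1L), n_samples)
  X <- matrix(stats::rnorm(n_samples * n_features), n_samples, n_features)
  if (n_informative > 0L)
    X[y == 1L, seq_len(n_informative)] <-
      X[y == 1L, seq_len(n_informative), drop = FALSE] + class_sep
  feature_matrix(X, paste0("V", seq_len(n_features)),
                 rep("toy", n_features), y, rep("toy", n_samples))
}
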