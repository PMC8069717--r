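test_that("band power concentrates on a pure tone's band and leaks little elsewhere", {
  t <- (0:499) / 500
  s <- sin(2 * pi * 10 * t)
  alpha <- 10^band_psd(s, 500, c(8, 12))
  total <- 10^band_psd(s, 500, c(0.5, 30))
  delta <- 10^band_psd(s, 500, c(0.5, 4))
  expect_gte(alpha / total, 0.95)
  expect_lt(delta / total, 0.01)
  expect_error(band_psd(s, 500, c(200, 300)), "Nyquist")
  expect_error(band_psd(s, 500, c(12, 8)), "f_lo < f_hi")
  # constant series: zero power, log floor, no crash
  expect_equal(band_psd(rep(2, 500), 500, c(8, 12)), log10(1e-12))
})

test_that("white noise spreads power evenly over equal-width bands", {
  ratios <- vapply(1:50, function(s) {
    set.seed(s)
    x <- rnorm(1000)
    p1 <- 10^band_psd(x, 500, c(20, 60))
    p2 <- 10^band_psd(x, 500, c(100, 140))
    p1 / p2
  }, 0)
  expect_gt(mean(ratios), 0.8)
  expect_lt(mean(ratios), 1.25)
})

test_that("band power is offset-invariant and scales quadratically", {
  set.seed(21)
  x <- rnorm(750)
  base <- 10^band_psd(x, 250, c(8, 12))
  shifted <- 10^band_psd(x + 57.3, 250, c(8, 12))
  scaled <- 10^band_psd(3 * x, 250, c(8, 12))
  expect_equal(shifted, base, tolerance = 1e-8)
  expect_equal(scaled / base, 9, tolerance = 1e-6)
})

test_that("sample entropy matches the brute-force template-counting oracle", {
  # deterministic alternating series
  alt <- rep(c(1, 2), 5)
  expect_identical(sample_entropy(alt, m = 2, r = 0.1),
                   oracle_sampen(alt, 2L, 0.1))
  # constant series: every template matches, entropy 0
  expect_identical(sample_entropy(rep(3.3, 30), m = 2, r = 0.5), 0)
  # white noise at several (n, m, r)
  set.seed(17)
  for (case in list(c(500L, 2L), c(200L, 3L), c(120L, 1L))) {
    x <- rnorm(case[[1L]])
    r <- 0.2 * sd(x)
    expect_equal(sample_entropy(x, m = case[[2L]], r = r),
                 oracle_sampen(x, case[[2L]], r), tolerance = 1e-12)
  }
})

test_that("sample entropy is invariant under affine maps when r tracks the sd", {
  set.seed(8)
  x <- rnorm(300)
  a <- sample_entropy(x, m = 2, r = 0.2 * sd(x))
  y <- 5 * x + 11
  b <- sample_entropy(y, m = 2, r = 0.2 * sd(y))
  expect_equal(a, b, tolerance = 1e-12)
  expect_error(sample_entropy(c(1, 2, 3), m = 2), "too short")
  expect_error(sample_entropy(rnorm(50), m = 2, r = 0), "positive")
})

test_that("feature extraction yields one column per (channel, feature), channels-major", {
  set.seed(30)
  mk <- function(n_ch, fs = 100, secs = 12)
    segment(eeg_recording(matrix(rnorm(n_ch * fs * secs), n_ch), fs,
                          paste0("ch", seq_len(n_ch)), "S1", 0L))
  ep16 <- mk(16L)
  expect_identical(ncol(extract_features(ep16, "sampen")$values), 16L)
  all16 <- extract_features(ep16)
  expect_identical(ncol(all16$values), 80L)

  ep2 <- mk(2L)
  two <- extract_features(ep2, c("psd_alpha", "sampen"))
  expect_identical(two$channels, c("ch1", "ch1", "ch2", "ch2"))
  expect_identical(two$features, rep(c("psd_alpha", "sampen"), 2L))
  # single epoch x 2 channels x 2 features -> 1 x 4
  one <- ep2
  one$epochs <- one$epochs[1L, , , drop = FALSE]
  one$labels <- one$labels[1L]
  one$subject_ids <- one$subject_ids[1L]
  expect_identical(dim(extract_features(one, c("psd_alpha", "sampen"))$values),
                   c(1L, 4L))

  # fixed Table-style feature order regardless of request order
  reordered <- extract_features(ep2, c("sampen", "psd_delta", "psd_beta"))
  expect_identical(unique(reordered$features),
                   c("psd_beta", "psd_delta", "sampen"))
  expect_error(extract_features(ep2, "psd_gamma"), "unknown feature")
  expect_error(extract_features(ep2, character()), "non-empty")
})

test_that("feature matrices round-trip through their CSV + sidecar form", {
  fm <- make_toy_feature_table(20L, 4L, 2L, 1.5, seed = 3L)
  path <- tempfile(fileext = ".csv")
  write_feature_matrix(fm, path)
  back <- read_feature_matrix(path)
  expect_equal(back$values, fm$values, tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(back$channels, fm$channels)
  expect_identical(back$labels, fm$labels)
})
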