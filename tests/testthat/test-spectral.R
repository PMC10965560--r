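# brute-force enumeration of window start positions
count_windows_oracle <- function(duration, length, step) {
  starts <- 0
  k <- 0
  while (starts * step + length <= duration + 1e-9) {
    k <- k + 1
    starts <- starts + 1
  }
  k
}

test_that("window counts match brute-force enumeration of start positions", {
  expect_equal(n_windows(58, window_spec(5, 0.125)), 425L)
  expect_equal(n_windows(58, window_spec(0.125, 0.125)), 464L)
  expect_equal(n_windows(5, window_spec(5, 5)), 1L)
  set.seed(31)
  for (i in 1:50) {
    length <- round(runif(1, 0.5, 10), 2)
    step <- round(runif(1, 0.1, length), 2)
    duration <- round(runif(1, length, 60), 2)
    expect_equal(n_windows(duration, window_spec(length, step)),
                 count_windows_oracle(duration, length, step),
                 info = sprintf("d=%g l=%g s=%g", duration, length, step))
  }
})

test_that("segmentation yields the expected starts and errors on short trials", {
  x <- matrix(rnorm(2 * 128 * 12), nrow = 2)
  seg <- segment_windows(x, 128, window_spec(5, 2))
  expect_length(seg$windows, 4)
  expect_equal(seg$start_s, c(0, 2, 4, 6))
  expect_identical(seg$windows[[2]], x[, (2 * 128 + 1):(7 * 128)])
  expect_error(segment_windows(x[, 1:100], 128, window_spec(5, 2)),
               "shorter than one window")
})

test_that("a pure 10 Hz tone concentrates its power in the alpha band", {
  fs <- 128
  t <- seq(0, 5 - 1 / fs, by = 1 / fs)
  x <- matrix(sin(2 * pi * 10 * t), nrow = 1)
  ps <- compute_psd(x, fs)
  bp <- band_powers(ps$psd, ps$freq, fs = fs)
  total <- sum(ps$psd[ps$freq >= 0.5 & ps$freq < 45]) * (ps$freq[2] - ps$freq[1])
  expect_gt(bp[1, "alpha"] / total, 0.95)
})

test_that("the periodogram integrates to the signal variance (Parseval)", {
  set.seed(7)
  n <- 640
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / n))
  integrals <- vars <- numeric(20)
  for (i in 1:20) {
    x <- matrix(rnorm(n, sd = runif(1, 0.5, 3)), nrow = 1)
    ps <- compute_psd(x, 128)
    integrals[i] <- sum(ps$psd) * (ps$freq[2] - ps$freq[1])
    # exact identity: integral equals the windowed-signal energy over the
    # window's power (discrete Parseval), for every single draw
    y <- (drop(x) - mean(x)) * w
    expect_equal(integrals[i], sum(y^2) / sum(w^2), tolerance = 1e-10)
    vars[i] <- var(drop(x))
  }
  # statistically, the integral estimates the sample variance
  expect_equal(mean(integrals / vars), 1, tolerance = 0.05)
})

test_that("constant signal has zero power in every band", {
  x <- matrix(3.3, nrow = 2, ncol = 640)
  ps <- compute_psd(x, 128)
  bp <- band_powers(ps$psd, ps$freq, fs = 128)
  expect_true(all(bp == 0))
})

test_that("an in-band tone dominates its own band", {
  fs <- 128
  t <- seq(0, 5 - 1 / fs, by = 1 / fs)
  x <- matrix(sin(2 * pi * 35 * t), nrow = 1)
  ps <- compute_psd(x, fs)
  bp <- band_powers(ps$psd, ps$freq, fs = fs)
  expect_true(all(bp[1, "gamma"] >= 20 * bp[1, colnames(bp) != "gamma"]))
})

test_that("flat PSD gives band powers proportional to bandwidths", {
  freq <- seq(0, 64, by = 0.2)
  psd <- matrix(1, nrow = 1, ncol = length(freq))
  bp <- band_powers(psd, freq, fs = 128)
  # analytic bandwidths 3.5 : 4 : 4 : 18 : 15, up to bin rounding (0.2 Hz)
  expect_equal(drop(bp), c(delta = 3.5, theta = 4, alpha = 4, beta = 18,
                           gamma = 15),
               tolerance = 0.2 / 3.5)
  expect_error(band_powers(psd, freq, fs = 80), "Nyquist")
})

test_that("band-ratio indices match their definitional quotients", {
  p <- c(delta = 1, theta = 2, alpha = 4, beta = 8, gamma = 1)
  ix <- band_ratios(p)
  expect_equal(drop(ix), c(relaxation = 2, excitement = 2, fatigue = 2,
                           engagement = 8 / 6))
  # theta = delta > 0 gives relaxation exactly 1
  expect_equal(unname(band_ratios(c(2, 2, 1, 1, 1))[1, "relaxation"]), 1)
  # zero denominator is floored at the documented epsilon
  ix0 <- band_ratios(c(delta = 0, theta = 2, alpha = 1, beta = 1, gamma = 0))
  expect_equal(ix0[1, "relaxation"], 2 / 1e-12)
  expect_true(is.finite(ix0[1, "relaxation"]))
  expect_error(band_ratios(c(-1, 1, 1, 1, 1)), "nonnegative")
})

test_that("feature table has the documented shape, labels and determinism", {
  rs <- planted_recording()
  ft <- planted_features()
  nw <- n_windows(rs$trial_duration_s, window_spec(5, 5))
  expect_equal(nrow(ft), 3 * 8 * nw)
  expect_length(feature_columns(ft), 32 * 9)

  ft8 <- build_feature_table(rs, window_spec(5, 5),
                             montage = reference_channels_8())
  expect_length(feature_columns(ft8), 72)

  # windows inherit their trial's rating and its discrete class
  r <- rs$ratings[rs$ratings$subject == "s02" & rs$ratings$trial == 3, ]
  rows <- ft$subject == "s02" & ft$trial == 3
  expect_true(all(ft$arousal[rows] == r$arousal))
  expect_true(all(ft$arousal_class[rows] == discretize_vad(r$arousal)))

  # determinism: identical input, identical table
  expect_identical(ft, build_feature_table(rs, window_spec(5, 5)))
  expect_error(build_feature_table(rs, montage = c("T7", "XX")), "XX")
})
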