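test_that("replayed chunks conserve the montage-restricted signal", {
  fx <- rt_fixture()
  it <- stream_from_recording(fx$rs, "s01", 1, fx$cfg)
  chunks <- list()
  while (!is.null(ch <- it())) chunks[[length(chunks) + 1L]] <- ch
  got <- do.call(cbind, chunks)
  expect_equal(got, fx$rs$signals[["s01"]][[1]][fx$cfg$montage, ],
               tolerance = 1e-12)
  expect_error(stream_from_recording(
    planted_recording(), "s01", 1,
    stream_config(montage = reference_channels_8(), source_fs = 128)),
    NA)
})

test_that("a 58 s trial yields 290 chunks of 0.2 s at the 250 Hz source rate", {
  fx <- rt_fixture()
  cfg250 <- stream_config(source_fs = 250)
  it <- stream_from_recording(fx$rs, "s01", 1, cfg250)
  n <- 0L
  total <- 0L
  while (!is.null(ch <- it())) {
    n <- n + 1L
    total <- total + ncol(ch)
    expect_equal(nrow(ch), 8)
  }
  expect_equal(n, 290L)
  expect_equal(total, 58L * 250L)  # resampled length is exact
})

test_that("the default stream montage is the optimal eight-channel set", {
  expect_equal(stream_config()$montage,
               c("Fp1", "F7", "FC5", "FC6", "T7", "T8", "P7", "O2"))
  expect_error(stream_from_recording(rt_fixture()$rs, "s01", 1,
                                     stream_config(
                                       montage = c("Fp1", "F7", "FC5", "FC6",
                                                   "T7", "T8", "P7", "Oz"),
                                       source_fs = 128)),
               "Oz")
})

test_that("pre-processing re-references to a zero common average", {
  fx <- rt_fixture()
  raw <- fx$rs$signals[["s01"]][[2]][fx$cfg$montage, 1:640]
  out <- preprocess_buffer(raw, fx$cfg)
  expect_equal(ncol(out), 640)  # identity rate: length unchanged
  expect_lt(max(abs(colMeans(out))), 1e-9)
  # CAR output is orthogonal to the all-ones channel vector
  expect_lt(max(abs(crossprod(rep(1, 8), out))), 1e-6)
  expect_error(preprocess_buffer(raw[, 1:64], fx$cfg), "warm-up")
})

test_that("a 60 Hz tone is attenuated by at least 40 dB", {
  fs <- 250
  t <- seq(0, 5 - 1 / fs, by = 1 / fs)
  amps <- 1:8
  buf <- t(sapply(amps, function(a) a * sin(2 * pi * 60 * t)))
  cfg <- stream_config(source_fs = 250)
  out <- preprocess_buffer(buf, cfg)
  t2 <- seq(0, by = 1 / 128, length.out = ncol(out))
  fit60 <- function(x) {
    f <- stats::lm(x ~ sin(2 * pi * 60 * t2) + cos(2 * pi * 60 * t2))
    sqrt(sum(stats::coef(f)[2:3]^2))
  }
  a_in <- abs(amps - mean(amps))   # amplitude surviving the CAR
  for (i in c(1, 8)) {
    expect_lt(20 * log10(fit60(out[i, ]) / a_in[i]), -40)
  }
})

test_that("one 5 s buffer consumes 640 samples and yields a mapped emotion", {
  fx <- rt_fixture()
  raw <- fx$rs$signals[["s01"]][[3]][fx$cfg$montage, 1:640]
  buf <- preprocess_buffer(raw, fx$cfg)
  expect_equal(dim(buf), c(8, 5 * 128))
  p <- predict_buffer(buf, fx$vm, fx$cfg, timestamp_s = 5)
  expect_true(all(c(p$arousal, p$valence, p$dominance) %in% -1:1))
  expect_equal(p$emotion,
               triple_to_emotion(c(p$arousal, p$valence, p$dominance))$emotion)
  # montage mismatch with the bundle metadata is refused
  vm_bad <- fx$vm
  vm_bad$metadata$montage <- c("Fp1", "Fp2", "C3", "C4", "P7", "P8", "O1",
                               "O2")
  expect_error(predict_buffer(buf, vm_bad, fx$cfg), "montage")
})

test_that("the loop emits one prediction per period and is deterministic", {
  fx <- rt_fixture()
  sink <- file.path(withr::local_tempdir(), "preds.jsonl")
  p1 <- run_stream(stream_from_recording(fx$rs, "s01", 1, fx$cfg),
                   fx$vm, fx$cfg, sink = sink)
  expect_equal(nrow(p1), floor(58 / 5))   # 11 predictions
  expect_equal(p1$t, 5 * seq_len(11))
  expect_true(all(p1$emotion %in% emotion_inventory()$emotion))
  p2 <- run_stream(stream_from_recording(fx$rs, "s01", 1, fx$cfg),
                   fx$vm, fx$cfg)
  expect_identical(p1[names(p2)], p2)
  # the JSON-lines sink holds one record per prediction
  lines <- readLines(sink)
  expect_length(lines, 11)
  rec <- jsonlite::fromJSON(lines[[1]])
  expect_equal(rec$vad, c(p1$arousal[1], p1$valence[1], p1$dominance[1]))
})

test_that("streaming predictions equal the offline pipeline on each window", {
  fx <- rt_fixture()
  preds <- run_stream(stream_from_recording(fx$rs, "s01", 2, fx$cfg),
                      fx$vm, fx$cfg)
  x <- fx$rs$signals[["s01"]][[2]][fx$cfg$montage, ]
  for (i in seq_len(nrow(preds))) {
    seg <- x[, ((i - 1) * 640 + 1):(i * 640)]
    buf <- preprocess_buffer(seg, fx$cfg)
    # offline route: wrap the window as a one-trial recording and run the
    # feature-table path
    rs1 <- structure(list(
      signals = list(s01 = list(buf)),
      ratings = data.frame(subject = "s01", trial = 1L, valence = 5,
                           arousal = 5, dominance = 5),
      channel_names = fx$cfg$montage, fs = 128, trial_duration_s = 5),
      class = "recording_set")
    ft1 <- build_feature_table(rs1, window_spec(5, 5))
    off <- drop(predict_vad(fx$vm, ft1))
    expect_identical(unname(c(preds$arousal[i], preds$valence[i],
                              preds$dominance[i])),
                     unname(off[c("arousal", "valence", "dominance")]))
  }
})
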