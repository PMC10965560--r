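# shared fixture builders; heavier fixtures are built lazily and cached for
# the duration of the test run
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- force(expr)
  .fixture_cache[[name]]
}

make_recording <- function(n_subjects = 2, n_trials = 6,
                           trial_duration_s = 20, channels = eeg_channels(),
                           couplings = NULL, noise_sd = 1, seed = 1,
                           ratings = NULL) {
  generate_recordings(
    generator_config(n_subjects = n_subjects, n_trials = n_trials,
                     trial_duration_s = trial_duration_s,
                     channels = channels),
    effect_spec(couplings = couplings, noise_sd = noise_sd),
    seed = seed, ratings = ratings)
}

# couplings planting one strong gamma effect per VAD component on a channel
gamma_coupling <- function(channels, components, slope = 2) {
  data.frame(channel = channels, band = "gamma", component = components,
             slope = slope, stringsAsFactors = FALSE)
}

# small full-montage recording with temporal-gamma couplings on all three
# components, used by several selection-stage tests
planted_recording <- function() {
  cached("planted_rs", {
    cpl <- rbind(gamma_coupling("T7", c("valence", "arousal", "dominance")),
                 gamma_coupling("T8", c("valence", "arousal", "dominance")))
    make_recording(n_subjects = 3, n_trials = 8, trial_duration_s = 20,
                   couplings = cpl, noise_sd = 1, seed = 42)
  })
}

planted_features <- function() {
  cached("planted_ft", build_feature_table(planted_recording(),
                                           window_spec(5, 5)))
}

# synthetic feature-table-shaped data.frame with directly separable features,
# for classifier machinery tests that need no EEG generation
toy_feature_table <- function(n = 600, n_features = 6, seed = 99,
                              noise = 0.3) {
  set.seed(seed)
  rating <- runif(n, 1, 9)
  cls <- discretize_vad(rating)
  ft <- data.frame(subject = "s01", trial = 1L, window = seq_len(n),
                   start_s = 0)
  for (j in seq_len(n_features)) {
    ft[[paste0("ch", j, "_gamma")]] <- rating + rnorm(n, sd = noise)
  }
  for (e in c("valence", "arousal", "dominance")) {
    ft[[e]] <- rating
    ft[[paste0(e, "_class")]] <- cls
  }
  ft
}

# direct-formula Pearson correlation, the oracle used instead of cor()
pearson_oracle <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# couplings for the end-to-end fixture: three gamma channels drive each VAD
# component (O2 mixes arousal and dominance)
e2e_couplings <- function() {
  rbind(gamma_coupling(c("Fp1", "T7", "FC6"), "valence"),
        gamma_coupling(c("F7", "T8", "O2"), "arousal"),
        gamma_coupling(c("FC5", "P7"), "dominance"),
        gamma_coupling("O2", "dominance", slope = 1.5))
}

# 8-channel corpus with strong planted couplings plus the trained trio,
# shared by the classification and streaming tests
e2e_fixture <- function() {
  cached("e2e", {
    rs <- make_recording(n_subjects = 3, n_trials = 40,
                         trial_duration_s = 20,
                         channels = reference_channels_8(),
                         couplings = e2e_couplings(), noise_sd = 1,
                         seed = 271)
    ft <- build_feature_table(rs, window_spec(5, 2.5))
    vm <- train_final(ft, k = 34, seed = 271)
    list(rs = rs, ft = ft, vm = vm)
  })
}

# 58 s single-subject replay recording + identity-rate stream config; the
# model trio comes from the end-to-end fixture (same montage and window)
rt_fixture <- function() {
  cached("rt", {
    rs <- make_recording(n_subjects = 1, n_trials = 6,
                         trial_duration_s = 58,
                         channels = reference_channels_8(),
                         couplings = e2e_couplings(), noise_sd = 1,
                         seed = 314)
    list(rs = rs, vm = e2e_fixture()$vm,
         cfg = stream_config(source_fs = 128))
  })
}
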