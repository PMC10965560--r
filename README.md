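# emorec

Real-time EEG emotion recognition in R: spectral band-power features, a
hybrid PCA/correlation/Gini-importance channel-selection procedure, 3-class
valence/arousal/dominance (VAD) classifiers under shift-based
cross-validation, and a buffered streaming loop that maps each predicted
VAD triple to a named emotion — including Descartes' six fundamental
passions (desire, admiration, joy, love, hate, sadness).

The package is aimed at affective-BCI researchers who want a transparent,
fully testable implementation of this recipe. Because the human corpus the
method was designed around is access-restricted, `emorec` ships a
synthetic-data generator that emulates its shape (32 subjects x 40 trials
x 32 channels x 58 s @ 128 Hz, one continuous 1-9 VAD rating triple per
trial) with *planted*, recoverable couplings between band power and
ratings, so every stage can be validated against known ground truth.

## The method in brief

For each analysis window (5 s default) and channel, the one-sided Hann
periodogram is integrated over the five canonical bands — delta 0.5-4,
theta 4-8, alpha 8-12, beta 12-30, gamma 30-45 Hz — and four band-ratio
indices are added (relaxation θ/δ, excitement β/α, fatigue α/θ,
engagement β/(θ+α)).

Channel selection works in two passes. First, channels are grouped into
six anatomical lobes; per subject, each (lobe, band) block is compressed
to its first principal component *Z = X·V₁*, and the mean absolute
Pearson correlation between *Z* and each VAD axis, averaged over
subjects, identifies the most informative band. Second, random-forest
regressions on that band's 32 channel powers give per-channel Gini
importances *GI(c, e)* (normalised so Σ_c GI(c, e) = 1), averaged over 10
random restarts and all subjects, and the Emotion Importance Index

    EII(c) = (1/3) · Σ_e GI(c, e)

ranks channels; the top 8 — reference set Fp1, F7, FC5, FC6, T7, T8, P7,
O2 — form the portable montage.

Classification is 3-class per axis after discretising ratings (low 1-3.6
→ −1, medium 3.7-6.3 → 0, high 6.4-9 → +1). Five families (extra-trees,
random forest, gradient boosting, kNN, RBF SVC) are compared with
shift-based cross-validation: indices are circularly rotated by
φ(fold) = fold·⌊n/8⌋ and cut into contiguous 60:20:20
train/validation/test blocks. The final deliverable is an extra-trees
trio, one model per axis, each on its own top-34 features. The streaming
loop buffers 5 s of an 8-channel stream, resamples to 128 Hz, band-passes
0.4-45 Hz, common-average references, featurises, classifies, and maps
the triple through the packaged 27-cell emotion table.

## Worked example

```r
library(emorec)

cpl <- data.frame(
  channel   = c("Fp1", "T7", "F7", "T8", "FC5", "P7"),
  band      = "gamma",
  component = rep(c("valence", "arousal", "dominance"), each = 2),
  slope     = 2)
rs <- generate_recordings(
  generator_config(n_subjects = 3, n_trials = 20, trial_duration_s = 20),
  effect_spec(couplings = cpl, noise_sd = 1), seed = 1)

ft <- build_feature_table(rs, window_spec(5, 5))
best_band(correlation_table(ft))
#> [1] "gamma"

gi <- gi_table(ft, "gamma", seed = 1)
eii_ranking(gi, k = 8)$selected
#> [1] "FC5" "F7"  "T7"  "Fp1" "T8"  "P7"  "P3"  "AF4"
```

The six planted channels occupy the top six ranks; the remaining two
slots go to noise channels, as expected when only six couplings exist. A
trained trio then drives the replay loop:

```r
ft8 <- build_feature_table(rs, window_spec(5, 5),
                           montage = reference_channels_8())
vm  <- train_final(ft8, k = 34, seed = 1)
cfg <- stream_config(source_fs = 128)
head(run_stream(stream_from_recording(rs, "s01", 1, cfg), vm, cfg), 3)
#>    t arousal valence dominance emotion descartes
#> 1  5      -1       0         0   Other     FALSE
#> 2 10      -1       0         0   Other     FALSE
#> 3 15      -1       0         0   Other     FALSE
```

One prediction per 5 s of stream time; each row's emotion is the
packaged-table entry for the predicted triple — here a low-arousal,
mid-valence, mid-dominance cell that the map leaves unnamed ("Other").
Note the streaming path band-passes and re-references each buffer before
featurising, so for best accuracy the training table should be built from
identically pre-processed recordings.

A command-line wrapper over the same functions is installed at
`inst/cli/emorec.R` with subcommands `simulate`, `features`,
`select-channels`, `evaluate`, `train` and `stream` (EDF directories with
a `ratings.csv` sidecar in, CSV/JSON-lines out).

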