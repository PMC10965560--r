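---
title: "From band power to Descartes' passions: the emorec pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From band power to Descartes' passions: the emorec pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emorec)
```

## The problem

Affective brain-computer interfaces try to estimate, from scalp EEG alone,
where a person sits in the three-dimensional
valence-arousal-dominance (VAD) space: how pleasant, how activated and how
in-control they feel. `emorec` implements one complete recipe for this task,
from raw multichannel EEG to a named emotion emitted every five seconds,
and ships a synthetic-data generator so that every stage can be exercised
and validated without access to restricted human recordings.

The pipeline has five stages:

1. **Spectral features.** Trials are segmented into overlapping windows;
   each window's one-sided Hann periodogram is integrated over the five
   canonical bands (delta 0.5-4, theta 4-8, alpha 8-12, beta 12-30,
   gamma 30-45 Hz) per channel, and four band-ratio indices are added
   (relaxation $\theta/\delta$, excitement $\beta/\alpha$, fatigue
   $\alpha/\theta$, engagement $\beta/(\theta+\alpha)$).
2. **Emotion map.** Continuous 1-9 ratings per axis are discretised to
   $\{-1, 0, 1\}$ and the 27 possible (arousal, valence, dominance)
   triples are mapped to named emotions, six of which are Descartes'
   fundamental passions (desire, admiration, joy, love, hate, sadness).
3. **Channel selection.** Channels are grouped into six anatomical lobes;
   per subject, each (lobe, band) block of band powers is compressed to
   its first principal component, and the mean absolute Pearson
   correlation with each VAD axis identifies the most informative band
   (gamma, in both the source data and the synthetic default). Per-channel
   Gini importances from random-forest regressions on that band's 32
   channel powers, averaged over random restarts and subjects, are then
   combined into the Emotion Importance Index
   $EII(c) = \frac{1}{3}\sum_e GI(c, e)$, and the top 8 channels form the
   portable montage.
4. **Model evaluation.** Five classifier families (extra-trees, random
   forest, gradient boosting, k-nearest neighbours, RBF support-vector
   classifier) are compared per VAD axis under shift-based
   cross-validation; window lengths and feature counts are swept; the
   final deliverable is a trio of extra-trees models, one per axis, each
   on its own top-34 features.
5. **Streaming.** A replayed (or live) 8-channel stream is buffered in
   5-second blocks, resampled to 128 Hz, band-passed 0.4-45 Hz,
   common-average referenced, featurised and classified; the discrete
   triple is mapped to its emotion and emitted once per period.

## The synthetic generator and what it does (not) emulate

`generate_recordings()` produces a corpus shaped like the 32-subject
benchmark the method targets: 40 trials per subject, 32 channels of the
10-20 system at 128 Hz, 58 s per trial, one continuous VAD triple per
trial. Each trial is a sum of five band-limited carriers — white noise
passed through a 4th-order Butterworth band-pass at the band edges and
normalised to unit RMS — plus white measurement noise. Filtered noise
rather than sinusoids is used deliberately: tones make band-power
estimates essentially noiseless and would trivialise every downstream
statistical question.

Ground truth is planted through `effect_spec()`: on a coupled channel the
carrier amplitude in one band becomes
$a = \max(a_0 + s\,(r - 5),\ 0.1)$ microvolts, where $r$ is the trial's
rating on one axis, $a_0 = 10\,\mu V$ is the baseline amplitude and $s$
the coupling slope in microvolts per rating unit. Band power then scales
as $a^2$, so a planted coupling induces a strong monotone
power-rating relation that the correlation, importance and classification
stages can recover — and an uncoupled channel is provably uninformative.
Defaults ($a_0 = 10$, noise SD $1\,\mu V$, slopes around 2) keep
amplitudes in a plausible scalp-EEG range within the $\pm 200\,\mu V$ EDF
physical range; the amplitude scale of real band powers is not dictated by
the published material, so this is a package choice recorded here and in
the generator documentation.

What the generator does **not** emulate: eye-blink and muscle artifacts,
volume conduction (channels are independent given the ratings),
non-stationarity within a trial, inter-subject variability in spectral
shape, and rating distributions other than uniform on $[1, 9]$. Passing
tests on this synthetic corpus therefore demonstrates that the pipeline's
arithmetic and its selection/classification logic are correct and
recover planted structure; it does not certify accuracy figures on real
EEG.

Ratings are broadcast: every window of a trial inherits the trial's
rating. This mirrors how whole-clip annotations are used in the source
methodology, and it has a consequence worth stating plainly: windows of
one trial share carrier realisations, so any splitting scheme that puts
windows of the same trial on both sides of a split leaks information, and
a flexible classifier can beat chance even with shuffled labels. The
package's chance-level control therefore evaluates on a table thinned to
two non-overlapping windows per trial, where that leakage is negligible.

## Numerical choices

* **Periodogram.** One Hann-tapered FFT per analysis window, scaled so the
  integral of the one-sided density equals the windowed-signal variance
  (the discrete Parseval identity holds to 1e-10 in tests). Windows are
  demeaned before tapering. No Welch averaging by default — the window
  itself is short — and no log transform by default; `log10_powers`
  is available in `build_feature_table()`.
* **Band edges.** Half-open $[lo, hi)$ binning so the shared edges 4, 8,
  12 and 30 Hz are counted once. At the 5 s default window the grid step
  is 0.2 Hz, giving the delta band 17 bins.
* **Index floors.** Ratio denominators are floored at $10^{-12}$ so
  degenerate windows give finite indices.
* **PCA.** Per-subject column centring, no variance scaling (all columns
  of a lobe/band block are powers in the same units); the first right
  singular vector of the centred matrix, sign-fixed so the
  largest-magnitude loading is positive; zero-variance blocks degrade to
  a documented arbitrary-loading fallback with a warning. Tests check the
  loading against a covariance eigendecomposition to 1e-8.
* **Correlations.** Per-subject Pearson coefficients on the projected
  series against broadcast ratings, absolute value, then the subject
  mean; constant series are excluded with a warning rather than producing
  NaN.
* **Random forests for importance.** 100 trees, variance (MSE) split
  criterion, all features candidate at every split — matching the
  convention of the regression forests the method was built around, and
  necessary for importance to concentrate on informative channels rather
  than diffusing over noise. Ten random restarts per subject (seeds
  `seed + 0..9`); importances are normalised to sum to one per fit, so
  the per-component averages and the EII sum to one by construction
  (asserted to 1e-9).
* **Shift splits.** `phi(fold) = fold * floor(n / folds)` circular
  rotation, then contiguous 60:20:20 cuts. The offset formula is a
  package choice (only the existence of a shift is prescribed); it is
  configurable. The validation block is reserved and unused by default.
* **Classifier defaults.** Extra-trees and random forest: 100 trees
  (extra-trees with one random split candidate per feature and no
  bootstrap); kNN with $k = 5$; RBF SVC with $C = 1$; gradient boosting
  with 50 rounds, depth 6, learning rate 0.3. All configurable through
  `model_spec()`; none are tuned — the validation block exists for users
  who wish to.
* **Tie-breaks.** Equal EII ranks alphabetically; equal band totals go to
  the higher-frequency band; equal sweep scores go to the shorter window
  or the smaller feature count (the feature-count sweep compares scores
  rounded to 3 decimals, which is why 34 can be preferred over 35).
* **Decimation.** Model-comparison runs train on every 16th training row
  (configurable `stride` in `split_spec()`); final-model training uses
  all rows.
* **Determinism.** One master seed drives fixed per-subject generator
  substreams; every forest fit and prediction carries an explicit seed
  (classification vote ties in the forest backend would otherwise draw
  from the session RNG); kNN tie-breaking pins and restores the RNG
  state. Identical inputs give bitwise-identical tables and predictions.

## Discretisation gaps

The published rating bins — low 1-3.6, medium 3.7-6.3, high 6.4-9 —
leave the open intervals (3.6, 3.7) and (6.3, 6.4) undefined on a
continuous scale. The effective cut points default to the gap midpoints
3.65 and 6.35, which reproduce the stated classes everywhere the bins
apply and make the mapping total; both are parameters of
`discretization_rule()`.

## Problem sizes used in validation

The test-suite and the acceptance script validate on deliberately small
synthetic corpora: recovery of eight planted gamma couplings uses
8 subjects x 10 trials x 20 s per master seed; importance normalisation
uses 4 subjects x 16 trials (about 2,100 windows); end-to-end
classification uses 3 subjects x 40 trials on the 8-channel montage
(840 windows); streaming equivalence replays full 58 s trials. These
sizes were chosen as the smallest at which the planted effects are
comfortably identifiable; the full 593,920-window default shape is
arithmetic-checked rather than materialised.

## Known limitations

* The synthetic corpus is the only validation substrate; no claim is made
  about accuracy on real EEG, where artifacts, volume conduction and
  weaker, non-linear couplings dominate.
* Window-level cross-validation with broadcast labels measures
  within-trial generalisation; trial- or subject-level generalisation
  requires grouped splits, which the shift scheme does not provide.
* The EDF writer covers the subset of the format the package itself
  produces (identical rates, one-second records, 16-bit); it is not a
  general-purpose EDF library.
* The streaming loop replays recordings; live acquisition hardware would
  implement the same chunk-iterator contract but is out of scope.
* The streaming path band-passes and common-average references every
  buffer before featurising. A model trio trained on raw-signal features
  remains usable (the equivalence tests compare predictions, not
  accuracy), but deployments that care about accuracy should build the
  training table from identically pre-processed recordings.

## A worked example

```{r example, eval = FALSE}
library(emorec)

# a small corpus with one strong gamma coupling per VAD axis
cpl <- data.frame(
  channel   = c("Fp1", "T7", "F7", "T8", "FC5", "P7"),
  band      = "gamma",
  component = rep(c("valence", "arousal", "dominance"), each = 2),
  slope     = 2)
rs <- generate_recordings(
  generator_config(n_subjects = 3, n_trials = 20, trial_duration_s = 20),
  effect_spec(couplings = cpl, noise_sd = 1), seed = 1)

ft <- build_feature_table(rs, window_spec(5, 5))
ct <- correlation_table(ft)
best_band(ct)                       # "gamma"
gi <- gi_table(ft, "gamma", seed = 1)
eii_ranking(gi, k = 8)$selected     # the six coupled channels rank on top

ft8 <- build_feature_table(rs, window_spec(5, 5),
                           montage = reference_channels_8())
vm <- train_final(ft8, k = 34, seed = 1)

cfg <- stream_config(source_fs = 128)
run_stream(stream_from_recording(rs, "s01", 1, cfg), vm, cfg)
```
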