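#' Analysis-window specification
#'
#' @param length_s Window length in seconds (default 5, the length selected
#'   for the final models).
#' @param step_s Step between window starts in seconds (default 0.125, the
#'   moving-window stride used for the channel-selection feature tables).
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(length_s = 5, step_s = 0.125) {
  stopifnot(step_s > 0, step_s <= length_s)
  structure(list(length_s = length_s, step_s = step_s),
            class = "window_spec")
}

#' Number of analysis windows in a trial
#'
#' Closed form `floor((duration - length) / step) + 1` for windows starting
#' at 0, step, 2*step, ... whose end does not pass the trial end. A 58 s
#' trial yields 425 windows at 5 s / 0.125 s and 464 at 0.125 s / 0.125 s.
#'
#' @param duration_s Trial duration in seconds.
#' @param spec A [window_spec()].
#' @return Integer window count (0 if the trial is shorter than one window).
#' @export
n_windows <- function(duration_s, spec = window_spec()) {
  if (duration_s < spec$length_s) return(0L)
  # tiny tolerance so e.g. 58/0.125 is not floored down by float error
  as.integer(floor((duration_s - spec$length_s) / spec$step_s + 1e-9)) + 1L
}

#' Segment a trial into overlapping analysis windows
#'
#' @param x Channels x samples signal matrix.
#' @param fs Sampling rate in Hz.
#' @param spec A [window_spec()]; `fs * length_s` and `fs * step_s` must be
#'   whole numbers of samples.
#' @return List with `windows` (list of channels x window-samples matrices)
#'   and `start_s` (numeric vector of start times).
#' @export
segment_windows <- function(x, fs, spec = window_spec()) {
  stopifnot(is.matrix(x))
  wl <- round(fs * spec$length_s)
  st <- round(fs * spec$step_s)
  if (abs(fs * spec$length_s - wl) > 1e-6 || abs(fs * spec$step_s - st) > 1e-6) {
    stop("window length and step must be whole numbers of samples at fs = ", fs)
  }
  n <- ncol(x)
  if (n < wl) {
    stop("trial (", n, " samples) is shorter than one window (", wl,
         " samples); no output")
  }
  starts <- seq(0L, n - wl, by = st)
  list(
    windows = lapply(starts, function(s0) x[, (s0 + 1L):(s0 + wl), drop = FALSE]),
    start_s = starts / fs
  )
}

#' One-sided Hann periodogram of a multichannel window
#'
#' Each channel is demeaned, multiplied by a Hann taper and Fourier
#' transformed; the squared modulus is scaled by `1 / (fs * sum(w^2))` and
#' doubled off DC/Nyquist, giving a density in (signal units)^2 per Hz whose
#' integral over frequency recovers the windowed-signal variance (Parseval).
#'
#' @param window Channels x samples matrix (>= 2 samples, finite).
#' @param fs Sampling rate in Hz.
#' @return List with `freq` (Hz, 0..fs/2) and `psd` (channels x frequencies).
#' @export
compute_psd <- function(window, fs) {
  stopifnot(is.matrix(window), ncol(window) >= 2)
  if (!all(is.finite(window))) stop("non-finite samples in window")
  n <- ncol(window)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / n))  # periodic Hann
  y <- sweep(window, 1, rowMeans(window)) * rep(w, each = nrow(window))
  ft <- stats::mvfft(t(y))  # samples x channels
  n_keep <- floor(n / 2) + 1L
  p <- Mod(ft[seq_len(n_keep), , drop = FALSE])^2 / (fs * sum(w^2))
  # one-sided: double everything except DC and (for even n) Nyquist
  dbl <- rep(2, n_keep)
  dbl[1] <- 1
  if (n %% 2 == 0) dbl[n_keep] <- 1
  p <- p * dbl
  list(freq = (seq_len(n_keep) - 1) * fs / n, psd = t(p))
}

#' Integrate a PSD over the five frequency bands
#'
#' Band power is the sum of PSD bins with `lo <= f < hi`, times the bin
#' width. The half-open convention keeps shared band edges (4, 8, 12, 30 Hz)
#' from being counted twice.
#'
#' @param psd Channels x frequencies PSD matrix.
#' @param freq Frequency grid in Hz.
#' @param bands A band table as from [band_set()].
#' @param fs Sampling rate, used only to check bands against Nyquist.
#' @return Channels x bands matrix of nonnegative powers.
#' @export
band_powers <- function(psd, freq, bands = band_set(), fs = NULL) {
  stopifnot(is.matrix(psd), length(freq) == ncol(psd))
  if (!is.null(fs) && any(bands$hi_hz > fs / 2 + 1e-9)) {
    stop("band upper edge exceeds the Nyquist frequency ", fs / 2, " Hz")
  }
  df <- freq[2] - freq[1]
  out <- matrix(0, nrow = nrow(psd), ncol = nrow(bands),
                dimnames = list(rownames(psd), bands$band))
  for (b in seq_len(nrow(bands))) {
    sel <- freq >= bands$lo_hz[b] - 1e-9 & freq < bands$hi_hz[b] - 1e-9
    if (any(sel)) {
      out[, b] <- rowSums(psd[, sel, drop = FALSE]) * df
    }
  }
  out
}

# denominator floor keeping ratios finite on degenerate windows
RATIO_EPS <- 1e-12

#' Band-ratio indices from one channel's five band powers
#'
#' Four interpretable quotients of band powers: relaxation theta/delta,
#' excitement beta/alpha, mental fatigue alpha/theta and engagement
#' beta/(theta+alpha). Denominators are floored at `1e-12` so degenerate
#' (e.g. all-zero) windows give finite values.
#'
#' @param powers Numeric vector or matrix of band powers named/ordered
#'   delta, theta, alpha, beta, gamma; one row per channel if a matrix.
#' @return Matrix (channels x 4) with columns `relaxation`, `excitement`,
#'   `fatigue`, `engagement`.
#' @export
band_ratios <- function(powers) {
  if (is.null(dim(powers))) powers <- matrix(powers, nrow = 1,
                                             dimnames = list(NULL, names(powers)))
  if (!is.null(colnames(powers))) {
    powers <- powers[, c("delta", "theta", "alpha", "beta", "gamma"),
                     drop = FALSE]
  }
  if (any(powers < 0)) stop("band powers must be nonnegative")
  d <- powers[, 1]; th <- powers[, 2]; a <- powers[, 3]; b <- powers[, 4]
  cbind(
    relaxation = th / pmax(d, RATIO_EPS),
    excitement = b / pmax(a, RATIO_EPS),
    fatigue    = a / pmax(th, RATIO_EPS),
    engagement = b / pmax(th + a, RATIO_EPS)
  )
}

feature_colnames <- function(montage) {
  nm <- c(band_set()$band, c("relaxation", "excitement", "fatigue",
                             "engagement"))
  as.vector(t(outer(montage, nm, paste, sep = "_")))
}

#' Build the per-window feature table of a recording set
#'
#' Runs the whole spectral stage: segments every trial, estimates the Hann
#' periodogram per window, integrates the five band powers and the four
#' band-ratio indices for every montage channel, and attaches the trial's
#' continuous VAD ratings (broadcast to all of its windows) plus their
#' discrete \{-1, 0, 1\} classes.
#'
#' @param rs A `recording_set`.
#' @param spec A [window_spec()].
#' @param bands Band table, default [band_set()].
#' @param montage Channel subset to featurise (default all channels of
#'   `rs`); unknown names are an error.
#' @param rule Discretisation rule for the class labels, default
#'   [discretization_rule()].
#' @param log10_powers If `TRUE`, band powers (not indices) are log10
#'   transformed after a `1e-12` floor. Default `FALSE`.
#' @return A data.frame with key columns `subject`, `trial`, `window`,
#'   `start_s`, then `<channel>_<band>` and `<channel>_<index>` feature
#'   columns, then `valence`, `arousal`, `dominance` and the corresponding
#'   `*_class` columns.
#' @export
build_feature_table <- function(rs, spec = window_spec(), bands = band_set(),
                                montage = NULL, rule = discretization_rule(),
                                log10_powers = FALSE) {
  stopifnot(inherits(rs, "recording_set"))
  if (is.null(montage)) montage <- rs$channel_names
  unknown <- setdiff(montage, rs$channel_names)
  if (length(unknown) > 0) {
    stop("montage channel(s) not in recording: ",
         paste(unknown, collapse = ", "),
         "; valid names: ", paste(rs$channel_names, collapse = ", "))
  }
  comps <- c("valence", "arousal", "dominance")
  out <- vector("list", length(rs$signals) * length(rs$signals[[1]]))
  k <- 0L
  for (subject in names(rs$signals)) {
    for (tr in seq_along(rs$signals[[subject]])) {
      x <- rs$signals[[subject]][[tr]][montage, , drop = FALSE]
      seg <- segment_windows(x, rs$fs, spec)
      nw <- length(seg$windows)
      feats <- matrix(NA_real_, nrow = nw, ncol = 9L * length(montage))
      for (i in seq_len(nw)) {
        ps <- compute_psd(seg$windows[[i]], rs$fs)
        bp <- band_powers(ps$psd, ps$freq, bands, fs = rs$fs)
        ix <- band_ratios(bp)
        if (log10_powers) bp <- log10(pmax(bp, 1e-12))
        feats[i, ] <- as.vector(t(cbind(bp, ix)))
      }
      colnames(feats) <- feature_colnames(montage)
      r <- trial_ratings(rs, subject, tr)
      df <- data.frame(subject = subject, trial = tr,
                       window = seq_len(nw), start_s = seg$start_s,
                       feats, check.names = FALSE,
                       stringsAsFactors = FALSE)
      for (e in comps) {
        df[[e]] <- r[[e]]
        df[[paste0(e, "_class")]] <- discretize_vad(r[[e]], rule)
      }
      k <- k + 1L
      out[[k]] <- df
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Names of the feature columns of a feature table
#'
#' @param ft A feature table from [build_feature_table()].
#' @return Character vector of the `<channel>_<band/index>` columns.
#' @export
feature_columns <- function(ft) {
  setdiff(names(ft),
          c("subject", "trial", "window", "start_s",
            "valence", "arousal", "dominance",
            "valence_class", "arousal_class", "dominance_class"))
}
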