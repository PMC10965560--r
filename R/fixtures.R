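#' Generator configuration for synthetic recordings
#'
#' Shape parameters of the synthetic EEG corpus. The defaults reproduce the
#' layout of the DEAP benchmark that the pipeline targets: 32 subjects, 40
#' one-minute-class trials of 58 s each, 32 channels of the 10-20 system
#' sampled at 128 Hz, one continuous valence/arousal/dominance rating triple
#' (each on a 1-9 scale) per trial.
#'
#' @param n_subjects Number of subjects (default 32).
#' @param n_trials Trials per subject (default 40).
#' @param fs Sampling rate in Hz (default 128).
#' @param trial_duration_s Trial length in seconds (default 58).
#' @param channels Ordered channel labels (default the full 32-channel
#'   montage of [eeg_channels()]). Every label must belong to [lobe_map()].
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_subjects = 32, n_trials = 40, fs = 128,
                             trial_duration_s = 58,
                             channels = eeg_channels()) {
  stopifnot(n_subjects >= 1, n_trials >= 1, fs > 0, trial_duration_s > 0)
  channel_lobes(channels)  # validates labels
  structure(
    list(n_subjects = as.integer(n_subjects),
         n_trials = as.integer(n_trials),
         fs = fs,
         trial_duration_s = trial_duration_s,
         channels = channels),
    class = "generator_config"
  )
}

#' Planted band-power/rating couplings for synthetic recordings
#'
#' Describes the ground truth planted into generated recordings: for each
#' coupling, the amplitude of the band-limited carrier on `channel` in
#' `band` becomes `baseline_amplitude + slope * (rating - 5)` where `rating`
#' is the trial's value of `component`. Uncoupled channel/band pairs keep
#' the rating-independent baseline. Because band power scales with squared
#' amplitude, a positive slope yields a monotone power/rating relation that
#' the selection and classification stages can recover.
#'
#' @param couplings `NULL` (no planted effect) or a data.frame with columns
#'   `channel`, `band`, `component` (one of "valence", "arousal",
#'   "dominance") and `slope` (microvolts per rating unit).
#' @param noise_sd Standard deviation of the additive white noise, in
#'   microvolts (default 1).
#' @param baseline_amplitude Root-mean-square amplitude of every uncoupled
#'   carrier, in microvolts (default 10, a plausible scalp-EEG scale).
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(couplings = NULL, noise_sd = 1,
                        baseline_amplitude = 10) {
  stopifnot(noise_sd >= 0, baseline_amplitude > 0)
  if (!is.null(couplings)) {
    stopifnot(is.data.frame(couplings),
              all(c("channel", "band", "component", "slope") %in%
                    names(couplings)))
    bad_band <- setdiff(couplings$band, band_set()$band)
    if (length(bad_band) > 0) {
      stop("unknown band(s) in couplings: ", paste(bad_band, collapse = ", "))
    }
    bad_comp <- setdiff(couplings$component,
                        c("valence", "arousal", "dominance"))
    if (length(bad_comp) > 0) {
      stop("unknown VAD component(s) in couplings: ",
           paste(bad_comp, collapse = ", "))
    }
    channel_lobes(unique(couplings$channel))
    stopifnot(all(is.finite(couplings$slope)))
  }
  structure(
    list(couplings = couplings, noise_sd = noise_sd,
         baseline_amplitude = baseline_amplitude),
    class = "effect_spec"
  )
}

# band-pass filter bank, one 4th-order Butterworth per band
band_filters <- function(fs, bands = band_set()) {
  lapply(seq_len(nrow(bands)), function(i) {
    signal::butter(4, c(bands$lo_hz[i], bands$hi_hz[i]) / (fs / 2),
                   type = "pass")
  })
}

#' Generate a synthetic recording set with known ground truth
#'
#' Each trial is synthesised as a sum of five band-limited carriers (white
#' noise filtered through a 4th-order Butterworth band-pass at the band
#' edges, normalised to unit RMS) plus white noise. Carrier amplitudes
#' follow the planted couplings of `effect`, so band power carries a known,
#' recoverable relation to the trial's continuous VAD rating. Ratings are
#' drawn uniformly on \[1, 9\] unless supplied.
#'
#' Randomness is reproducible: one master `seed` is expanded into fixed
#' per-subject substreams, so the full corpus is bitwise identical across
#' runs for a given seed, and generating subjects in any order gives each
#' subject the same data.
#'
#' @param config A [generator_config()].
#' @param effect An [effect_spec()].
#' @param seed Integer master seed.
#' @param ratings Optional data.frame `(subject, trial, valence, arousal,
#'   dominance)` overriding the uniform draws; values must lie in \[1, 9\].
#' @return An object of class `recording_set`: a list with `signals` (per
#'   subject, per trial, a channels x samples matrix in microvolts),
#'   `ratings` (data.frame), `channel_names`, `fs` and `trial_duration_s`.
#' @export
generate_recordings <- function(config = generator_config(),
                                effect = effect_spec(),
                                seed = 1L, ratings = NULL) {
  stopifnot(inherits(config, "generator_config"),
            inherits(effect, "effect_spec"))
  seed <- as.integer(seed)
  fs <- config$fs
  n_samp <- round(fs * config$trial_duration_s)
  channels <- config$channels
  bands <- band_set()
  filters <- band_filters(fs, bands)
  comps <- c("valence", "arousal", "dominance")

  if (!is.null(ratings)) {
    stopifnot(all(c("subject", "trial", comps) %in% names(ratings)))
    vals <- unlist(ratings[comps])
    if (any(vals < 1 | vals > 9)) {
      stop("ratings must lie on the 1-9 scale; got value(s) outside [1, 9]")
    }
  }

  # amplitude lookup: slope[channel, band, component]
  slope_arr <- array(0, dim = c(length(channels), nrow(bands), 3),
                     dimnames = list(channels, bands$band, comps))
  if (!is.null(effect$couplings)) {
    cp <- effect$couplings
    for (i in seq_len(nrow(cp))) {
      slope_arr[cp$channel[i], cp$band[i], cp$component[i]] <-
        slope_arr[cp$channel[i], cp$band[i], cp$component[i]] + cp$slope[i]
    }
  }

  subjects <- sprintf("s%02d", seq_len(config$n_subjects))
  signals <- vector("list", config$n_subjects)
  names(signals) <- subjects
  rating_rows <- vector("list", config$n_subjects)

  # burn-in to let the IIR filters settle before the retained samples
  pad <- round(2 * fs)

  for (s in seq_len(config$n_subjects)) {
    # fixed per-subject substream derived from the master seed
    set.seed((seed + 104729L * s) %% 2147483647L)
    trial_list <- vector("list", config$n_trials)
    rt <- matrix(stats::runif(config$n_trials * 3, 1, 9), ncol = 3,
                 dimnames = list(NULL, comps))
    if (!is.null(ratings)) {
      sub_r <- ratings[ratings$subject == subjects[s], , drop = FALSE]
      sub_r <- sub_r[order(sub_r$trial), , drop = FALSE]
      stopifnot(nrow(sub_r) == config$n_trials)
      rt <- as.matrix(sub_r[comps])
    }
    for (tr in seq_len(config$n_trials)) {
      x <- matrix(0, nrow = length(channels), ncol = n_samp,
                  dimnames = list(channels, NULL))
      for (b in seq_len(nrow(bands))) {
        # amplitude per channel for this band and trial
        amp <- rep(effect$baseline_amplitude, length(channels))
        for (e in 1:3) {
          amp <- amp + slope_arr[, b, e] * (rt[tr, e] - 5)
        }
        amp <- pmax(amp, 0.1)
        for (ch in seq_along(channels)) {
          carrier <- signal::filter(filters[[b]],
                                    stats::rnorm(n_samp + pad))
          carrier <- carrier[(pad + 1):(pad + n_samp)]
          carrier <- carrier / stats::sd(carrier)
          x[ch, ] <- x[ch, ] + amp[ch] * carrier
        }
      }
      if (effect$noise_sd > 0) {
        x <- x + matrix(stats::rnorm(length(x), sd = effect$noise_sd),
                        nrow = nrow(x))
      }
      trial_list[[tr]] <- x
    }
    signals[[s]] <- trial_list
    rating_rows[[s]] <- data.frame(subject = subjects[s],
                                   trial = seq_len(config$n_trials),
                                   rt, stringsAsFactors = FALSE)
  }

  structure(
    list(signals = signals,
         ratings = do.call(rbind, rating_rows),
         channel_names = channels,
         fs = fs,
         trial_duration_s = config$trial_duration_s),
    class = "recording_set"
  )
}

#' @export
print.recording_set <- function(x, ...) {
  cat(sprintf(
    "<recording_set> %d subject(s) x %d trial(s), %d channels, %g Hz, %g s\n",
    length(x$signals), length(x$signals[[1]]), length(x$channel_names),
    x$fs, x$trial_duration_s))
  invisible(x)
}

trial_ratings <- function(rs, subject, trial) {
  r <- rs$ratings[rs$ratings$subject == subject & rs$ratings$trial == trial, ]
  stopifnot(nrow(r) == 1)
  r
}

# ---- EDF I/O --------------------------------------------------------------

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

# physical range of the 16-bit encoding, microvolts
EDF_PHYS <- c(-200, 200)
EDF_DIG <- c(-32768L, 32767L)

#' Write / read a recording set as EDF files with a ratings sidecar
#'
#' `write_recording_edf()` stores each (subject, trial) signal matrix as one
#' 16-bit EDF file (`<subject>_t<trial>.edf`, physical range +/-200
#' microvolts, one-second data records) under `path`, plus a sidecar
#' `ratings.csv` with header `subject,trial,valence,arousal,dominance`.
#' `read_recording_edf()` reconstructs the `recording_set`; channel order,
#' sampling rate and samples survive the round trip up to the 16-bit
#' quantisation step (about 0.006 microvolts).
#'
#' @param rs A `recording_set`.
#' @param path Directory to write to / read from.
#' @param channels Channel labels the reader requires; defaults to the full
#'   32-channel montage, and `NULL` accepts whatever valid 10-20 labels the
#'   first file carries. A file whose labels differ triggers a validation
#'   error naming the discrepancy.
#' @return `read_recording_edf()` returns a `recording_set`;
#'   `write_recording_edf()` returns `path` invisibly.
#' @export
write_recording_edf <- function(rs, path) {
  stopifnot(inherits(rs, "recording_set"))
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  dur <- rs$trial_duration_s
  if (abs(dur - round(dur)) > 1e-9) {
    stop("EDF export uses one-second data records; trial duration must be ",
         "an integer number of seconds, got ", dur)
  }
  n_rec <- as.integer(round(dur))
  spr <- as.integer(round(rs$fs))  # samples per record
  if (abs(rs$fs - spr) > 1e-9) stop("sampling rate must be integer Hz for EDF")
  ns <- length(rs$channel_names)

  for (subject in names(rs$signals)) {
    for (tr in seq_along(rs$signals[[subject]])) {
      x <- rs$signals[[subject]][[tr]]
      f <- file.path(path, sprintf("%s_t%02d.edf", subject, tr))
      con <- file(f, "wb")
      header_bytes <- 256L + 256L * ns
      # fixed 256-byte header
      writeChar(paste0(
        edf_pad("0", 8), edf_pad("synthetic subject", 80),
        edf_pad(sprintf("synthetic trial %d", tr), 80),
        "01.01.00", "00.00.00",
        edf_pad(header_bytes, 8), edf_pad("", 44),
        edf_pad(n_rec, 8), edf_pad("1", 8), edf_pad(ns, 4)),
        con, eos = NULL)
      # per-signal header fields, each field for all signals in turn
      writeChar(paste0(
        paste(edf_pad(rs$channel_names, 16), collapse = ""),
        paste(edf_pad(rep("synthetic", ns), 80), collapse = ""),
        paste(edf_pad(rep("uV", ns), 8), collapse = ""),
        paste(edf_pad(rep(EDF_PHYS[1], ns), 8), collapse = ""),
        paste(edf_pad(rep(EDF_PHYS[2], ns), 8), collapse = ""),
        paste(edf_pad(rep(EDF_DIG[1], ns), 8), collapse = ""),
        paste(edf_pad(rep(EDF_DIG[2], ns), 8), collapse = ""),
        paste(edf_pad(rep("none", ns), 80), collapse = ""),
        paste(edf_pad(rep(spr, ns), 8), collapse = ""),
        paste(edf_pad(rep("", ns), 32), collapse = "")),
        con, eos = NULL)
      # digital samples: record-major, signal within record
      scale <- diff(EDF_DIG) / diff(EDF_PHYS)
      xq <- round((pmin(pmax(x, EDF_PHYS[1]), EDF_PHYS[2]) - EDF_PHYS[1]) *
                    scale) + EDF_DIG[1]
      for (r in seq_len(n_rec)) {
        idx <- ((r - 1L) * spr + 1L):(r * spr)
        writeBin(as.integer(t(xq[, idx, drop = FALSE])), con, size = 2,
                 endian = "little")
      }
      close(con)
    }
  }
  utils::write.csv(rs$ratings, file.path(path, "ratings.csv"),
                   row.names = FALSE)
  invisible(path)
}

read_edf_file <- function(f) {
  con <- file(f, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256, useBytes = TRUE)
  field <- function(s, from, len) trimws(substr(s, from, from + len - 1))
  n_rec <- as.integer(field(hdr, 237, 8))
  rec_dur <- as.numeric(field(hdr, 245, 8))
  ns <- as.integer(field(hdr, 253, 4))
  sh <- readChar(con, 256L * ns, useBytes = TRUE)
  grab <- function(offset, width) {
    sapply(seq_len(ns), function(i) {
      trimws(substr(sh, offset + (i - 1L) * width + 1L,
                    offset + i * width))
    })
  }
  pos <- 0L
  labels <- grab(pos, 16L); pos <- pos + 16L * ns
  pos <- pos + 80L * ns    # transducer
  pos <- pos + 8L * ns     # dimension
  phys_min <- as.numeric(grab(pos, 8L)); pos <- pos + 8L * ns
  phys_max <- as.numeric(grab(pos, 8L)); pos <- pos + 8L * ns
  dig_min <- as.numeric(grab(pos, 8L)); pos <- pos + 8L * ns
  dig_max <- as.numeric(grab(pos, 8L)); pos <- pos + 8L * ns
  pos <- pos + 80L * ns    # prefiltering
  spr <- as.integer(grab(pos, 8L))

  x <- matrix(0, nrow = ns, ncol = n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      d <- readBin(con, integer(), n = spr[i], size = 2, endian = "little")
      x[i, ((r - 1L) * spr[i] + 1L):(r * spr[i])] <-
        (d - dig_min[i]) / (dig_max[i] - dig_min[i]) *
        (phys_max[i] - phys_min[i]) + phys_min[i]
    }
  }
  list(labels = labels, fs = spr[1] / rec_dur, x = x,
       duration = n_rec * rec_dur)
}

#' @rdname write_recording_edf
#' @export
read_recording_edf <- function(path, channels = eeg_channels()) {
  sidecar <- file.path(path, "ratings.csv")
  if (!file.exists(sidecar)) {
    stop("labelled-data error: ratings sidecar not found at ", sidecar)
  }
  ratings <- utils::read.csv(sidecar, stringsAsFactors = FALSE)
  vals <- unlist(ratings[c("valence", "arousal", "dominance")])
  if (any(vals < 1 | vals > 9)) {
    stop("sidecar rating(s) outside the 1-9 scale: ",
         paste(round(vals[vals < 1 | vals > 9], 2), collapse = ", "))
  }
  files <- sort(list.files(path, pattern = "\\.edf$", full.names = TRUE))
  if (length(files) == 0) stop("no EDF files under ", path)

  signals <- list()
  fs <- NULL
  dur <- NULL
  for (f in files) {
    e <- read_edf_file(f)
    if (is.null(channels)) {
      channel_lobes(e$labels)  # any valid montage subset is acceptable
      channels <- e$labels
    }
    missing <- setdiff(channels, e$labels)
    extra <- setdiff(e$labels, channels)
    if (length(missing) > 0 || length(extra) > 0) {
      stop("channel labels in ", basename(f),
           " do not match the expected montage",
           if (length(missing) > 0)
             paste0("; missing: ", paste(missing, collapse = ", ")),
           if (length(extra) > 0)
             paste0("; unexpected: ", paste(extra, collapse = ", ")))
    }
    m <- regmatches(basename(f),
                    regexec("^(.*)_t([0-9]+)\\.edf$", basename(f)))[[1]]
    if (length(m) != 3) stop("unrecognised EDF file name: ", basename(f))
    subject <- m[2]
    tr <- as.integer(m[3])
    rownames(e$x) <- e$labels
    x <- e$x[channels, , drop = FALSE]  # restore canonical order
    if (is.null(fs)) { fs <- e$fs; dur <- e$duration }
    signals[[subject]][[tr]] <- x
  }
  structure(
    list(signals = signals, ratings = ratings, channel_names = channels,
         fs = fs, trial_duration_s = dur),
    class = "recording_set"
  )
}
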