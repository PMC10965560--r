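#' Streaming-loop configuration
#'
#' @param montage Eight channel labels, default [reference_channels_8()].
#' @param source_fs Acquisition rate of the (replayed) source in Hz,
#'   default 250 (Cyton-board-like).
#' @param target_fs Processing rate in Hz, default 128.
#' @param buffer_s Buffer length per prediction in seconds, default 5.
#' @param emit_period_s Seconds of stream time per emitted prediction,
#'   default 5 (non-overlapping buffers).
#' @param chunk_s Chunk duration yielded by the source, default 0.2.
#' @return An object of class `stream_config`.
#' @export
stream_config <- function(montage = reference_channels_8(),
                          source_fs = 250, target_fs = 128,
                          buffer_s = 5, emit_period_s = 5, chunk_s = 0.2) {
  stopifnot(length(montage) == 8, target_fs <= source_fs,
            abs(buffer_s * target_fs - round(buffer_s * target_fs)) < 1e-9,
            emit_period_s >= buffer_s)
  channel_lobes(montage)
  structure(list(montage = montage, source_fs = source_fs,
                 target_fs = target_fs, buffer_s = buffer_s,
                 emit_period_s = emit_period_s, chunk_s = chunk_s),
            class = "stream_config")
}

#' Replay a recorded trial as a chunked stream source
#'
#' Returns an iterator closure that yields successive channels x samples
#' chunks of `chunk_s` seconds at `source_fs`, restricted to the montage,
#' then `NULL` when exhausted — the same contract a live acquisition
#' adapter would implement. If `source_fs` differs from the recording rate
#' the trial is resampled (polyphase anti-aliased) before chunking.
#'
#' @param rs A `recording_set`.
#' @param subject,trial Which trial to replay.
#' @param cfg A [stream_config()].
#' @return A function; each call returns the next chunk or `NULL`.
#' @export
stream_from_recording <- function(rs, subject, trial,
                                  cfg = stream_config()) {
  missing <- setdiff(cfg$montage, rs$channel_names)
  if (length(missing) > 0) {
    stop("montage channel(s) absent from recording: ",
         paste(missing, collapse = ", "))
  }
  x <- rs$signals[[subject]][[trial]][cfg$montage, , drop = FALSE]
  x <- resample_matrix(x, rs$fs, cfg$source_fs)
  chunk_n <- round(cfg$chunk_s * cfg$source_fs)
  pos <- 0L
  function() {
    if (pos >= ncol(x)) return(NULL)
    upto <- min(pos + chunk_n, ncol(x))  # final chunk may be partial
    out <- x[, (pos + 1L):upto, drop = FALSE]
    pos <<- upto
    out
  }
}

# polyphase resampling of each row from fs_in to fs_out
resample_matrix <- function(x, fs_in, fs_out) {
  if (abs(fs_in - fs_out) < 1e-9) return(x)
  g <- function(a, b) if (b == 0) a else g(b, a %% b)
  d <- g(round(fs_out * 1000), round(fs_in * 1000))
  p <- round(fs_out * 1000) / d
  q <- round(fs_in * 1000) / d
  t(apply(x, 1, function(row) signal::resample(row, p, q)))
}

#' Pre-process one raw buffer for feature extraction
#'
#' The standard conditioning chain: anti-aliased resampling from the
#' source rate to `target_fs`, zero-phase (forward-backward) 4th-order
#' Butterworth band-pass 0.4-45 Hz, and common average referencing
#' (subtracting the across-channel mean at every sample, so the output
#' channel mean is zero).
#'
#' @param buffer Channels x samples matrix at `cfg$source_fs`.
#' @param cfg A [stream_config()].
#' @return Channels x samples matrix at `cfg$target_fs`.
#' @export
preprocess_buffer <- function(buffer, cfg = stream_config()) {
  stopifnot(is.matrix(buffer))
  if (ncol(buffer) < round(cfg$source_fs)) {
    stop("buffer shorter than the 1 s filter warm-up")
  }
  x <- resample_matrix(buffer, cfg$source_fs, cfg$target_fs)
  bp <- signal::butter(4, c(0.4, 45) / (cfg$target_fs / 2), type = "pass")
  x <- t(apply(x, 1, function(row) signal::filtfilt(bp, row)))
  sweep(x, 2, colMeans(x))  # common average reference
}

#' Predict the emotion of one pre-processed 5-second buffer
#'
#' Computes the per-channel band powers and band-ratio indices of the
#' buffer, subsets each component's stored feature list, runs the three
#' classifiers and maps the resulting discrete triple through the emotion
#' inventory. The feature path is the same code the offline
#' [build_feature_table()] uses, so streaming and offline predictions of
#' the same window agree exactly.
#'
#' @param buffer Channels x samples matrix at `cfg$target_fs`, rows named
#'   (or ordered) as `cfg$montage`.
#' @param vm A `vad_models` bundle whose montage matches `cfg$montage`.
#' @param cfg A [stream_config()].
#' @param timestamp_s Stream time attached to the prediction.
#' @return A one-row data.frame (`t`, `arousal`, `valence`, `dominance`,
#'   `emotion`, `descartes`).
#' @export
predict_buffer <- function(buffer, vm, cfg = stream_config(),
                           timestamp_s = NA_real_) {
  stopifnot(inherits(vm, "vad_models"))
  if (!setequal(vm$metadata$montage, cfg$montage)) {
    stop("model bundle was trained on montage {",
         paste(vm$metadata$montage, collapse = ", "),
         "} but the stream uses {", paste(cfg$montage, collapse = ", "), "}")
  }
  rownames(buffer) <- cfg$montage
  ps <- compute_psd(buffer, cfg$target_fs)
  bp <- band_powers(ps$psd, ps$freq, fs = cfg$target_fs)
  ix <- band_ratios(bp)
  feats <- matrix(as.vector(t(cbind(bp, ix))), nrow = 1,
                  dimnames = list(NULL, feature_colnames(cfg$montage)))
  triple <- drop(predict_vad(vm, as.data.frame(feats, check.names = FALSE)))
  emo <- triple_to_emotion(triple[c("arousal", "valence", "dominance")])
  data.frame(t = timestamp_s,
             arousal = triple[["arousal"]], valence = triple[["valence"]],
             dominance = triple[["dominance"]],
             emotion = emo$emotion, descartes = emo$descartes,
             stringsAsFactors = FALSE)
}

#' Run the buffered real-time prediction loop
#'
#' Pulls chunks from a source iterator, accumulates `emit_period_s`
#' seconds of stream time, pre-processes the trailing `buffer_s`-second
#' buffer and emits one prediction per period. A trailing partial buffer
#' at source exhaustion is dropped with a message. On a complete replay
#' of a `D`-second trial this emits `floor(D / emit_period_s)`
#' predictions.
#'
#' @param source Chunk iterator, e.g. from [stream_from_recording()].
#' @param vm A `vad_models` bundle.
#' @param cfg A [stream_config()].
#' @param sink Optional path; `.jsonl` gets JSON-lines records
#'   (`{"t": ..., "vad": [a, v, d], "emotion": ..., "descartes": ...}`),
#'   anything else CSV.
#' @return Data.frame of predictions, one row per emitted period.
#' @export
run_stream <- function(source, vm, cfg = stream_config(), sink = NULL) {
  period_n <- round(cfg$emit_period_s * cfg$source_fs)
  buffer_n <- round(cfg$buffer_s * cfg$source_fs)
  acc <- NULL
  t_emit <- cfg$emit_period_s
  out <- list()
  repeat {
    chunk <- source()
    if (is.null(chunk)) {
      if (!is.null(acc) && ncol(acc) > 0) {
        message("source exhausted mid-buffer; dropping ", ncol(acc),
                " trailing samples")
      }
      break
    }
    acc <- if (is.null(acc)) chunk else cbind(acc, chunk)
    while (ncol(acc) >= period_n) {
      raw <- acc[, (period_n - buffer_n + 1):period_n, drop = FALSE]
      buf <- preprocess_buffer(raw, cfg)
      out[[length(out) + 1L]] <-
        predict_buffer(buf, vm, cfg, timestamp_s = t_emit)
      acc <- acc[, -seq_len(period_n), drop = FALSE]
      t_emit <- t_emit + cfg$emit_period_s
    }
  }
  preds <- do.call(rbind, out)
  if (!is.null(sink) && length(out) > 0) {
    if (grepl("\\.jsonl$", sink)) {
      lines <- vapply(seq_len(nrow(preds)), function(i) {
        jsonlite::toJSON(list(t = preds$t[i],
                              vad = c(preds$arousal[i], preds$valence[i],
                                      preds$dominance[i]),
                              emotion = preds$emotion[i],
                              descartes = preds$descartes[i]),
                         auto_unbox = TRUE)
      }, character(1))
      writeLines(lines, sink)
    } else {
      utils::write.csv(preds, sink, row.names = FALSE)
    }
  }
  preds
}
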