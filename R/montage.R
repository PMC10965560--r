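#' Standard 32-channel 10-20 montage
#'
#' The 32 scalp electrodes of the extended 10-20 system used throughout the
#' package, ordered lobe by lobe (frontal, temporal, parietal, occipital,
#' central, central-parietal). This is the union of the rows of [lobe_map()].
#'
#' @return Character vector of 32 channel labels.
#' @seealso [lobe_map()], [reference_channels_8()]
#' @export
#' @examples
#' eeg_channels()
eeg_channels <- function() {
  unlist(lobe_map(), use.names = FALSE)
}

#' Anatomical lobe grouping of the 32-channel montage
#'
#' Assignment of the 32 electrodes to six anatomical groups used for
#' lobe-wise PCA: Frontal (9 channels), Temporal (2), Parietal (7),
#' Occipital (3), Central (7) and Central-Parietal (4). Lobes are disjoint
#' and their union is the full montage.
#'
#' @return Named list of character vectors, one per lobe.
#' @export
lobe_map <- function() {
  list(
    Frontal          = c("Fp1", "Fp2", "F3", "F4", "F7", "F8", "Fz", "AF3", "AF4"),
    Temporal         = c("T7", "T8"),
    Parietal         = c("P3", "P4", "P7", "P8", "Pz", "PO3", "PO4"),
    Occipital        = c("O1", "O2", "Oz"),
    Central          = c("FC5", "FC1", "C3", "C4", "FC2", "FC6", "Cz"),
    `Central-Parietal` = c("CP5", "CP1", "CP2", "CP6")
  )
}

#' The five canonical EEG frequency bands
#'
#' delta 0.5-4 Hz, theta 4-8 Hz, alpha 8-12 Hz, beta 12-30 Hz and
#' gamma 30-45 Hz. Band intervals are half-open `[lo, hi)` when binning
#' PSD estimates, so a bin at exactly 4 Hz belongs to theta, not delta.
#'
#' @return A data.frame with columns `band`, `lo_hz`, `hi_hz`.
#' @export
band_set <- function() {
  data.frame(
    band  = c("delta", "theta", "alpha", "beta", "gamma"),
    lo_hz = c(0.5, 4, 8, 12, 30),
    hi_hz = c(4, 8, 12, 30, 45),
    stringsAsFactors = FALSE
  )
}

#' Reference eight-channel montage for portable acquisition
#'
#' The eight-channel electrode set selected by the Emotion Importance Index
#' ranking on the full 32-channel montage: four frontal channels (Fp1, F7,
#' FC5, FC6), both temporals (T7, T8), one parietal (P7) and one occipital
#' (O2). This is the default montage of the streaming loop.
#'
#' @return Character vector of 8 channel labels.
#' @export
reference_channels_8 <- function() {
  c("Fp1", "F7", "FC5", "FC6", "T7", "T8", "P7", "O2")
}

# map each channel to its lobe; errors on unknown labels
channel_lobes <- function(channels) {
  lm <- lobe_map()
  lookup <- rep(names(lm), lengths(lm))
  names(lookup) <- unlist(lm, use.names = FALSE)
  unknown <- setdiff(channels, names(lookup))
  if (length(unknown) > 0) {
    stop("unknown channel label(s): ", paste(unknown, collapse = ", "),
         "; valid labels are: ", paste(names(lookup), collapse = ", "))
  }
  unname(lookup[channels])
}
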