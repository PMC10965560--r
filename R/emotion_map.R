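# cache for the packaged emotion table
.emorec_env <- new.env(parent = emptyenv())

#' Discretisation rule for continuous 1-9 VAD ratings
#'
#' Ratings between 1 and 3.6 are "low" (-1), between 3.7 and 6.3 "medium"
#' (0) and between 6.4 and 9 "high" (+1). Those bins leave the open gaps
#' (3.6, 3.7) and (6.3, 6.4) undefined on a continuous scale; the effective
#' cut points `t1`, `t2` default to the gap midpoints 3.65 and 6.35 so the
#' mapping is total while agreeing with the stated bins everywhere they
#' apply.
#'
#' @param t1,t2 Effective low/medium and medium/high cut points.
#' @return An object of class `discretization_rule`.
#' @export
discretization_rule <- function(t1 = 3.65, t2 = 6.35) {
  stopifnot(t1 > 3.6, t1 <= 3.7, t2 > 6.3, t2 <= 6.4)
  structure(list(low_upper = 3.6, mid_lower = 3.7, mid_upper = 6.3,
                 high_lower = 6.4, t1 = t1, t2 = t2),
            class = "discretization_rule")
}

#' Discretise continuous VAD ratings to \{-1, 0, 1\}
#'
#' @param rating Numeric rating(s) on the 1-9 scale.
#' @param rule A [discretization_rule()].
#' @return Integer vector in \{-1, 0, 1\}: below `t1` maps to -1, below
#'   `t2` to 0, otherwise to 1. Monotone non-decreasing in the rating.
#' @export
#' @examples
#' discretize_vad(c(2, 5, 9))
discretize_vad <- function(rating, rule = discretization_rule()) {
  if (any(!is.finite(rating)) || any(rating < 1) || any(rating > 9)) {
    stop("rating must lie on the 1-9 scale")
  }
  ifelse(rating < rule$t1, -1L, ifelse(rating < rule$t2, 0L, 1L))
}

#' The 27-cell emotion inventory of the discrete VAD cube
#'
#' Every (arousal, valence, dominance) triple in \{-1, 0, 1\}^3 with its
#' named emotion. Six cells carry Descartes' fundamental passions (Desire,
#' Admiration, Joy, Love, Hate, Sadness); nine unnamed cells are "Other".
#' The table ships as a package data file (`extdata/emotion_map.csv`) so it
#' can be audited directly.
#'
#' @return Data.frame with columns `arousal`, `valence`, `dominance`
#'   (integers in -1..1), `emotion` (character) and `descartes` (logical),
#'   in stable packaged order.
#' @export
emotion_inventory <- function() {
  if (is.null(.emorec_env$emotion_map)) {
    f <- system.file("extdata", "emotion_map.csv", package = "emorec",
                     mustWork = TRUE)
    m <- utils::read.csv(f, stringsAsFactors = FALSE)
    m$arousal <- as.integer(m$arousal)
    m$valence <- as.integer(m$valence)
    m$dominance <- as.integer(m$dominance)
    stopifnot(nrow(m) == 27, sum(m$descartes) == 6,
              !anyDuplicated(m[c("arousal", "valence", "dominance")]))
    .emorec_env$emotion_map <- m
  }
  .emorec_env$emotion_map
}

#' Map a discrete (arousal, valence, dominance) triple to its emotion
#'
#' Total lookup in the 27-entry inventory; key order is (Arousal, Valence,
#' Dominance).
#'
#' @param triple Integer vector of length 3, each element in \{-1, 0, 1\},
#'   ordered (arousal, valence, dominance).
#' @return One row of [emotion_inventory()] as a list with fields
#'   `arousal`, `valence`, `dominance`, `emotion`, `descartes`.
#' @export
#' @examples
#' triple_to_emotion(c(0, 1, 0))$emotion   # "Desire"
triple_to_emotion <- function(triple) {
  if (length(triple) != 3 || !all(triple %in% c(-1L, 0L, 1L))) {
    stop("triple must be three values in {-1, 0, 1}, ordered ",
         "(arousal, valence, dominance)")
  }
  m <- emotion_inventory()
  row <- m[m$arousal == triple[1] & m$valence == triple[2] &
             m$dominance == triple[3], ]
  as.list(row[1, ])
}
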