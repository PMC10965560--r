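#' First principal component of one subject/lobe/band feature block
#'
#' Columns (member-channel band powers) are centred per subject, the first
#' right singular vector `V1` of the centred matrix is taken as the loading
#' vector, and the block is compressed to the projected series
#' `Z = X_centred %*% V1`. `V1` has unit norm and maximises projected
#' variance among unit vectors; its sign is fixed so the largest-magnitude
#' loading is positive, making artifacts reproducible (downstream
#' correlations use absolute values and are sign-invariant anyway).
#'
#' @param x Windows x member-channels numeric matrix (>= 2 rows).
#' @return List with `v1` (unit loading vector, named by column) and `z`
#'   (projected series, one value per window). A zero-variance block
#'   degenerates to an arbitrary unit loading with `z = 0` and a warning.
#' @export
lobe_pca_first_component <- function(x) {
  stopifnot(is.matrix(x) || is.data.frame(x))
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 windows for PCA")
  xc <- sweep(x, 2, colMeans(x))
  if (max(abs(xc)) < 1e-300) {
    warning("zero-variance block; returning arbitrary unit loading, z = 0")
    v1 <- c(1, rep(0, ncol(x) - 1))
    names(v1) <- colnames(x)
    return(list(v1 = v1, z = rep(0, nrow(x))))
  }
  sv <- svd(xc, nu = 0, nv = 1)
  v1 <- sv$v[, 1]
  if (v1[which.max(abs(v1))] < 0) v1 <- -v1
  names(v1) <- colnames(x)
  list(v1 = v1, z = drop(xc %*% v1))
}

#' Mean absolute Pearson correlation across subjects
#'
#' For each subject the Pearson correlation between that subject's
#' projected series and rating series is computed, its absolute value
#' taken, and the result averaged over subjects, giving a value in
#' \[0, 1\]. Subjects with a constant series (undefined correlation) are
#' excluded from the average with a warning.
#'
#' @param z_list List of per-subject projected series.
#' @param y_list List of per-subject rating series (same lengths).
#' @return Mean absolute correlation in \[0, 1\].
#' @export
mean_abs_corr <- function(z_list, y_list) {
  stopifnot(length(z_list) == length(y_list))
  rs <- mapply(function(z, y) {
    stopifnot(length(z) == length(y))
    if (stats::sd(z) == 0 || stats::sd(y) == 0) return(NA_real_)
    abs(stats::cor(z, y))
  }, z_list, y_list)
  if (anyNA(rs)) {
    warning(sum(is.na(rs)), " subject(s) with a constant series excluded ",
            "from the correlation average")
    rs <- rs[!is.na(rs)]
  }
  if (length(rs) == 0) stop("no subject with non-degenerate series")
  mean(rs)
}

#' Lobe x band x component correlation table
#'
#' For every (lobe, band) cell, each subject's member-channel band powers
#' are compressed to their first principal component and correlated with
#' each continuous VAD component (windows inherit their trial's rating);
#' absolute coefficients are averaged over subjects. The `sum` column adds
#' the three components, the overall importance score used to pick the best
#' band.
#'
#' @param ft Feature table from [build_feature_table()] on the full
#'   montage.
#' @param lobes Lobe grouping, default [lobe_map()].
#' @param bands Band table, default [band_set()].
#' @return A data.frame (`lobe`, `band`, `arousal`, `valence`, `dominance`,
#'   `sum`) with one row per lobe/band cell.
#' @export
correlation_table <- function(ft, lobes = lobe_map(), bands = band_set()) {
  missing <- setdiff(unlist(lobes), sub("_delta$", "",
                     grep("_delta$", names(ft), value = TRUE)))
  if (length(missing) > 0) {
    stop("feature table lacks lobe member channel(s): ",
         paste(missing, collapse = ", "))
  }
  subjects <- unique(ft$subject)
  comps <- c("valence", "arousal", "dominance")
  sub_rows <- split(seq_len(nrow(ft)), ft$subject)

  out <- expand.grid(lobe = names(lobes), band = bands$band,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  for (e in c("arousal", "valence", "dominance")) out[[e]] <- NA_real_
  for (i in seq_len(nrow(out))) {
    cols <- paste(lobes[[out$lobe[i]]], out$band[i], sep = "_")
    z_list <- lapply(subjects, function(s) {
      lobe_pca_first_component(as.matrix(ft[sub_rows[[s]], cols]))$z
    })
    for (e in c("arousal", "valence", "dominance")) {
      y_list <- lapply(subjects, function(s) ft[[e]][sub_rows[[s]]])
      out[[e]][i] <- mean_abs_corr(z_list, y_list)
    }
  }
  out$sum <- out$arousal + out$valence + out$dominance
  out
}

#' Best frequency band by summed correlation
#'
#' Sums the per-(lobe, band) three-component correlation totals over lobes
#' and returns the band with the largest total; ties break toward the
#' higher-frequency band.
#'
#' @param ct Table from [correlation_table()].
#' @return Band name (e.g. `"gamma"`).
#' @export
best_band <- function(ct) {
  stopifnot(all(c("band", "sum") %in% names(ct)))
  bands <- band_set()$band
  totals <- vapply(bands, function(b) sum(ct$sum[ct$band == b]), 0)
  if (anyNA(totals)) stop("incomplete correlation table")
  # ties toward higher frequency: scan from gamma down
  bands[rev(seq_along(bands))][which.max(rev(totals))]
}

#' Per-channel Gini importance table from random-forest regression
#'
#' For each VAD component and each subject, `iterations` random-forest
#' regressors with different seeds are fitted on the 32 best-band channel
#' powers against the continuous rating; impurity (MSE-criterion) variable
#' importances are normalised to sum to one per fit, averaged over
#' iterations, then over subjects. Each component's importance vector
#' therefore sums to one.
#'
#' @param ft Feature table on the full montage.
#' @param band Band whose channel powers are used (normally the
#'   [best_band()], gamma).
#' @param iterations Random restarts per subject, default 10.
#' @param seed Base seed; iteration `i` uses `seed + i - 1`.
#' @param num_trees Trees per forest, default 100.
#' @param channels Channel set, default the full montage.
#' @return Data.frame (`channel`, `arousal`, `valence`, `dominance`), each
#'   importance column summing to 1.
#' @export
gi_table <- function(ft, band = "gamma", iterations = 10, seed = 1,
                     num_trees = 100, channels = eeg_channels()) {
  cols <- paste(channels, band, sep = "_")
  missing <- setdiff(cols, names(ft))
  if (length(missing) > 0) {
    stop("feature table lacks column(s): ", paste(missing, collapse = ", "))
  }
  subjects <- unique(ft$subject)
  counts <- table(ft$subject)
  if (any(counts < 10)) {
    stop("insufficient data: every subject needs >= 10 windows, got min ",
         min(counts))
  }
  comps <- c("arousal", "valence", "dominance")
  out <- data.frame(channel = channels, stringsAsFactors = FALSE)
  for (e in comps) {
    acc <- numeric(length(channels))
    for (s in subjects) {
      rows <- ft$subject == s
      x <- as.matrix(ft[rows, cols])
      colnames(x) <- channels
      y <- ft[[e]][rows]
      gi_s <- numeric(length(channels))
      for (i in seq_len(iterations)) {
        # all features are candidates at every split (the usual
        # regression-forest default), so importance concentrates on the
        # predictive channels instead of diffusing over noise
        fit <- ranger::ranger(x = x, y = y, num.trees = num_trees,
                              mtry = ncol(x), importance = "impurity",
                              seed = seed + i - 1, num.threads = 1)
        imp <- fit$variable.importance
        gi_s <- gi_s + imp / sum(imp)
      }
      acc <- acc + gi_s / iterations
    }
    out[[e]] <- acc / length(subjects)
  }
  out
}

#' Emotion Importance Index ranking and top-k channel selection
#'
#' The EII of a channel is the unweighted mean of its three per-component
#' Gini importances; since each component's importances sum to one, the EII
#' column sums to one as well. Channels are ranked by descending EII (ties
#' broken alphabetically) and the top `k` form the selected montage.
#'
#' @param gi Table from [gi_table()].
#' @param k Number of channels to select, default 8.
#' @return List with `ranking` (data.frame `channel`, `arousal`, `valence`,
#'   `dominance`, `eii`, sorted) and `selected` (character vector of `k`
#'   channel names in rank order).
#' @export
eii_ranking <- function(gi, k = 8) {
  stopifnot(all(c("channel", "arousal", "valence", "dominance") %in%
                  names(gi)))
  if (k > nrow(gi)) stop("k = ", k, " exceeds the ", nrow(gi),
                         " available channels")
  gi$eii <- (gi$arousal + gi$valence + gi$dominance) / 3
  ord <- order(-gi$eii, gi$channel)
  ranking <- gi[ord, c("channel", "arousal", "valence", "dominance", "eii")]
  rownames(ranking) <- NULL
  list(ranking = ranking, selected = ranking$channel[seq_len(k)])
}
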