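#' Shift-based cross-validation split specification
#'
#' Intra-subject splitting into contiguous 60:20:20 train/validation/test
#' blocks, repeated over `folds` folds by circularly rotating the sample
#' indices by a fold-dependent offset `phi(fold) = fold * floor(n /
#' folds)`, so each fold sees a different partition of the same ordered
#' data. The validation block is reserved for hyperparameter choices and
#' unused by the default evaluation, which reports test-block metrics.
#'
#' @param train,validation,test Block fractions, summing to 1.
#' @param folds Number of shifts, default 8.
#' @param stride Training-row decimation stride used by model-comparison
#'   runs (every `stride`-th training row), default 16. Final-model
#'   training does not decimate.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(train = 0.6, validation = 0.2, test = 0.2,
                       folds = 8, stride = 16) {
  stopifnot(abs(train + validation + test - 1) < 1e-9, folds >= 1,
            stride >= 1)
  structure(list(train = train, validation = validation, test = test,
                 folds = as.integer(folds), stride = as.integer(stride)),
            class = "split_spec")
}

#' Train/validation/test indices for one shift fold
#'
#' @param n Number of samples.
#' @param spec A [split_spec()].
#' @param fold Zero-based fold index in `0 .. folds - 1`.
#' @return List of integer index vectors `train`, `validation`, `test`;
#'   pairwise disjoint, jointly covering `1..n`.
#' @export
shift_split <- function(n, spec = split_spec(), fold = 0) {
  stopifnot(fold >= 0, fold < spec$folds, n >= spec$folds)
  n_train <- floor(spec$train * n)
  n_val <- floor(spec$validation * n)
  n_test <- n - n_train - n_val
  if (n_train < 1 || n_val < 1 || n_test < 1) {
    stop("n = ", n, " too small for nonempty 60:20:20 blocks")
  }
  phi <- fold * floor(n / spec$folds)
  idx <- ((seq_len(n) - 1 + phi) %% n) + 1
  list(train = idx[seq_len(n_train)],
       validation = idx[n_train + seq_len(n_val)],
       test = idx[n_train + n_val + seq_len(n_test)])
}

#' Classification metrics from true and predicted labels
#'
#' Accuracy is the fraction of correct predictions. Precision, recall and
#' F1 are computed one-vs-rest per class from the TP/FP/FN counts, and the
#' macro F1 is their unweighted class mean. A class absent from both the
#' truth and the predictions is skipped in the macro mean with a message.
#'
#' @param y_true,y_pred Equal-length label vectors (classes -1, 0, 1).
#' @return List with `accuracy`, `per_class` (data.frame `class`, `tp`,
#'   `fp`, `fn`, `tn`, `precision`, `recall`, `f1`) and `macro_f1`.
#' @export
compute_metrics <- function(y_true, y_pred) {
  if (length(y_true) == 0) stop("empty input")
  stopifnot(length(y_true) == length(y_pred))
  classes <- c(-1L, 0L, 1L)
  per <- lapply(classes, function(k) {
    tp <- sum(y_true == k & y_pred == k)
    fp <- sum(y_true != k & y_pred == k)
    fn <- sum(y_true == k & y_pred != k)
    tn <- sum(y_true != k & y_pred != k)
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (precision + recall > 0) {
      2 * precision * recall / (precision + recall)
    } else 0
    data.frame(class = k, tp = tp, fp = fp, fn = fn, tn = tn,
               precision = precision, recall = recall, f1 = f1)
  })
  per <- do.call(rbind, per)
  present <- per$tp + per$fn + per$fp > 0
  if (!all(present)) {
    message("class(es) ", paste(per$class[!present], collapse = ", "),
            " absent from truth and predictions; skipped in macro F1")
  }
  list(accuracy = mean(y_true == y_pred),
       per_class = per,
       macro_f1 = mean(per$f1[present]))
}

#' Classifier specification
#'
#' @param family One of `"extra_trees"`, `"random_forest"`, `"xgboost"`,
#'   `"knn"`, `"svc"`.
#' @param params Named list of hyperparameters. Defaults: 100 trees for the
#'   tree ensembles, `nrounds = 50` for xgboost, `k = 5` for kNN, RBF
#'   kernel with `cost = 1` for the SVC.
#' @param seed Integer seed for the stochastic families.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(family, params = list(), seed = 1L) {
  family <- match.arg(family, c("extra_trees", "random_forest", "xgboost",
                                "knn", "svc"))
  structure(list(family = family, params = params, seed = as.integer(seed)),
            class = "model_spec")
}

vad_levels <- c("-1", "0", "1")

#' Fit a 3-class classifier
#'
#' @param spec A [model_spec()].
#' @param x Numeric feature matrix.
#' @param y Integer labels in \{-1, 0, 1\}.
#' @return A fitted-model object of class `emorec_fit` for
#'   [predict_model()].
#' @export
fit_model <- function(spec, x, y) {
  stopifnot(inherits(spec, "model_spec"))
  x <- as.matrix(x)
  # keep only observed classes (a fold may lack one); predictions are mapped
  # back through the level labels
  yf <- factor(as.character(y),
               levels = intersect(vad_levels, as.character(y)))
  p <- spec$params
  fit <- switch(
    spec$family,
    extra_trees = ranger::ranger(
      x = x, y = yf, num.trees = p$num_trees %||% 100,
      splitrule = "extratrees", num.random.splits = p$num_random_splits %||% 1,
      replace = FALSE, sample.fraction = 1,
      seed = spec$seed, num.threads = 1),
    random_forest = ranger::ranger(
      x = x, y = yf, num.trees = p$num_trees %||% 100,
      seed = spec$seed, num.threads = 1),
    xgboost = xgboost::xgb.train(
      params = list(objective = "multi:softmax",
                    num_class = length(levels(yf)),
                    max_depth = p$max_depth %||% 6,
                    eta = p$eta %||% 0.3,
                    nthread = 1, seed = spec$seed),
      data = xgboost::xgb.DMatrix(x, label = as.integer(yf) - 1L),
      nrounds = p$nrounds %||% 50, verbose = 0),
    knn = list(x = x, y = yf, k = p$k %||% 5),
    svc = e1071::svm(x = x, y = yf, kernel = "radial",
                     cost = p$cost %||% 1, scale = TRUE)
  )
  structure(list(family = spec$family, fit = fit,
                 levels = levels(yf), feature_names = colnames(x)),
            class = "emorec_fit")
}

#' Predict 3-class labels from a fitted classifier
#'
#' @param model An `emorec_fit` from [fit_model()].
#' @param x Feature matrix with the training columns.
#' @return Integer labels in \{-1, 0, 1\}.
#' @export
predict_model <- function(model, x) {
  stopifnot(inherits(model, "emorec_fit"))
  x <- as.matrix(x)
  if (!is.null(model$feature_names)) {
    x <- x[, model$feature_names, drop = FALSE]
  }
  lab <- switch(
    model$family,
    extra_trees = ,
    random_forest = as.character(stats::predict(
      model$fit, data = x, num.threads = 1, seed = 1L)$predictions),
    xgboost = model$levels[stats::predict(
      model$fit, xgboost::xgb.DMatrix(x)) + 1L],
    knn = {
      # knn breaks distance ties at random; pin the stream and restore it
      old <- if (exists(".Random.seed", globalenv())) {
        get(".Random.seed", globalenv())
      }
      set.seed(20201L)
      p <- as.character(class::knn(model$fit$x, x, model$fit$y,
                                   k = model$fit$k))
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
      p
    },
    svc = as.character(stats::predict(model$fit, x))
  )
  as.integer(lab)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compare classifier families under shift-based cross-validation
#'
#' For each VAD component and each fold, fits every model on the
#' (stride-decimated) training block and scores it on the test block.
#' Folds whose training block holds a single class are skipped with a
#' message.
#'
#' @param ft Feature table with discrete `*_class` labels.
#' @param specs Named list of [model_spec()]s; default all five families.
#' @param split A [split_spec()].
#' @param components VAD components to evaluate.
#' @param features Feature columns to use, default all.
#' @return Data.frame (`model`, `component`, `fold`, `accuracy`,
#'   `macro_f1`); summarise with [summarize_evaluation()].
#' @export
evaluate_models <- function(ft, specs = default_model_specs(),
                            split = split_spec(),
                            components = c("valence", "arousal", "dominance"),
                            features = feature_columns(ft)) {
  x_all <- as.matrix(ft[features])
  out <- list()
  for (e in components) {
    y_all <- ft[[paste0(e, "_class")]]
    for (fold in 0:(split$folds - 1)) {
      idx <- shift_split(nrow(ft), split, fold)
      tr <- idx$train[seq(1, length(idx$train), by = split$stride)]
      if (length(unique(y_all[tr])) < 2) {
        message("fold ", fold, " (", e, "): single-class training block, ",
                "skipped")
        next
      }
      for (m in names(specs)) {
        fit <- fit_model(specs[[m]], x_all[tr, , drop = FALSE], y_all[tr])
        met <- compute_metrics(y_all[idx$test],
                               predict_model(fit, x_all[idx$test, ,
                                                        drop = FALSE]))
        out[[length(out) + 1L]] <- data.frame(
          model = m, component = e, fold = fold,
          accuracy = met$accuracy, macro_f1 = met$macro_f1,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Default specifications of the five compared families
#'
#' @param seed Shared seed.
#' @return Named list of [model_spec()]s: extra_trees, random_forest,
#'   xgboost, knn, svc.
#' @export
default_model_specs <- function(seed = 1L) {
  fams <- c("extra_trees", "random_forest", "xgboost", "knn", "svc")
  stats::setNames(lapply(fams, model_spec, seed = seed), fams)
}

#' Mean metrics per model and component across folds
#'
#' @param report Output of [evaluate_models()].
#' @return Data.frame (`model`, `component`, `accuracy`, `macro_f1`).
#' @export
summarize_evaluation <- function(report) {
  agg <- stats::aggregate(cbind(accuracy, macro_f1) ~ model + component,
                          data = report, FUN = mean)
  agg[order(agg$model, agg$component), ]
}

#' Sweep analysis-window lengths
#'
#' Rebuilds the feature table for each candidate window length
#' (non-overlapping windows) and evaluates the models; reports the mean
#' test accuracy per (length, model) cell averaged across folds and
#' components. The winner is the cell-wise best length, ties to the
#' shortest.
#'
#' @param rs A `recording_set`.
#' @param lengths Window lengths in seconds, default `c(2, 4, 5, 8, 10)`.
#' @param specs,split,montage Passed to the feature/evaluation stages.
#' @return List with `grid` (data.frame `length_s`, `model`, `accuracy`)
#'   and `best_length_s`.
#' @export
window_sweep <- function(rs, lengths = c(2, 4, 5, 8, 10),
                         specs = default_model_specs(),
                         split = split_spec(), montage = NULL) {
  stopifnot(all(lengths <= rs$trial_duration_s))
  grid <- list()
  for (L in lengths) {
    ft <- build_feature_table(rs, window_spec(L, L), montage = montage)
    rep <- evaluate_models(ft, specs, split)
    agg <- stats::aggregate(accuracy ~ model, data = rep, FUN = mean)
    agg <- data.frame(length_s = L, agg, stringsAsFactors = FALSE)
    grid[[length(grid) + 1L]] <- agg
  }
  grid <- do.call(rbind, grid)
  by_len <- stats::aggregate(accuracy ~ length_s, data = grid, FUN = mean)
  best <- by_len$length_s[which.max(by_len$accuracy)]  # first max: shortest
  list(grid = grid, best_length_s = best)
}

# per-component feature ranking by extra-trees impurity importance
rank_features <- function(ft, component, features, seed = 1L,
                          num_trees = 100) {
  x <- as.matrix(ft[features])
  cls <- as.character(ft[[paste0(component, "_class")]])
  y <- factor(cls, levels = intersect(vad_levels, cls))
  fit <- ranger::ranger(x = x, y = y, num.trees = num_trees,
                        splitrule = "extratrees", num.random.splits = 1,
                        replace = FALSE, sample.fraction = 1,
                        importance = "impurity", seed = seed,
                        num.threads = 1)
  names(sort(fit$variable.importance, decreasing = TRUE))
}

#' Sweep the number of retained features
#'
#' Features are ranked per component by extra-trees impurity importance on
#' the full table; for each candidate count `k` the model is refitted on
#' the top-`k` features under the shift splits and the fold-averaged test
#' accuracy recorded. The winner is the smallest `k` attaining the maximal
#' component-averaged accuracy after rounding to 3 decimals.
#'
#' @param ft Feature table (normally on the 8-channel montage).
#' @param model A [model_spec()], default extra-trees.
#' @param counts Candidate feature counts, default 25:35.
#' @param split A [split_spec()].
#' @param seed Seed for the ranking forest.
#' @return List with `grid` (data.frame `k`, `valence`, `arousal`,
#'   `dominance`, `average`), `best_k` and `rankings` (per-component
#'   ordered feature lists).
#' @export
feature_count_sweep <- function(ft, model = model_spec("extra_trees"),
                                counts = 25:35, split = split_spec(),
                                seed = 1L) {
  features <- feature_columns(ft)
  if (max(counts) > length(features)) {
    stop("feature count ", max(counts), " exceeds the ", length(features),
         " available features")
  }
  comps <- c("valence", "arousal", "dominance")
  rankings <- lapply(stats::setNames(comps, comps), function(e) {
    rank_features(ft, e, features, seed = seed)
  })
  grid <- data.frame(k = counts)
  for (e in comps) grid[[e]] <- NA_real_
  for (i in seq_along(counts)) {
    for (e in comps) {
      rep <- evaluate_models(ft, specs = list(m = model), split = split,
                             components = e,
                             features = rankings[[e]][seq_len(counts[i])])
      grid[[e]][i] <- mean(rep$accuracy)
    }
  }
  grid$average <- rowMeans(grid[comps])
  rounded <- round(grid$average, 3)
  best_k <- grid$k[which.max(rounded)]  # first max: smallest k
  list(grid = grid, best_k = best_k, rankings = rankings)
}

#' Train the final per-component classifier trio
#'
#' Ranks features per component by extra-trees impurity importance, keeps
#' the top `k` (each component gets its own list), and fits one 3-class
#' extra-trees classifier per VAD component on all rows. The returned
#' bundle carries the metadata (montage, window, band set, seed, feature
#' lists) that the streaming loop checks before predicting.
#'
#' @param ft Feature table from the selected montage and window length.
#' @param k Features per component, default 34.
#' @param model A [model_spec()], default extra-trees.
#' @param spec The [window_spec()] the table was built with (recorded in
#'   metadata), default the 5 s streaming window.
#' @param seed Seed for ranking and fitting.
#' @return An object of class `vad_models`.
#' @export
train_final <- function(ft, k = 34, model = model_spec("extra_trees"),
                        spec = window_spec(5, 5), seed = 1L) {
  features <- feature_columns(ft)
  if (k > length(features)) {
    stop("k = ", k, " exceeds the ", length(features), " available features")
  }
  comps <- c("valence", "arousal", "dominance")
  montage <- unique(sub("_[a-z0-9]+$", "", features))
  models <- list()
  feats <- list()
  for (e in comps) {
    top <- rank_features(ft, e, features, seed = seed)[seq_len(k)]
    feats[[e]] <- top
    models[[e]] <- fit_model(model, as.matrix(ft[top]),
                             ft[[paste0(e, "_class")]])
  }
  structure(
    list(models = models, features = feats,
         metadata = list(montage = montage, k = k,
                         family = model$family, seed = seed,
                         window_length_s = spec$length_s,
                         bands = band_set()$band,
                         trained = format(Sys.time(), tz = "UTC"))),
    class = "vad_models")
}

#' Predict discrete VAD triples from a feature table
#'
#' @param vm A `vad_models` bundle from [train_final()].
#' @param ft Feature table (or plain data.frame) holding the bundle's
#'   feature columns.
#' @return Integer matrix with columns `arousal`, `valence`, `dominance`,
#'   one row per input row.
#' @export
predict_vad <- function(vm, ft) {
  stopifnot(inherits(vm, "vad_models"))
  out <- sapply(c("arousal", "valence", "dominance"), function(e) {
    predict_model(vm$models[[e]], as.matrix(ft[vm$features[[e]]]))
  })
  matrix(as.integer(out), ncol = 3,
         dimnames = list(NULL, c("arousal", "valence", "dominance")))
}

#' Persist / restore a trained model bundle
#'
#' The bundle directory holds the three fitted models (`models.rds`) and a
#' human-readable `metadata.json`.
#'
#' @param vm A `vad_models` bundle.
#' @param path Bundle directory.
#' @return `load_vad_models()` returns the `vad_models` bundle.
#' @export
save_vad_models <- function(vm, path) {
  stopifnot(inherits(vm, "vad_models"))
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  saveRDS(vm[c("models", "features")], file.path(path, "models.rds"))
  jsonlite::write_json(vm$metadata, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname save_vad_models
#' @export
load_vad_models <- function(path) {
  core <- readRDS(file.path(path, "models.rds"))
  meta <- jsonlite::read_json(file.path(path, "metadata.json"),
                              simplifyVector = TRUE)
  structure(c(core, list(metadata = meta)), class = "vad_models")
}
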