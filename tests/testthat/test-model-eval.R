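test_that("shift splits cut rotated contiguous 60:20:20 blocks", {
  s <- shift_split(100, split_spec(), fold = 0)
  expect_equal(s$train, 1:60)
  expect_equal(s$validation, 61:80)
  expect_equal(s$test, 81:100)

  # fold 3 of n = 80: rotation by 3 * floor(80/8) = 30, against brute force
  s3 <- shift_split(80, split_spec(), fold = 3)
  rot <- c(31:80, 1:30)
  expect_equal(s3$train, rot[1:48])
  expect_equal(s3$validation, rot[49:64])
  expect_equal(s3$test, rot[65:80])

  # partition property for random (n, fold)
  set.seed(41)
  for (i in 1:25) {
    n <- sample(10:500, 1)
    fold <- sample(0:7, 1)
    s <- shift_split(n, split_spec(), fold)
    all_idx <- c(s$train, s$validation, s$test)
    expect_equal(sort(all_idx), 1:n)
    expect_equal(length(all_idx), length(unique(all_idx)))
  }
  expect_error(shift_split(4, split_spec(), 0))
})

test_that("metrics reproduce the confusion-count arithmetic", {
  y <- rep(c(1L, -1L), each = 50)
  p <- c(rep(1L, 40), rep(-1L, 10),   # class 1: TP 40, FN 10
         rep(-1L, 40), rep(1L, 10))   # class -1 correct 40, FP on 1: 10
  m <- compute_metrics(y, p)
  expect_equal(m$accuracy, 0.8)
  row1 <- m$per_class[m$per_class$class == 1, ]
  expect_equal(row1$tp, 40)
  expect_equal(row1$fp, 10)
  expect_equal(row1$fn, 10)
  expect_equal(row1$tn, 40)
  expect_equal(row1$precision, 0.8)
  expect_equal(row1$recall, 0.8)
  expect_equal(row1$f1, 0.8)

  perfect <- compute_metrics(c(-1, 0, 1, 0), c(-1, 0, 1, 0))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$macro_f1, 1)
  expect_error(compute_metrics(integer(0), integer(0)), "empty")
})

test_that("metrics agree exactly with a brute-force oracle on random labels", {
  set.seed(43)
  for (i in 1:20) {
    n <- sample(20:200, 1)
    y <- sample(c(-1L, 0L, 1L), n, replace = TRUE)
    p <- sample(c(-1L, 0L, 1L), n, replace = TRUE)
    m <- compute_metrics(y, p)
    expect_equal(m$accuracy, sum(y == p) / n, tolerance = 1e-12)
    f1s <- sapply(c(-1L, 0L, 1L), function(k) {
      tp <- sum(y == k & p == k); fp <- sum(y != k & p == k)
      fn <- sum(y == k & p != k)
      pr <- if (tp + fp > 0) tp / (tp + fp) else 0
      rc <- if (tp + fn > 0) tp / (tp + fn) else 0
      if (pr + rc > 0) 2 * pr * rc / (pr + rc) else 0
    })
    expect_equal(m$macro_f1, mean(f1s), tolerance = 1e-12)
  }
})

test_that("random balanced 3-class predictions sit at chance accuracy", {
  set.seed(47)
  y <- sample(c(-1L, 0L, 1L), 3000, replace = TRUE)
  p <- sample(c(-1L, 0L, 1L), 3000, replace = TRUE)
  expect_equal(compute_metrics(y, p)$accuracy, 1 / 3, tolerance = 0.03 * 3)
})

test_that("all five classifier families fit, predict and beat chance on
          separable data", {
  ft <- toy_feature_table(n = 400)
  rep <- evaluate_models(ft, default_model_specs(seed = 1),
                         split = split_spec(folds = 2, stride = 1),
                         components = "valence")
  expect_setequal(unique(rep$model),
                  c("extra_trees", "random_forest", "xgboost", "knn", "svc"))
  agg <- summarize_evaluation(rep)
  expect_true(all(agg$accuracy > 0.6))
  expect_true(all(agg$macro_f1 >= 0 & agg$macro_f1 <= 1))
})

test_that("evaluation is reproducible and decimation only thins training", {
  ft <- toy_feature_table(n = 300)
  s <- split_spec(folds = 2, stride = 4)
  specs <- list(extra_trees = model_spec("extra_trees", seed = 5))
  r1 <- evaluate_models(ft, specs, s, components = "arousal")
  r2 <- evaluate_models(ft, specs, s, components = "arousal")
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 2)  # one row per fold
})

test_that("label-shuffled data drops every family to chance", {
  ft <- toy_feature_table(n = 450, seed = 7)
  set.seed(7)
  ft$valence_class <- sample(ft$valence_class)
  rep <- evaluate_models(ft, list(et = model_spec("extra_trees")),
                         split = split_spec(folds = 4, stride = 1),
                         components = "valence")
  expect_equal(mean(rep$accuracy), 1 / 3, tolerance = 0.1 * 3)
})

test_that("feature-count sweep ranks, refits and prefers the smallest best k", {
  ft <- toy_feature_table(n = 300, n_features = 8)
  sw <- feature_count_sweep(ft, counts = c(2, 4, 6),
                            split = split_spec(folds = 2, stride = 1))
  expect_equal(sw$grid$k, c(2, 4, 6))
  expect_true(all(!is.na(sw$grid$average)))
  expect_true(sw$best_k %in% c(2, 4, 6))
  expect_length(sw$rankings$valence, length(feature_columns(ft)))
  expect_error(feature_count_sweep(ft, counts = 100), "exceeds")
})

test_that("a single-length window sweep equals a direct evaluation", {
  rs <- planted_recording()
  specs <- list(et = model_spec("extra_trees", seed = 2))
  sw <- window_sweep(rs, lengths = 5, specs = specs,
                     split = split_spec(folds = 2, stride = 4))
  ft <- build_feature_table(rs, window_spec(5, 5))
  rep <- evaluate_models(ft, specs, split_spec(folds = 2, stride = 4))
  expect_equal(sw$grid$accuracy, mean(rep$accuracy), tolerance = 1e-12)
  expect_equal(sw$best_length_s, 5)
})

test_that("the final trio persists, reloads and reproduces predictions", {
  ft <- toy_feature_table(n = 300, n_features = 12)
  vm <- train_final(ft, k = 10, seed = 3)
  expect_s3_class(vm, "vad_models")
  expect_length(vm$features$valence, 10)
  # per-component feature lists are allowed to differ
  expect_true(is.list(vm$features) && length(vm$features) == 3)

  holdout <- toy_feature_table(n = 50, n_features = 12, seed = 11)
  p1 <- predict_vad(vm, holdout)
  expect_true(all(p1 %in% c(-1L, 0L, 1L)))

  dir <- withr::local_tempdir()
  save_vad_models(vm, dir)
  vm2 <- load_vad_models(dir)
  expect_equal(vm2$metadata$k, 10)
  expect_identical(predict_vad(vm2, holdout), p1)
})
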