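# build a feature_matrix directly from a numeric matrix
fake_fm <- function(X, labels, subjects = "S01", domain = "time") {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  structure(list(values = X,
                 meta = data.frame(subject_id = rep_len(subjects, nrow(X)),
                                   label = rep_len(labels, nrow(X)),
                                   start_s = seq_len(nrow(X)),
                                   stringsAsFactors = FALSE),
                 domain = domain, window_s = 10, sampling_rate = 32),
            class = "feature_matrix")
}

test_that("the printed k-NN grid enumerates 10 x 2 x 2 = 40 candidates", {
  g <- default_grid("knn")
  expect_identical(g$k, seq(1L, 28L, by = 3L))
  expect_length(g$k, 10L)
  cand <- wristhar:::grid_candidates(model_config("knn"), 27)
  expect_length(cand, 40L)
})

test_that("svm grid spans 0.01 to 50 with the four kernels", {
  g <- default_grid("svm")
  expect_equal(range(g$cost), c(0.01, 50))
  expect_setequal(g$kernel, c("linear", "polynomial", "rbf", "sigmoid"))
})

test_that("infeasible rf mtry candidates are skipped with a warning", {
  cfg <- model_config("rf")
  expect_warning(cand <- wristhar:::grid_candidates(cfg, 27), "skipped")
  expect_length(cand, 5L)  # only mtry = 20 survives on 27 features
  expect_true(all(vapply(cand, function(p) p$mtry, 0L) == 20L))
  expect_error(suppressWarnings(wristhar:::grid_candidates(cfg, 10)),
               "no feasible")
})

test_that("ties in CV accuracy go to the first candidate in grid order", {
  set.seed(1)
  X <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 8), 20))
  fm <- fake_fm(X, rep(c("sitting", "walking"), each = 20))
  cfg <- model_config("knn", grid = list(k = c(1L, 4L), metric = "euclidean",
                                         weight = c("uniform", "distance")),
                      cv_folds = 5, seed = 2)
  fit <- tune_model(fm, cfg)
  expect_true(all(fit$cv_accuracy == 1))  # fully separable: all candidates tie
  expect_identical(fit$chosen$k, 1L)
  expect_identical(fit$chosen$weight, "uniform")
})

test_that("single-class training sets are rejected", {
  fm <- fake_fm(matrix(rnorm(20), 10), rep("sitting", 10))
  expect_error(tune_model(fm, model_config("knn")), "single class")
})

test_that("evaluation metrics match hand-computed confusion arithmetic", {
  # train a 1-NN on two anchors, place test points to force the
  # confusion matrix [[8, 2], [0, 10]] (rows = truth)
  train <- fake_fm(rbind(matrix(0, 5, 2), matrix(10, 5, 2)),
                   rep(c("sitting", "walking"), each = 5))
  cfg <- model_config("knn", grid = list(k = 1L, metric = "euclidean",
                                         weight = "uniform"), cv_folds = 2)
  model <- tune_model(train, cfg)$model
  test_X <- rbind(matrix(0, 8, 2), matrix(10, 2, 2), matrix(10, 10, 2))
  test <- fake_fm(test_X, c(rep("sitting", 10), rep("walking", 10)))
  ev <- evaluate_model(model, test)
  expect_equal(unname(as.vector(ev$confusion)), c(8, 0, 2, 10))
  sit <- ev$per_class[ev$per_class$label == "sitting", ]
  expect_equal(sit$precision, 1.0)
  expect_equal(sit$recall, 0.8)
  expect_equal(sit$f1, 2 * 1 * 0.8 / 1.8, tolerance = 1e-12)
  expect_equal(ev$accuracy, 0.9)

  # perfect predictions give all-ones metrics
  ev2 <- evaluate_model(model, train)
  expect_true(all(ev2$per_class[, c("precision", "recall", "f1")] == 1))
  expect_equal(ev2$accuracy, 1)
})

test_that("dimension mismatches between train and test error", {
  train <- fake_fm(matrix(rnorm(40), 20, 2), rep(c("sitting", "walking"), 10))
  cfg <- model_config("knn", grid = list(k = 1L, metric = "euclidean",
                                         weight = "uniform"), cv_folds = 2)
  model <- tune_model(train, cfg)$model
  bad <- fake_fm(matrix(rnorm(30), 10, 3), "sitting")
  expect_error(evaluate_model(model, bad), "does not match")
})

test_that("tuned 1-NN agrees with a brute-force nearest-neighbour scan", {
  set.seed(21)
  Xtr <- matrix(rnorm(60 * 5), 60, 5)
  ytr <- rep(c("sitting", "walking", "typing"), each = 20)
  Xte <- matrix(rnorm(50 * 5), 50, 5)
  fm <- fake_fm(Xtr, ytr)
  cfg <- model_config("knn", grid = list(k = 1L, metric = "euclidean",
                                         weight = "uniform"), cv_folds = 5)
  model <- tune_model(fm, cfg)$model
  got <- predict(model, Xte)
  # oracle: scan standardized distances by hand
  mu <- colMeans(Xtr); sdv <- apply(Xtr, 2, sd)
  Ztr <- sweep(sweep(Xtr, 2, mu), 2, sdv, "/")
  Zte <- sweep(sweep(Xte, 2, mu), 2, sdv, "/")
  oracle <- vapply(seq_len(nrow(Zte)), function(i) {
    ytr[which.min(colSums((t(Ztr) - Zte[i, ])^2))]
  }, "")
  expect_identical(got, oracle)
})

test_that("manhattan metric and distance weights change predictions sensibly", {
  # a point at (0.9, 0) is euclidean-closer to (0,0) than to (2,2) but
  # its 3 nearest by manhattan include both anchors' clusters; just
  # verify both configurations run deterministically and agree twice
  set.seed(4)
  X <- rbind(matrix(rnorm(30, 0, .3), 15), matrix(rnorm(30, 3, .3), 15))
  fm <- fake_fm(X, rep(c("sitting", "walking"), each = 15))
  for (metric in c("euclidean", "manhattan")) {
    cfg <- model_config("knn", grid = list(k = 4L, metric = metric,
                                           weight = "distance"), cv_folds = 3)
    m <- tune_model(fm, cfg)$model
    p1 <- predict(m, X)
    p2 <- predict(m, X)
    expect_identical(p1, p2)
    expect_gt(mean(p1 == fm$meta$label), 0.9)
  }
})

test_that("intra-subject protocol uses stratified round(0.2 n) test sizes", {
  set.seed(8)
  X <- rbind(matrix(rnorm(45 * 2, 0), 45), matrix(rnorm(40 * 2, 6), 40))
  fm <- fake_fm(X, c(rep("sitting", 45), rep("walking", 40)))
  cfg <- model_config("knn", grid = list(k = 1L, metric = "euclidean",
                                         weight = "uniform"), cv_folds = 5)
  rep1 <- intra_subject_eval(fm, cfg, split_seed = 3)
  # 45 x 0.2 = 9 and 40 x 0.2 = 8 test windows
  expect_equal(sum(rep1$confusion), 17)
  expect_equal(unname(rowSums(rep1$confusion)), c(9, 8))
  rep2 <- intra_subject_eval(fm, cfg, split_seed = 3)
  expect_identical(rep1$replicate_accuracies, rep2$replicate_accuracies)
  expect_identical(rep1$confusion, rep2$confusion)
})

test_that("subjects below 5 windows per class are skipped with a warning", {
  X <- matrix(rnorm(8 * 2), 8, 2)
  fm <- fake_fm(X, rep(c("sitting", "walking"), 4))
  cfg <- model_config("knn", grid = list(k = 1L, metric = "euclidean",
                                         weight = "uniform"))
  expect_warning(expect_error(intra_subject_eval(fm, cfg), "no eligible"),
                 "fewer than 5")
})

test_that("inter-subject folds partition subjects 8,8,7,7,7 at n = 37", {
  set.seed(12)
  n_sub <- 37
  rows_per <- 10
  X <- NULL; labs <- c(); subs <- c()
  for (s in seq_len(n_sub)) {
    X <- rbind(X, matrix(rnorm(rows_per, 0), rows_per / 2),
               matrix(rnorm(rows_per, 6), rows_per / 2))
    labs <- c(labs, rep(c("sitting", "walking"), each = rows_per / 2))
    subs <- c(subs, rep(sprintf("S%02d", s), rows_per))
  }
  fm <- fake_fm(X, labs, subjects = NA)
  fm$meta$subject_id <- subs
  cfg <- model_config("knn", grid = list(k = 1L, metric = "euclidean",
                                         weight = "uniform"), cv_folds = 3)
  rep1 <- inter_subject_eval(fm, cfg, fold_seed = 7)
  sizes <- sort(lengths(rep1$fold_subjects), decreasing = TRUE)
  expect_identical(sizes, c(8L, 8L, 7L, 7L, 7L))
  # each subject is held out exactly once
  expect_setequal(unlist(rep1$fold_subjects), unique(subs))
  expect_identical(anyDuplicated(unlist(rep1$fold_subjects)), 0L)
  # determinism
  rep2 <- inter_subject_eval(fm, cfg, fold_seed = 7)
  expect_identical(rep1$fold_subjects, rep2$fold_subjects)
  expect_identical(rep1$replicate_accuracies, rep2$replicate_accuracies)
  expect_error(inter_subject_eval(fake_fm(X[1:20, ], labs[1:20]), cfg),
               "at least 5 subjects")
})

test_that("svm and rf models train, predict and expose scores", {
  set.seed(30)
  X <- rbind(matrix(rnorm(60, 0), 30), matrix(rnorm(60, 5), 30))
  fm <- fake_fm(X, rep(c("sitting", "walking"), each = 30))
  svm_cfg <- model_config("svm", grid = list(cost = 1, kernel = "rbf"),
                          cv_folds = 3, want_scores = TRUE)
  svm_fit <- tune_model(fm, svm_cfg)
  expect_gt(mean(predict(svm_fit$model, X) == fm$meta$label), 0.95)
  sc <- predict_scores(svm_fit$model, X[1:5, ])
  expect_identical(colnames(sc), svm_fit$model$levels)
  expect_equal(unname(rowSums(sc)), rep(1, 5), tolerance = 1e-6)

  rf_cfg <- model_config("rf", grid = list(max_depth = 10L, mtry = 2L),
                         cv_folds = 3, num_trees = 100L)
  rf_fit <- tune_model(fm, rf_cfg)
  expect_gt(mean(predict(rf_fit$model, X) == fm$meta$label), 0.95)
  sc2 <- predict_scores(rf_fit$model, X[1:5, ])
  expect_equal(unname(rowSums(sc2)), rep(1, 5), tolerance = 1e-9)
})
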