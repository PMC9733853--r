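fake_fm2 <- function(X, labels, domain = "timefreq") {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  structure(list(values = X,
                 meta = data.frame(subject_id = "S01",
                                   label = rep_len(labels, nrow(X)),
                                   start_s = seq_len(nrow(X)),
                                   stringsAsFactors = FALSE),
                 domain = domain, window_s = 10, sampling_rate = 32),
            class = "feature_matrix")
}

test_that("rf importance is normalised, sorted, and finds a known separator", {
  set.seed(40)
  n <- 120
  X <- matrix(rnorm(n * 6), n, 6)
  y <- ifelse(X[, 3] > 0, "sitting", "walking")
  X[, 3] <- X[, 3] * 4  # the separating column, exaggerated
  fm <- fake_fm2(X, y)
  cfg <- model_config("rf", grid = list(max_depth = 10L, mtry = 2L),
                      cv_folds = 3, num_trees = 500L)
  fit <- tune_model(fm, cfg)
  imp <- rf_overall_importance(fit$model)
  expect_equal(sum(imp$weight), 1, tolerance = 1e-9)
  expect_true(!is.unsorted(rev(imp$weight)))
  expect_identical(imp$feature[1], "f3")
  expect_gt(imp$weight[1], 0.5)
  expect_identical(nrow(rf_overall_importance(fit$model, top_k = 3)), 3L)
})

test_that("rf importance is near-uniform when labels are pure noise", {
  set.seed(41)
  X <- matrix(rnorm(300 * 5), 300, 5)
  y <- sample(c("sitting", "walking"), 300, replace = TRUE)
  fm <- fake_fm2(X, y)
  cfg <- model_config("rf", grid = list(max_depth = 10L, mtry = 2L),
                      cv_folds = 3, num_trees = 500L)
  fit <- tune_model(fm, cfg)
  imp <- rf_overall_importance(fit$model)
  expect_lt(max(imp$weight) / min(imp$weight), 3)
})

test_that("the local surrogate recovers a known linear model", {
  set.seed(42)
  d <- 10
  w_true <- rnorm(d)
  B <- matrix(rnorm(300 * d), 300, d)
  colnames(B) <- paste0("f", seq_len(d))
  f <- function(X) as.numeric(X %*% w_true)
  ex <- lime_explain(f, B[1, ], B, cfg = lime_config(n_perturbations = 3000,
                                                     seed = 5))
  expect_identical(unname(sign(ex$weights)), sign(w_true))
  expect_gt(cor(ex$weights, w_true), 0.95)
})

test_that("selection keeps the requested number of features", {
  set.seed(43)
  d <- 8
  w_true <- c(5, -4, 3, 0.01, -0.01, 0.02, 0.01, -0.02)
  B <- matrix(rnorm(200 * d), 200, d)
  colnames(B) <- paste0("f", seq_len(d))
  f <- function(X) as.numeric(X %*% w_true)
  ex3 <- lime_explain(f, B[2, ], B, cfg = lime_config(n_perturbations = 2000,
                                                      n_selected = 3, seed = 6))
  expect_setequal(ex3$selected, c("f1", "f2", "f3"))
  expect_identical(sum(ex3$weights != 0), 3L)
  # n_selected = dimension: the selection is the identity
  ex_all <- lime_explain(f, B[2, ], B, cfg = lime_config(n_perturbations = 2000,
                                                         n_selected = d, seed = 6))
  expect_setequal(ex_all$selected, colnames(B))
})

test_that("explanations are stable across perturbation seeds", {
  set.seed(44)
  d <- 12
  w_true <- c(rnorm(4, 0, 3), rnorm(8, 0, 0.1))
  B <- matrix(rnorm(250 * d), 250, d)
  colnames(B) <- paste0("f", seq_len(d))
  B[1, ] <- B[2, ]  # instance duplicated in the background
  f <- function(X) as.numeric(X %*% w_true)
  top5 <- lapply(c(7, 8), function(s) {
    ex <- lime_explain(f, B[1, ], B,
                       cfg = lime_config(n_perturbations = 2000, seed = s))
    names(sort(abs(ex$weights), decreasing = TRUE))[1:5]
  })
  expect_gte(length(intersect(top5[[1]], top5[[2]])), 4L)
})

test_that("a locally constant model yields a flagged zero explanation", {
  B <- matrix(rnorm(100 * 4), 100, 4)
  colnames(B) <- paste0("f", 1:4)
  f <- function(X) rep(0.7, nrow(X))
  ex <- lime_explain(f, B[1, ], B, cfg = lime_config(n_perturbations = 200))
  expect_identical(ex$flag, "constant_output")
  expect_true(all(ex$weights == 0))
})

test_that("class importance with n_obs = 1 equals the single explanation", {
  set.seed(45)
  X <- rbind(matrix(rnorm(60, 0), 30), matrix(rnorm(60, 6), 30))
  fm <- fake_fm2(X, rep(c("sitting", "walking"), each = 30))
  cfg <- model_config("rf", grid = list(max_depth = 10L, mtry = 2L),
                      cv_folds = 3, num_trees = 100L)
  model <- tune_model(fm, cfg)$model
  lcfg <- lime_config(n_perturbations = 500, seed = 9)
  expect_warning(ci <- class_importance(model, fm, "sitting", n_obs = 1,
                                        cfg = lcfg), NA)
  idx <- which(fm$meta$label == "sitting")
  first_correct <- idx[predict(model, fm$values[idx, ]) == "sitting"][1]
  lcfg1 <- lcfg; lcfg1$seed <- lcfg$seed + 1L
  ex <- lime_explain(model, fm$values[first_correct, ], fm,
                     target_class = "sitting", cfg = lcfg1)
  expect_equal(ci$weight, unname(ex$weights[ci$feature]), tolerance = 1e-12)
  expect_error(class_importance(model, fm, "typing"), "no windows")
})

test_that("frequency reconstruction: full selection is the identity", {
  w <- small_windows(10)[[5]]
  all_names <- unlist(lapply(c("x", "y", "z"), function(a)
    sprintf("%s_fft_%ghz", a, (0:160) / 10)))
  rec <- reconstruct_from_freq(w, all_names)
  expect_lt(max(abs(rec$signals - w$samples)), 1e-9)
})

test_that("frequency reconstruction: DC-only gives the axis mean", {
  w <- small_windows(10)[[3]]
  rec <- reconstruct_from_freq(w, "x_fft_0hz")
  expect_lt(max(abs(rec$signals[, "x"] - mean(w$samples[, 1]))), 1e-9)
  expect_true(all(rec$signals[, c("y", "z")] == 0))
})

test_that("frequency reconstruction recovers a clean sinusoid from its bin", {
  w <- sine_window(1.5, amp = 0.5, L = 320, axis = 1, noise = 0)
  rec <- reconstruct_from_freq(w, "x_fft_1.5hz")
  expect_gt(cor(rec$signals[, "x"], w$samples[, 1]), 0.999)
  expect_error(reconstruct_from_freq(w, "x_fft_1.23hz"), "align")
  expect_error(reconstruct_from_freq(w, "x_mean"), "not frequency")
})

test_that("wavelet reconstruction: full band selection is the identity", {
  w <- small_windows(10)[[7]]
  bands <- c("cA5", paste0("cD", 5:1))
  sel <- unlist(lapply(c("x", "y", "z"), function(a)
    paste0(a, "_", bands, "_rms")))
  rec <- reconstruct_from_dwt(w, sel)
  expect_lt(max(abs(rec$signals - w$samples)),
            1e-8 * diff(range(w$samples)))
})

test_that("wavelet reconstruction: cA-only of a constant axis is the constant", {
  m <- matrix(0, 320, 3); m[, 2] <- 0.81
  w <- make_window(m)
  rec <- reconstruct_from_dwt(w, "y_cA5_mean")
  expect_lt(max(abs(rec$signals[, "y"] - 0.81)), 1e-8)
})

test_that("wavelet reconstruction: cD1-only carries no DC", {
  w <- small_windows(10)[[11]]
  rec <- reconstruct_from_dwt(w, c("x_cD1_rms", "x_cD1_entropy"))
  expect_lt(abs(mean(rec$signals[, "x"])), 1e-6 * sd(w$samples[, 1]))
  expect_error(reconstruct_from_dwt(w, "x_cD9_rms"), "do not exist")
})
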