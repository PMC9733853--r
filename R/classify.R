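# Classifier harness: k-NN (own implementation: Euclidean/Manhattan,
# uniform/distance weights), SVM (e1071) and random forest (ranger),
# tuned by exhaustive grid search with 10-fold cross-validation and
# evaluated under two protocols:
#   intra-subject — stratified 80/20 split within each subject,
#                   metrics averaged (unweighted) across subjects;
#   inter-subject — subjects partitioned into 5 folds, each fold held
#                   out once; no subject contributes to both training
#                   and test data of a repetition.
# k-NN and SVM features are z-scored with training-partition statistics
# (distance/kernel methods are scale sensitive; random forests are
# scale invariant and use raw features).

#' Default hyperparameter grids
#'
#' k-NN: neighbours 1 to 28 by increments of 3, Euclidean/Manhattan
#' metric, uniform/distance vote weights (40 candidates). SVM: cost C
#' on a log-spaced grid spanning 0.01 to 50, with linear, polynomial,
#' RBF and sigmoid kernels. Random forest: maximum tree depth
#' (5, 10, 20, 30, 40) by features tried per split (20, 30, 40, 50,
#' 60); candidates whose `mtry` exceeds the feature dimension are
#' skipped at tuning time with a warning.
#'
#' @param kind One of `"knn"`, `"svm"`, `"rf"`.
#' @return Named list of candidate value vectors.
#' @export
default_grid <- function(kind = c("knn", "svm", "rf")) {
  kind <- match.arg(kind)
  switch(kind,
    knn = list(k = seq(1L, 28L, by = 3L),
               metric = c("euclidean", "manhattan"),
               weight = c("uniform", "distance")),
    svm = list(cost = c(0.01, 0.1, 1, 10, 50),
               kernel = c("linear", "polynomial", "rbf", "sigmoid")),
    rf = list(max_depth = c(5L, 10L, 20L, 30L, 40L),
              mtry = c(20L, 30L, 40L, 50L, 60L))
  )
}

#' Configure a classifier for tuning and evaluation
#'
#' @param kind `"knn"`, `"svm"` or `"rf"`.
#' @param grid Hyperparameter grid (named list of candidate vectors);
#'   defaults to [default_grid()] for the kind.
#' @param cv_folds Cross-validation folds for tuning (default 10).
#' @param seed Integer seed governing fold assignment and any model
#'   randomness.
#' @param num_trees Random-forest ensemble size (default 500).
#' @param want_scores If `TRUE`, fitted models expose per-class scores
#'   (needed by [lime_explain()]); adds probability calibration cost
#'   for SVM.
#' @return An object of class `model_config`.
#' @export
model_config <- function(kind = c("knn", "svm", "rf"), grid = NULL,
                         cv_folds = 10L, seed = 1L, num_trees = 500L,
                         want_scores = FALSE) {
  kind <- match.arg(kind)
  if (is.null(grid)) grid <- default_grid(kind)
  structure(list(kind = kind, grid = grid, cv_folds = as.integer(cv_folds),
                 seed = as.integer(seed), num_trees = as.integer(num_trees),
                 want_scores = isTRUE(want_scores)),
            class = "model_config")
}

class_levels <- function(y) {
  u <- unique(y)
  if (all(u %in% TASK_LABELS)) TASK_LABELS[TASK_LABELS %in% u] else sort(u)
}

fit_scaler <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  list(mu = mu, sd = sdv)
}

apply_scaler <- function(scaler, X) {
  sweep(sweep(X, 2L, scaler$mu, "-"), 2L, scaler$sd, "/")
}

fit_model <- function(cfg, params, X, y) {
  y <- factor(y, levels = class_levels(y))
  if (nlevels(y) < 2L)
    stop("training set contains a single class", call. = FALSE)
  obj <- list(kind = cfg$kind, params = params, levels = levels(y))
  if (cfg$kind == "knn") {
    obj$scaler <- fit_scaler(X)
    obj$X <- apply_scaler(obj$scaler, X)
    obj$y <- y
  } else if (cfg$kind == "svm") {
    obj$scaler <- fit_scaler(X)
    kern <- if (params$kernel == "rbf") "radial" else params$kernel
    set.seed(cfg$seed)
    obj$fit <- e1071::svm(apply_scaler(obj$scaler, X), y,
                          cost = params$cost, kernel = kern,
                          probability = cfg$want_scores, scale = FALSE)
  } else {
    obj$fit <- ranger::ranger(
      x = X, y = y, num.trees = cfg$num_trees,
      max.depth = params$max_depth, mtry = params$mtry,
      probability = TRUE, importance = "impurity",
      seed = cfg$seed, num.threads = 1L)
  }
  structure(obj, class = "har_model")
}

knn_vote <- function(model, Xte) {
  Xtr <- model$X
  k <- model$params$k
  w_dist <- model$params$weight == "distance"
  lev <- model$levels
  yi <- as.integer(model$y)
  scores <- matrix(0, nrow(Xte), length(lev), dimnames = list(NULL, lev))
  if (model$params$metric == "euclidean") {
    d2 <- outer(rowSums(Xte^2), rowSums(Xtr^2), "+") - 2 * Xte %*% t(Xtr)
    D <- sqrt(pmax(d2, 0))
  } else {
    D <- matrix(0, nrow(Xte), nrow(Xtr))
    for (i in seq_len(nrow(Xte)))
      D[i, ] <- colSums(abs(t(Xtr) - Xte[i, ]))
  }
  for (i in seq_len(nrow(Xte))) {
    ord <- order(D[i, ])[seq_len(min(k, nrow(Xtr)))]
    wts <- if (w_dist) {
      di <- D[i, ord]
      if (any(di < 1e-12)) as.numeric(di < 1e-12) else 1 / di
    } else rep(1, length(ord))
    for (j in seq_along(ord))
      scores[i, yi[ord[j]]] <- scores[i, yi[ord[j]]] + wts[j]
  }
  scores / pmax(rowSums(scores), .Machine$double.eps)
}

#' Per-class scores of a fitted model
#'
#' k-NN returns (weighted) neighbour vote shares; random forests return
#' out-of-bag-free predicted class probabilities; SVMs return Platt
#' probabilities (requires `want_scores = TRUE` at fit time). Columns
#' follow the model's class levels.
#'
#' @param model A fitted `har_model`.
#' @param X Numeric matrix of rows to score.
#' @return Matrix, one column per class.
#' @export
predict_scores <- function(model, X) {
  stopifnot(inherits(model, "har_model"))
  X <- as.matrix(X)
  if (model$kind == "knn") {
    knn_vote(model, apply_scaler(model$scaler, X))
  } else if (model$kind == "svm") {
    if (is.null(model$fit$compprob) || !model$fit$compprob)
      stop("svm fitted without probability scores; set want_scores = TRUE",
           call. = FALSE)
    pr <- attr(stats::predict(model$fit, apply_scaler(model$scaler, X),
                              probability = TRUE), "probabilities")
    pr[, model$levels, drop = FALSE]
  } else {
    if (is.null(colnames(X)))
      colnames(X) <- model$fit$forest$independent.variable.names
    pr <- stats::predict(model$fit, data = X, num.threads = 1L)$predictions
    pr[, model$levels, drop = FALSE]
  }
}

#' @export
predict.har_model <- function(object, newdata, ...) {
  if (object$kind == "svm") {
    as.character(stats::predict(object$fit,
                                apply_scaler(object$scaler, as.matrix(newdata))))
  } else {
    sc <- predict_scores(object, newdata)
    object$levels[max.col(sc, ties.method = "first")]
  }
}

grid_candidates <- function(cfg, n_features) {
  g <- expand.grid(cfg$grid, stringsAsFactors = FALSE)
  cand <- lapply(seq_len(nrow(g)), function(i) as.list(g[i, , drop = FALSE]))
  if (cfg$kind == "rf") {
    feasible <- vapply(cand, function(p) p$mtry <= n_features, TRUE)
    if (!all(feasible))
      warning(sum(!feasible), " rf candidate(s) skipped: mtry exceeds the ",
              n_features, "-feature dimension", call. = FALSE)
    cand <- cand[feasible]
    if (!length(cand))
      stop("no feasible rf candidate for ", n_features, " features", call. = FALSE)
  }
  cand
}

stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Tune a classifier by grid search with cross-validation
#'
#' Exhaustive search over the configured grid; each candidate is scored
#' by mean accuracy over stratified `cv_folds`-fold cross-validation of
#' the training rows (folds are reduced with a warning when the rarest
#' class has fewer members than folds). Ties are broken by first-in-grid
#' order, and the winner is refit on all training rows.
#'
#' @param train A `feature_matrix` of training rows.
#' @param cfg A [model_config()].
#' @return List with `model` (fitted `har_model`), `chosen`
#'   (winning hyperparameters), and `cv_accuracy` (per-candidate mean
#'   CV accuracy, in grid order).
#' @export
tune_model <- function(train, cfg) {
  stopifnot(inherits(train, "feature_matrix"), inherits(cfg, "model_config"))
  X <- train$values
  y <- train$meta$label
  if (length(unique(y)) < 2L)
    stop("training set contains a single class", call. = FALSE)
  cand <- grid_candidates(cfg, ncol(X))
  min_n <- min(table(y))
  k <- cfg$cv_folds
  if (min_n < k) {
    k <- max(2L, min_n)
    warning("reducing CV folds to ", k, ": rarest class has ", min_n, " rows",
            call. = FALSE)
  }
  fold <- stratified_folds(y, k, cfg$seed)
  acc <- numeric(length(cand))
  for (ci in seq_along(cand)) {
    hits <- 0L
    for (f in seq_len(k)) {
      tr <- fold != f
      m <- fit_model(cfg, cand[[ci]], X[tr, , drop = FALSE], y[tr])
      hits <- hits + sum(predict(m, X[!tr, , drop = FALSE]) == y[!tr])
    }
    acc[ci] <- hits / length(y)
  }
  best <- which.max(acc)  # ties: first in grid order
  list(model = fit_model(cfg, cand[[best]], X, y),
       chosen = cand[[best]],
       cv_accuracy = acc)
}

#' Evaluate a fitted model on a test feature matrix
#'
#' Computes the confusion matrix over the union of training classes,
#' per-class precision (`TP/(TP+FP)`), recall (`TP/(TP+FN)`) and F1
#' (harmonic mean), and overall accuracy. Classes absent from both
#' truth and prediction get zero metrics and are flagged. Micro-averaged
#' recall is asserted to equal overall accuracy.
#'
#' @param model A fitted `har_model`.
#' @param test A `feature_matrix` with the same feature dimension as
#'   training.
#' @return List (`evaluation` fragment): `per_class` data frame,
#'   `accuracy`, `confusion`.
#' @export
evaluate_model <- function(model, test) {
  stopifnot(inherits(model, "har_model"), inherits(test, "feature_matrix"))
  if (!nrow(test$values)) stop("empty test set", call. = FALSE)
  dim_train <- if (model$kind == "knn") ncol(model$X)
               else if (model$kind == "svm") length(model$scaler$mu)
               else model$fit$num.independent.variables
  if (ncol(test$values) != dim_train)
    stop("test dimension ", ncol(test$values), " does not match training (",
         dim_train, ")", call. = FALSE)
  lev <- model$levels
  pred <- factor(predict(model, test$values), levels = lev)
  truth <- factor(test$meta$label, levels = lev)
  confusion <- table(truth = truth, predicted = pred)
  tp <- diag(confusion)
  fp <- colSums(confusion) - tp
  fn <- rowSums(confusion) - tp
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  absent <- (rowSums(confusion) == 0) & (colSums(confusion) == 0)
  accuracy <- sum(tp) / sum(confusion)
  # micro-averaged recall must coincide with overall accuracy
  stopifnot(abs(sum(tp) / sum(tp + fn) - accuracy) < 1e-12)
  list(per_class = data.frame(label = lev, precision = unname(precision),
                              recall = unname(recall), f1 = unname(f1),
                              support = unname(rowSums(confusion)),
                              flagged_absent = unname(absent),
                              stringsAsFactors = FALSE),
       accuracy = accuracy,
       confusion = confusion)
}

subset_fm <- function(fm, idx) {
  out <- fm
  out$values <- fm$values[idx, , drop = FALSE]
  out$meta <- fm$meta[idx, , drop = FALSE]
  out
}

aggregate_reports <- function(frags, protocol, fm, cfg, chosen) {
  accs <- vapply(frags, `[[`, 0, "accuracy")
  per_class <- frags[[1L]]$per_class[, "label", drop = FALSE]
  for (m in c("precision", "recall", "f1")) {
    per_class[[m]] <- rowMeans(vapply(frags, function(f) f$per_class[[m]],
                                      numeric(nrow(per_class))))
  }
  confusion <- Reduce(`+`, lapply(frags, `[[`, "confusion"))
  structure(
    list(protocol = protocol, window_s = fm$window_s, domain = fm$domain,
         model = cfg$kind, per_class = per_class,
         accuracy = mean(accs),
         dispersion = if (length(accs) > 1L) stats::sd(accs) else NA_real_,
         replicate_accuracies = accs,
         confusion = confusion, chosen = chosen),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "<evaluation_report> %s | %s features | %s | %g s windows\n  accuracy %.3f (sd %.3f over %d replicates)\n",
    x$protocol, x$domain, x$model, x$window_s, x$accuracy, x$dispersion,
    length(x$replicate_accuracies)))
  invisible(x)
}

#' Intra-subject evaluation protocol
#'
#' For every subject independently: stratified 80/20 train/test split
#' (per class, test size `round(0.2 n)`, at least 1), hyperparameter
#' tuning on the 80% and evaluation on the 20%. Reported metrics are
#' unweighted means across subjects; dispersion is the across-subject
#' standard deviation of accuracy. Subjects with fewer than 5 windows
#' in any class are skipped with a warning.
#'
#' @param fm A `feature_matrix` covering all subjects (rows carry
#'   `subject_id` metadata).
#' @param cfg A [model_config()].
#' @param split_seed Integer seed for the splits.
#' @return An `evaluation_report` with `protocol = "intra"`.
#' @export
intra_subject_eval <- function(fm, cfg, split_seed = 1L) {
  stopifnot(inherits(fm, "feature_matrix"))
  subjects <- unique(fm$meta$subject_id)
  frags <- list()
  chosen <- list()
  for (si in seq_along(subjects)) {
    idx <- which(fm$meta$subject_id == subjects[si])
    y <- fm$meta$label[idx]
    if (min(table(y)) < 5L) {
      warning("skipping subject ", subjects[si],
              ": fewer than 5 windows in some class", call. = FALSE)
      next
    }
    set.seed(split_seed + si)
    test_idx <- unlist(lapply(unique(y), function(cl) {
      cl_idx <- which(y == cl)
      sample(cl_idx, max(1L, round(0.2 * length(cl_idx))))
    }))
    sub_cfg <- cfg
    sub_cfg$seed <- cfg$seed + si
    fit <- tune_model(subset_fm(fm, idx[-test_idx]), sub_cfg)
    frags[[length(frags) + 1L]] <-
      evaluate_model(fit$model, subset_fm(fm, idx[test_idx]))
    chosen[[subjects[si]]] <- fit$chosen
  }
  if (!length(frags)) stop("no eligible subject for intra-subject evaluation",
                           call. = FALSE)
  aggregate_reports(frags, "intra", fm, cfg, chosen)
}

#' Inter-subject evaluation protocol
#'
#' Subjects are partitioned into five folds (balanced sizes, e.g. 37
#' subjects give folds of 8, 8, 7, 7, 7); each fold's subjects are
#' held out once while the remaining subjects' rows are pooled for
#' tuning. The disjointness of training and test subject sets is
#' asserted on every repetition. Reported metrics are unweighted means
#' over the five repetitions.
#'
#' @param fm A `feature_matrix` covering at least 5 subjects.
#' @param cfg A [model_config()].
#' @param fold_seed Integer seed for the subject partition.
#' @return An `evaluation_report` with `protocol = "inter"` whose
#'   `replicate_accuracies` are the five fold accuracies.
#' @export
inter_subject_eval <- function(fm, cfg, fold_seed = 1L) {
  stopifnot(inherits(fm, "feature_matrix"))
  subjects <- unique(fm$meta$subject_id)
  if (length(subjects) < 5L)
    stop("inter-subject protocol needs at least 5 subjects", call. = FALSE)
  set.seed(fold_seed)
  shuffled <- sample(subjects)
  fold_of <- stats::setNames(rep_len(1:5, length(subjects)), shuffled)
  frags <- list()
  chosen <- list()
  fold_subjects <- vector("list", 5L)
  for (f in 1:5) {
    test_subjects <- names(fold_of)[fold_of == f]
    fold_subjects[[f]] <- test_subjects
    train_subjects <- setdiff(subjects, test_subjects)
    stopifnot(length(intersect(train_subjects, test_subjects)) == 0L)
    rep_cfg <- cfg
    rep_cfg$seed <- cfg$seed + f
    fit <- tune_model(subset_fm(fm, fm$meta$subject_id %in% train_subjects),
                      rep_cfg)
    frags[[f]] <- evaluate_model(
      fit$model, subset_fm(fm, fm$meta$subject_id %in% test_subjects))
    chosen[[f]] <- fit$chosen
  }
  rep <- aggregate_reports(frags, "inter", fm, cfg, chosen)
  rep$fold_subjects <- fold_subjects
  rep
}
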