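# Interpretation tools: global feature importance from the random
# forest; class-specific local importance via a weighted linear
# surrogate (LIME-style) averaged over correctly classified windows;
# and reconstruction of the acceleration signal carried by the
# top-ranked frequency or wavelet features via the inverse transforms.

#' Overall feature importance from a fitted random forest
#'
#' Mean impurity-decrease importance per feature, normalised to sum 1
#' and sorted descending. The study reports all 27 time features but
#' only the top 30 frequency and top 15 time-frequency features;
#' `top_k` truncates the ranking accordingly (normalisation is over
#' all features, before truncation).
#'
#' @param model A `har_model` of kind `"rf"` (from [tune_model()] /
#'   `fit_model`).
#' @param top_k Optional truncation of the returned ranking.
#' @return An `importance_ranking`: data frame `(feature, weight)` with
#'   attributes `scope = "overall"` and `model_kind`.
#' @export
rf_overall_importance <- function(model, top_k = NULL) {
  if (!inherits(model, "har_model") || model$kind != "rf")
    stop("rf_overall_importance needs a fitted random forest model", call. = FALSE)
  imp <- ranger::importance(model$fit)
  imp <- imp / sum(imp)
  ord <- order(imp, decreasing = TRUE)
  out <- data.frame(feature = names(imp)[ord], weight = unname(imp[ord]),
                    stringsAsFactors = FALSE)
  if (!is.null(top_k)) out <- out[seq_len(min(top_k, nrow(out))), ]
  structure(out, scope = "overall", model_kind = "rf",
            class = c("importance_ranking", "data.frame"))
}

#' LIME configuration
#'
#' Defaults follow the original local-surrogate method's conventions:
#' 5000 Gaussian perturbations in standardised feature space, an
#' exponential kernel of width `0.75 * sqrt(d)` on the standardised
#' Euclidean distance, and a ridge penalty of 1.
#'
#' @param n_perturbations Number of perturbed samples.
#' @param kernel_width Kernel width; `NULL` means `0.75 * sqrt(d)`.
#' @param n_selected Number of features kept in the final surrogate;
#'   `NULL` keeps all.
#' @param ridge Ridge penalty of the weighted linear surrogate.
#' @param seed Integer seed.
#' @return A list of class `lime_config`.
#' @export
lime_config <- function(n_perturbations = 5000L, kernel_width = NULL,
                        n_selected = NULL, ridge = 1, seed = 1L) {
  structure(list(n_perturbations = as.integer(n_perturbations),
                 kernel_width = kernel_width, n_selected = n_selected,
                 ridge = ridge, seed = as.integer(seed)),
            class = "lime_config")
}

weighted_ridge <- function(Z, s, w, lambda) {
  wm_z <- colSums(Z * w) / sum(w)
  wm_s <- sum(s * w) / sum(w)
  Zc <- sweep(Z, 2L, wm_z, "-")
  sc <- s - wm_s
  A <- crossprod(Zc * sqrt(w)) + diag(lambda, ncol(Z))
  beta <- solve(A, crossprod(Zc, sc * w))
  list(beta = as.numeric(beta),
       intercept = wm_s - sum(wm_z * beta))
}

#' Explain one prediction with a local linear surrogate
#'
#' Draws Gaussian perturbations around the instance in standardised
#' feature space (scales taken from the background matrix), weights
#' them by `exp(-d^2 / kernel_width^2)` with `d` the standardised
#' Euclidean distance to the instance, and fits a weighted ridge
#' regression of the model's target-class score. The `n_selected`
#' features with the largest absolute weighted coefficients are kept
#' and the surrogate refit on them; all other features get weight 0.
#' Returned weights are on the original feature scale, so a linear
#' scoring model is recovered up to ridge shrinkage.
#'
#' @param model A `har_model` exposing class scores (see
#'   [predict_scores()]), or any function `f(X) -> numeric` scoring
#'   rows directly (then `target_class` is ignored).
#' @param instance Numeric feature vector (named as the background).
#' @param background A `feature_matrix` or numeric matrix providing
#'   feature location/scale.
#' @param target_class Class label whose score is explained.
#' @param cfg A [lime_config()].
#' @return An object of class `explanation`: list with `weights`
#'   (named, original scale; zeros for unselected features),
#'   `weights_std`, `selected`, `intercept`, `kernel_width`,
#'   `n_perturbations`, `target_class`, and `flag`
#'   (`"constant_output"` when the model does not vary locally).
#' @export
lime_explain <- function(model, instance, background, target_class = NULL,
                         cfg = lime_config()) {
  B <- if (inherits(background, "feature_matrix")) background$values
       else as.matrix(background)
  if (!nrow(B)) stop("background must be nonempty", call. = FALSE)
  x0 <- as.numeric(instance)
  d <- length(x0)
  if (d != ncol(B))
    stop("instance dimension does not match the background", call. = FALSE)
  scaler <- fit_scaler(B)
  z0 <- (x0 - scaler$mu) / scaler$sd
  kw <- if (is.null(cfg$kernel_width)) 0.75 * sqrt(d) else cfg$kernel_width
  set.seed(cfg$seed)
  Z <- matrix(stats::rnorm(cfg$n_perturbations * d), cfg$n_perturbations, d)
  Z <- sweep(Z, 2L, z0, "+")
  X <- sweep(sweep(Z, 2L, scaler$sd, "*"), 2L, scaler$mu, "+")
  colnames(X) <- colnames(B)
  s <- if (is.function(model)) {
    as.numeric(model(X))
  } else {
    if (is.null(target_class))
      stop("target_class is required for a fitted model", call. = FALSE)
    sc <- predict_scores(model, X)
    if (!target_class %in% colnames(sc))
      stop("target_class '", target_class, "' unknown to the model", call. = FALSE)
    sc[, target_class]
  }
  dist2 <- rowSums(sweep(Z, 2L, z0, "-")^2)
  w <- exp(-dist2 / kw^2)
  nm <- colnames(B)
  if (is.null(nm)) nm <- paste0("f", seq_len(d))
  if (stats::sd(s) < 1e-12) {
    return(structure(list(
      weights = stats::setNames(numeric(d), nm),
      weights_std = stats::setNames(numeric(d), nm),
      selected = character(0), intercept = mean(s),
      kernel_width = kw, n_perturbations = cfg$n_perturbations,
      target_class = target_class, flag = "constant_output"),
      class = "explanation"))
  }
  full <- weighted_ridge(Z, s, w, cfg$ridge)
  n_sel <- if (is.null(cfg$n_selected)) d else min(cfg$n_selected, d)
  sel <- order(abs(full$beta), decreasing = TRUE)[seq_len(n_sel)]
  refit <- if (n_sel == d) full else {
    r <- weighted_ridge(Z[, sel, drop = FALSE], s, w, cfg$ridge)
    beta <- numeric(d)
    beta[sel] <- r$beta
    list(beta = beta, intercept = r$intercept)
  }
  w_std <- stats::setNames(refit$beta, nm)
  structure(list(
    weights = stats::setNames(refit$beta / scaler$sd, nm),
    weights_std = w_std,
    selected = nm[sort(sel)],
    intercept = refit$intercept,
    kernel_width = kw, n_perturbations = cfg$n_perturbations,
    target_class = target_class, flag = NULL),
    class = "explanation")
}

#' Class-specific feature importance averaged over correct predictions
#'
#' Runs [lime_explain()] on up to `n_obs` windows of the given label
#' that the model classifies correctly (the study averages over 30)
#' and averages the signed weights elementwise; the ranking orders
#' features by absolute mean weight. Typical `n_selected` values are
#' 30 for frequency features and 15 for time-frequency features.
#'
#' @param model A `har_model` exposing class scores.
#' @param fm A `feature_matrix` to draw observations from (also used as
#'   the LIME background).
#' @param label Target class label.
#' @param n_obs Number of correctly classified windows to average over;
#'   if fewer are available, all are used with a warning.
#' @param cfg A [lime_config()].
#' @return An `importance_ranking` with `scope = "class:<label>"`,
#'   columns `(feature, weight)` where `weight` is the signed mean, and
#'   attribute `n_obs_used`.
#' @export
class_importance <- function(model, fm, label, n_obs = 30L, cfg = lime_config()) {
  stopifnot(inherits(fm, "feature_matrix"))
  idx <- which(fm$meta$label == label)
  if (!length(idx)) stop("no windows of class '", label, "'", call. = FALSE)
  correct <- idx[predict(model, fm$values[idx, , drop = FALSE]) == label]
  if (!length(correct))
    stop("no correctly classified windows of class '", label, "'", call. = FALSE)
  if (length(correct) < n_obs)
    warning("only ", length(correct), " correctly classified windows available",
            call. = FALSE)
  use <- correct[seq_len(min(n_obs, length(correct)))]
  W <- vapply(seq_along(use), function(i) {
    ecfg <- cfg
    ecfg$seed <- cfg$seed + i
    lime_explain(model, fm$values[use[i], ], fm, target_class = label,
                 cfg = ecfg)$weights
  }, numeric(ncol(fm$values)))
  mw <- rowMeans(W)
  ord <- order(abs(mw), decreasing = TRUE)
  structure(
    data.frame(feature = colnames(fm$values)[ord], weight = unname(mw[ord]),
               stringsAsFactors = FALSE),
    scope = paste0("class:", label), model_kind = model$kind,
    n_obs_used = length(use),
    class = c("importance_ranking", "data.frame"))
}

parse_freq_names <- function(selected, window_s) {
  m <- regmatches(selected, regexec("^([xyz])_fft_([0-9.]+)hz$", selected))
  bad <- selected[lengths(m) != 3L]
  if (length(bad))
    stop("not frequency feature names: ", paste(bad, collapse = ", "),
         call. = FALSE)
  axis <- vapply(m, `[`, "", 2L)
  freq <- as.numeric(vapply(m, `[`, "", 3L))
  k <- freq * window_s
  if (any(abs(k - round(k)) > 1e-9))
    stop("selected frequencies do not align with the bins of a ",
         window_s, " s window", call. = FALSE)
  data.frame(axis = axis, k = as.integer(round(k)), stringsAsFactors = FALSE)
}

#' Reconstruct a window's signals from selected frequency features
#'
#' Per axis: full DFT of the raw signal, zeroing of every bin whose
#' name was not selected for that axis (conjugate-symmetric partners
#' are kept automatically so the inverse transform is real), then the
#' inverse DFT. Selecting every bin of an axis reproduces that axis
#' exactly.
#'
#' @param w A `window`.
#' @param selected Character vector of frequency feature names
#'   (`<axis>_fft_<freq>hz`); bins up to the Nyquist frequency are
#'   addressable, not only the sub-10 Hz feature vocabulary.
#' @return A `reconstruction`: list with `signals` (L x 3 matrix),
#'   `retained` (per-axis bin indices, 0-based) and `domain = "freq"`.
#' @export
reconstruct_from_freq <- function(w, selected) {
  check_window(w)
  L <- nrow(w$samples)
  sel <- parse_freq_names(selected, w$window_s)
  if (any(sel$k > floor(L / 2)))
    stop("selected bins exceed the Nyquist bin for this window length",
         call. = FALSE)
  signals <- matrix(0, L, 3L, dimnames = list(NULL, AXES))
  retained <- stats::setNames(vector("list", 3L), AXES)
  for (j in seq_len(3L)) {
    ks <- sel$k[sel$axis == AXES[j]]
    retained[[j]] <- sort(unique(ks))
    X <- stats::fft(w$samples[, j])
    mask <- logical(L)
    if (length(ks)) {
      mask[ks + 1L] <- TRUE
      mask[((L - ks) %% L) + 1L] <- TRUE  # conjugate partners keep it real
    }
    X[!mask] <- 0
    signals[, j] <- Re(stats::fft(X, inverse = TRUE)) / L
  }
  structure(list(signals = signals, retained = retained, domain = "freq"),
            class = "reconstruction")
}

parse_timefreq_names <- function(selected, valid_bands) {
  m <- regmatches(selected,
                  regexec("^([xyz])_(cA[0-9]+|cD[0-9]+)_([a-z0-9]+)$", selected))
  bad <- selected[lengths(m) != 4L]
  if (length(bad))
    stop("not time-frequency feature names: ", paste(bad, collapse = ", "),
         call. = FALSE)
  out <- data.frame(axis = vapply(m, `[`, "", 2L),
                    band = vapply(m, `[`, "", 3L),
                    stringsAsFactors = FALSE)
  unknown <- setdiff(unique(out$band), valid_bands)
  if (length(unknown))
    stop("band(s) ", paste(unknown, collapse = ", "),
         " do not exist at this window length", call. = FALSE)
  out
}

#' Reconstruct a window's signals from selected wavelet features
#'
#' Each selected time-frequency feature maps to its source band (the
#' deepest approximation `cA<L>` or a detail band `cD<l>`). Per axis,
#' every band containing at least one selected feature is retained,
#' all other bands are zeroed, and the inverse db4 transform is
#' applied. Selecting features from every band of an axis reproduces
#' that axis exactly (perfect reconstruction).
#'
#' @param w A `window`.
#' @param selected Character vector of time-frequency feature names
#'   (`<axis>_<band>_<descriptor>`).
#' @return A `reconstruction`: list with `signals` (L x 3), `retained`
#'   (per-axis band names) and `domain = "timefreq"`.
#' @export
reconstruct_from_dwt <- function(w, selected) {
  check_window(w)
  L <- nrow(w$samples)
  lev <- dwt_max_level(L)
  valid_bands <- c(paste0("cA", lev), paste0("cD", lev:1))
  sel <- parse_timefreq_names(selected, valid_bands)
  signals <- matrix(0, L, 3L, dimnames = list(NULL, AXES))
  retained <- stats::setNames(vector("list", 3L), AXES)
  for (j in seq_len(3L)) {
    keep <- unique(sel$band[sel$axis == AXES[j]])
    retained[[j]] <- keep
    bands <- dwt_decompose(w$samples[, j], level = lev)
    for (bn in setdiff(valid_bands, keep))
      bands[[bn]] <- numeric(length(bands[[bn]]))
    signals[, j] <- dwt_reconstruct(bands)
  }
  structure(list(signals = signals, retained = retained, domain = "timefreq"),
            class = "reconstruction")
}
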