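# Statistical comparison of feature sets and classifiers: a classical
# fixed-effects two-way ANOVA with interaction on inter-subject overall
# accuracy, run separately per window length, followed by Tukey HSD for
# significant main effects. Replicates are the five inter-subject fold
# accuracies — the only replicate structure the protocol exposes.

#' Assemble an accuracy table from inter-subject reports
#'
#' One row per (window length, feature domain, classifier, replicate)
#' with the replicate's overall accuracy. The design must be balanced
#' per window length for [two_way_anova()].
#'
#' @param reports List of `evaluation_report`s from
#'   [inter_subject_eval()].
#' @return An object of class `accuracy_table` (a data frame with
#'   columns `window_s, feature, classifier, replicate, accuracy`).
#' @export
accuracy_table <- function(reports) {
  rows <- lapply(reports, function(r) {
    stopifnot(inherits(r, "evaluation_report"))
    data.frame(window_s = r$window_s, feature = r$domain,
               classifier = r$model,
               replicate = seq_along(r$replicate_accuracies),
               accuracy = r$replicate_accuracies,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  as_accuracy_table(out)
}

#' Validate a data frame as an accuracy table
#'
#' @param df Data frame with columns
#'   `window_s, feature, classifier, replicate, accuracy`.
#' @return The validated `accuracy_table`.
#' @export
as_accuracy_table <- function(df) {
  req <- c("window_s", "feature", "classifier", "replicate", "accuracy")
  if (!all(req %in% names(df)))
    stop("accuracy table needs columns ", paste(req, collapse = ", "),
         call. = FALSE)
  if (any(df$accuracy < 0 | df$accuracy > 1))
    stop("accuracies must lie in [0, 1]", call. = FALSE)
  class(df) <- c("accuracy_table", "data.frame")
  df
}

check_balanced <- function(tbl) {
  cells <- table(tbl$feature, tbl$classifier)
  if (any(cells == 0)) {
    miss <- which(cells == 0, arr.ind = TRUE)
    stop("incomplete design, missing cell(s): ",
         paste(rownames(cells)[miss[, 1]], colnames(cells)[miss[, 2]],
               sep = ":", collapse = ", "), call. = FALSE)
  }
  if (length(unique(as.vector(cells))) != 1L)
    stop("unbalanced design: unequal replicate counts per cell", call. = FALSE)
  if (cells[1L] < 2L)
    stop("need >= 2 replicates per cell", call. = FALSE)
  invisible(cells)
}

anova_fit <- function(tbl, window_s) {
  tbl <- as_accuracy_table(as.data.frame(tbl))
  tbl <- tbl[tbl$window_s == window_s, , drop = FALSE]
  if (!nrow(tbl)) stop("no rows for window_s = ", window_s, call. = FALSE)
  check_balanced(tbl)
  tbl$feature <- factor(tbl$feature)
  tbl$classifier <- factor(tbl$classifier)
  stats::aov(accuracy ~ feature * classifier, data = tbl)
}

#' Two-way ANOVA on overall accuracy
#'
#' Fixed-effects ANOVA of accuracy on feature set and classifier with
#' their interaction, for one window length. The design must be
#' complete and balanced (so type I/II/III sums of squares coincide);
#' F ratios are tested against the residual mean square.
#'
#' @param tbl An [accuracy_table()] (or equivalent data frame).
#' @param window_s Window length to analyse.
#' @return List with `table` (data frame: term, df, sum_sq, mean_sq,
#'   F, p) and the underlying `aov` fit.
#' @export
two_way_anova <- function(tbl, window_s) {
  fit <- anova_fit(tbl, window_s)
  s <- summary(fit)[[1L]]
  terms <- trimws(rownames(s))
  out <- data.frame(term = c("feature", "classifier", "interaction", "residual"),
                    df = s$Df, sum_sq = s$`Sum Sq`, mean_sq = s$`Mean Sq`,
                    F = s$`F value`, p = s$`Pr(>F)`,
                    stringsAsFactors = FALSE)
  stopifnot(identical(terms, c("feature", "classifier",
                               "feature:classifier", "Residuals")))
  list(table = out, fit = fit)
}

#' Tukey honestly-significant-difference post hoc test
#'
#' Pairwise comparisons of one factor's level means after
#' [two_way_anova()], using the studentized range distribution with the
#' ANOVA residual mean square and degrees of freedom. P-values are
#' symmetric in the pair.
#'
#' @param tbl An [accuracy_table()].
#' @param window_s Window length to analyse.
#' @param factor_name `"feature"` or `"classifier"`.
#' @return List with `pairs` (data frame: level_a, level_b, diff, p)
#'   and `p_matrix` (symmetric matrix of p-values, diagonal `NA`).
#' @export
tukey_hsd <- function(tbl, window_s, factor_name = c("feature", "classifier")) {
  factor_name <- match.arg(factor_name)
  fit <- anova_fit(tbl, window_s)
  lev <- fit$xlevels[[factor_name]]
  if (length(lev) < 2L)
    stop("factor ", factor_name, " has fewer than 2 levels", call. = FALSE)
  tk <- stats::TukeyHSD(fit, which = factor_name)[[factor_name]]
  parts <- strsplit(rownames(tk), "-", fixed = TRUE)
  pairs <- data.frame(level_a = vapply(parts, `[`, "", 1L),
                      level_b = vapply(parts, `[`, "", 2L),
                      diff = unname(tk[, "diff"]),
                      p = unname(tk[, "p adj"]),
                      stringsAsFactors = FALSE)
  p_matrix <- matrix(NA_real_, length(lev), length(lev),
                     dimnames = list(lev, lev))
  for (i in seq_len(nrow(pairs))) {
    p_matrix[pairs$level_a[i], pairs$level_b[i]] <- pairs$p[i]
    p_matrix[pairs$level_b[i], pairs$level_a[i]] <- pairs$p[i]
  }
  list(pairs = pairs, p_matrix = p_matrix)
}
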