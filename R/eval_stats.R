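# Accuracy and robustness evaluation: coefficient of determination,
# corrected repeated k-fold t-test, Benjamini-Hochberg FDR, Levene's
# test, and repeated cross-validation of the stacking pipeline.

#' Coefficient of determination
#'
#' `R^2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`.  May be negative
#' when the predictions do worse than the mean of the observed values --
#' common for out-of-sample predictions of weakly predictable traits.
#'
#' @param y Observed values (non-constant, length `>= 2`).
#' @param yhat Predicted values.
#' @return A single numeric value.
#' @export
r_squared <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 2)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("y is constant; R^2 is undefined")
  1 - sum((y - yhat)^2) / ss_tot
}

#' Corrected repeated k-fold cross-validation t-test
#'
#' Paired test on per-fold accuracy differences
#' `x_ij = a_ij - b_ij` across `k` folds and `r` repetitions of
#' cross-validation.  Because training sets overlap heavily across folds,
#' the naive variance of the mean is too small; the corrected statistic
#' inflates it with a term depending on the test/train size ratio:
#' `t = mean(x) / sqrt((1/(k r) + n2/n1) * s2)`, with `s2` the sample
#' variance of the differences (squared deviations) and a Student-t
#' reference with `k r - 1` degrees of freedom.
#'
#' @param x Length `k * r` vector of per-(fold, repetition) accuracy
#'   differences.
#' @param k Folds per repetition.
#' @param r Repetitions.
#' @param n1,n2 Training- and test-set sizes.
#' @param correction Set to `FALSE` to drop the `n2/n1` term and recover
#'   the uncorrected resampled t-test (internal check mode).
#' @return List with `t`, `p` (two-sided), `df`.
#' @export
corrected_resampled_ttest <- function(x, k, r, n1, n2, correction = TRUE) {
  x <- as.numeric(x)
  if (length(x) != k * r) stop("x must have length k * r")
  if (k * r < 2) stop("need at least two fold-repetition cells")
  m <- mean(x)
  s2 <- sum((x - m)^2) / (k * r - 1)
  infl <- 1 / (k * r) + if (correction) n2 / n1 else 0
  df <- k * r - 1
  if (s2 == 0) {
    if (m == 0) return(list(t = 0, p = 1, df = df))
    warning("degenerate variance with nonzero mean difference")
    return(list(t = sign(m) * Inf, p = 0, df = df))
  }
  tstat <- m / sqrt(infl * s2)
  list(t = tstat, p = 2 * pt(-abs(tstat), df = df), df = df)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjustment of a vector of p-values
#' (monotonicity enforced, capped at 1).
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_fdr <- function(p) {
  p <- as.numeric(p)
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Levene's test for equality of variances
#'
#' Classic Levene statistic on absolute deviations from the group means
#' (a one-way ANOVA on `|x - mean(group)|`), with an F reference
#' distribution.  Used to compare the spread of accuracy scores across
#' repeated cross-validation, where normality of the scores cannot be
#' assumed.
#'
#' @param groups List of at least two numeric vectors, each of length
#'   `>= 2`.
#' @return List with `W` (the statistic), `p`, and the degrees of
#'   freedom `df1`, `df2`.
#' @export
levene_test <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(vapply(groups, length, 0L) < 2))
    stop("each group needs at least two values")
  g <- length(groups)
  z <- lapply(groups, function(v) abs(v - mean(v)))
  ni <- vapply(z, length, 0L)
  N <- sum(ni)
  zbar_i <- vapply(z, mean, 0.0)
  zbar <- sum(unlist(z)) / N
  num <- (N - g) * sum(ni * (zbar_i - zbar)^2)
  den <- (g - 1) * sum(vapply(z, function(v) sum((v - mean(v))^2), 0.0))
  if (den == 0) {
    if (num == 0) return(list(W = 0, p = 1, df1 = g - 1, df2 = N - g))
    stop("degenerate groups: zero within-group deviation spread")
  }
  W <- num / den
  list(W = W, p = pf(W, g - 1, N - g, lower.tail = FALSE),
       df1 = g - 1, df2 = N - g)
}

#' Repeated cross-validated evaluation of the stacking pipeline
#'
#' Runs [run_nested_stacking] `R` times with freshly randomised
#' (family-respecting) fold assignments, recording per-repetition pooled
#' out-of-sample R-squared per method (accuracy) and the per-fold
#' R-squared values needed by [corrected_resampled_ttest].  The variance
#' of the per-repetition scores is the robustness metric.
#'
#' @param feature_sets,y,confounds,grid,inner_folds,standardize Passed to
#'   [run_nested_stacking].
#' @param groups Group (family) labels per subject.
#' @param n_folds Outer folds per repetition.
#' @param R Number of repetitions.
#' @param seed Base seed; repetition `i` uses a derived fold seed.
#' @return Object of class `repetition_scores`: `scores` (`R x method`
#'   matrix of pooled R-squared), `fold_scores` (`R x n_folds x method`
#'   array), `variance` (per method), `fold_seeds`, `n1`, `n2`.
#' @export
repeated_cv_evaluate <- function(feature_sets, y, confounds = NULL,
                                 groups = NULL, n_folds = 10, R = 10,
                                 grid = default_lambda_grid(), seed = 1,
                                 inner_folds = 10, standardize = TRUE) {
  stopifnot(R >= 1)
  first <- if (inherits(feature_sets, "feature_matrix")) feature_sets else
    feature_sets[[1]]
  N <- nrow(if (inherits(first, "feature_matrix")) first$values else first)
  ids <- sprintf("s%05d", seq_len(N))
  fold_seeds <- vapply(seq_len(R), function(i) child_seed(seed, i), 0L)
  scores <- NULL
  fold_scores <- NULL
  for (i in seq_len(R)) {
    scheme <- make_folds(ids, groups, n_folds = n_folds,
                         seed = fold_seeds[i])
    res <- run_nested_stacking(feature_sets, y, confounds, scheme,
                               grid = grid, seed = fold_seeds[i],
                               inner_folds = inner_folds,
                               standardize = standardize)
    r2 <- summary(res)
    if (is.null(scores)) {
      scores <- matrix(NA_real_, R, length(r2),
                       dimnames = list(NULL, names(r2)))
      fold_scores <- array(NA_real_,
                           c(R, n_folds, ncol(res$fold_r2)),
                           dimnames = list(NULL, NULL,
                                           colnames(res$fold_r2)))
    }
    scores[i, ] <- r2
    fold_scores[i, , ] <- res$fold_r2
  }
  structure(list(scores = scores, fold_scores = fold_scores,
                 variance = apply(scores, 2, var),
                 fold_seeds = fold_seeds,
                 n1 = round(N * (n_folds - 1) / n_folds),
                 n2 = round(N / n_folds)),
            class = "repetition_scores")
}

#' Compare two methods with the corrected repeated k-fold t-test
#'
#' Builds the per-(fold, repetition) accuracy differences between two
#' methods recorded by [repeated_cv_evaluate] and applies
#' [corrected_resampled_ttest].
#'
#' @param rep_scores A `repetition_scores` object.
#' @param method_a,method_b Method names (columns of the score matrix).
#' @return The t-test result list, plus the mean difference.
#' @export
compare_methods <- function(rep_scores, method_a, method_b) {
  stopifnot(inherits(rep_scores, "repetition_scores"))
  fs <- rep_scores$fold_scores
  x <- as.numeric(fs[, , method_a] - fs[, , method_b])
  k <- dim(fs)[2]
  r <- dim(fs)[1]
  out <- corrected_resampled_ttest(x, k = k, r = r,
                                   n1 = rep_scores$n1, n2 = rep_scores$n2)
  out$mean_diff <- mean(x)
  out
}

#' @export
print.repetition_scores <- function(x, ...) {
  cat(sprintf("repetition_scores: %d repetitions\n", nrow(x$scores)))
  m <- colMeans(x$scores)
  for (nm in c("stacked", "averaged")) {
    if (nm %in% names(m))
      cat(sprintf("  %s: mean R^2 %.4f (variance %.2e)\n", nm, m[[nm]],
                  x$variance[[nm]]))
  }
  invisible(x)
}
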