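# Family-aware fold construction, simplex-constrained stacking weights,
# simple averaging, and the two-inner-loop nested cross-validation
# orchestration that produces out-of-sample stacked predictions.

#' Family-aware cross-validation folds
#'
#' Assigns subjects to `n_folds` folds such that no group (e.g., family)
#' is ever split across folds: groups are shuffled by `seed` and dealt
#' greedily to the currently smallest fold.
#'
#' @param subject_ids Character or integer subject identifiers (unique).
#' @param groups Group label per subject (same order); `NULL` treats
#'   every subject as a singleton group.
#' @param n_folds Number of folds (`>= 2`).
#' @param seed Integer seed for the shuffle.
#' @return Object of class `fold_scheme`: `n_folds`, `assignment` (named
#'   integer vector, subject -> fold), `groups` (named vector), `seed`.
#' @export
make_folds <- function(subject_ids, groups = NULL, n_folds = 10, seed = 1) {
  subject_ids <- as.character(subject_ids)
  if (anyDuplicated(subject_ids)) stop("duplicate subject ids")
  if (anyNA(subject_ids)) stop("subject ids contain NA")
  if (n_folds < 2) stop("n_folds must be at least 2")
  if (is.null(groups)) groups <- subject_ids
  groups <- as.character(groups)
  stopifnot(length(groups) == length(subject_ids))
  if (anyNA(groups)) stop("group labels contain NA")
  ug <- unique(groups)
  if (length(ug) < n_folds)
    stop("fewer groups (", length(ug), ") than folds (", n_folds, ")")
  sizes <- table(groups)
  N <- length(subject_ids)
  if (any(sizes > 2 * ceiling(N / n_folds)))
    warning("a group is larger than twice the target fold size; ",
            "fold imbalance is unavoidable")
  assignment <- with_local_seed(seed, {
    order_g <- sample(ug)
    fold_of_group <- integer(length(order_g))
    fold_n <- integer(n_folds)
    for (i in seq_along(order_g)) {
      f <- which.min(fold_n)
      fold_of_group[i] <- f
      fold_n[f] <- fold_n[f] + sizes[[order_g[i]]]
    }
    names(fold_of_group) <- order_g
    out <- fold_of_group[groups]
    names(out) <- subject_ids
    out
  })
  structure(list(n_folds = as.integer(n_folds), assignment = assignment,
                 groups = stats::setNames(groups, subject_ids),
                 seed = seed),
            class = "fold_scheme")
}

#' @export
print.fold_scheme <- function(x, ...) {
  cat(sprintf("fold_scheme: %d subjects in %d folds (%d groups)\n",
              length(x$assignment), x$n_folds, length(unique(x$groups))))
  invisible(x)
}

#' Simplex-constrained stacking weights
#'
#' Solves the constrained least-squares problem
#' `min_beta || Yhat beta - y ||^2` over the probability simplex
#' (`beta_i >= 0`, `sum beta_i = 1`) by an active-set algorithm on the
#' KKT system.  The constraints force the stacked prediction to
#' interpolate the base-level predictions, which is what keeps stacking
#' well-behaved when base predictions are highly correlated.  When the
#' optimum is non-unique (collinear base predictions) the minimum-norm
#' solution among the optima on the final support is returned (via a
#' pseudo-inverse solve).
#'
#' @param Yhat `N x J` matrix of base-level predictions (the stacking
#'   meta-features, ideally out-of-sample).
#' @param y Length-`N` target vector.
#' @param tol Tolerance for the KKT / non-negativity checks.
#' @return Object of class `stacking_weights`: `beta` (length `J`,
#'   non-negative, summing to 1), `objective`, and `kkt_residual`.
#' @export
stack_weights <- function(Yhat, y, tol = 1e-10) {
  Yhat <- as.matrix(Yhat)
  J <- ncol(Yhat)
  if (J == 0) stop("at least one base model is required")
  stopifnot(nrow(Yhat) == length(y))
  if (J == 1) {
    beta <- 1
    return(structure(list(beta = beta,
                          objective = sum((Yhat[, 1] - y)^2),
                          kkt_residual = 0),
                     class = "stacking_weights"))
  }
  G <- crossprod(Yhat)
  cvec <- crossprod(Yhat, y)[, 1]

  solve_support <- function(P) {
    nP <- length(P)
    KKT <- rbind(cbind(2 * G[P, P, drop = FALSE], 1),
                 c(rep(1, nP), 0))
    rhs <- c(2 * cvec[P], 1)
    sol <- tryCatch(solve(KKT, rhs), error = function(e) NULL)
    if (is.null(sol) || any(!is.finite(sol)))
      sol <- as.numeric(MASS::ginv(KKT) %*% rhs)
    list(beta = sol[seq_len(nP)], nu = sol[nP + 1])
  }

  beta <- rep(1 / J, J)  # feasible start
  P <- seq_len(J)
  for (iter in seq_len(10L * J)) {
    sol <- solve_support(P)
    bP <- sol$beta
    if (all(bP >= -tol)) {
      full <- numeric(J)
      full[P] <- pmax(bP, 0)
      full <- full / sum(full)
      # dual feasibility for the zero set
      g <- 2 * (G %*% full - cvec)[, 1]
      nu <- if (any(full > tol)) mean(g[full > tol]) else sol$nu
      mu <- g - nu
      zero <- which(full <= tol)
      bad <- zero[mu[zero] < -1e-8 * max(1, max(abs(g)))]
      if (length(bad) == 0) {
        beta <- full
        break
      }
      beta <- full
      P <- sort(unique(c(which(full > tol), bad[which.min(mu[bad])])))
    } else {
      # step from the previous feasible point towards bP, stopping at the
      # first variable to hit zero; drop it from the support
      prev <- beta[P]
      dir <- bP - prev
      neg <- which(bP < -tol)
      steps <- prev[neg] / (prev[neg] - bP[neg])
      tstep <- max(min(steps), 0)
      newP <- prev + tstep * dir
      beta[P] <- pmax(newP, 0)
      beta[-P] <- 0
      beta <- beta / sum(beta)
      drop_idx <- P[which.min(newP)]
      P <- setdiff(P, drop_idx)
      if (length(P) == 0) P <- which.max(cvec)
    }
  }
  beta <- pmax(beta, 0)
  beta <- beta / sum(beta)
  g <- 2 * (G %*% beta - cvec)[, 1]
  support <- beta > tol
  nu <- if (any(support)) mean(g[support]) else min(g)
  kkt <- max(c(0, abs(g[support] - nu), nu - g[!support]))
  structure(list(beta = beta,
                 objective = sum((Yhat %*% beta - y)^2),
                 kkt_residual = kkt),
            class = "stacking_weights")
}

#' @export
print.stacking_weights <- function(x, ...) {
  cat("stacking weights:", paste(signif(x$beta, 3), collapse = " "), "\n")
  invisible(x)
}

#' Simple averaging of base-level predictions
#'
#' Row means of the base-prediction matrix: the uniform-weight special
#' case of stacking, with every base model contributing equally.
#'
#' @param Yhat `N x J` matrix of base-level predictions.
#' @return Length-`N` vector.
#' @export
average_predictions <- function(Yhat) {
  Yhat <- as.matrix(Yhat)
  stopifnot(ncol(Yhat) >= 1)
  rowMeans(Yhat)
}

#' Nested cross-validated stacking
#'
#' The full orchestration: for each outer fold, the outer-training
#' subjects are split into `inner_folds` folds shared by two inner
#' loops.  Inner loop 1 selects the ridge penalty per base model by
#' cross-validated MSE; inner loop 2 re-uses those penalties to build
#' out-of-sample base predictions for all outer-training subjects, on
#' which the simplex-constrained stacking weights are fitted.  Each base
#' model is then refitted on the full outer-training set with its
#' selected penalty, predicts the outer test fold, and the fold's weights
#' combine these into the stacked out-of-sample prediction (simple
#' averaging and the individual base predictions are recorded from the
#' same test predictions).  Deconfounding (when confounds are given) and
#' feature standardisation are fitted on outer-training subjects only and
#' applied to both sides of every split.
#'
#' @param feature_sets List of `feature_matrix` objects (or plain `N x D`
#'   matrices), one per base model; names become model tags.
#' @param y Length-`N` trait vector.
#' @param confounds Optional `N x C` confound matrix; when supplied, both
#'   features and trait are residualised with training-estimated
#'   parameters before the kernel regression.
#' @param scheme A [fold_scheme] covering all `N` subjects (outer folds).
#' @param grid Candidate ridge penalties (default: 17 log-spaced values,
#'   `1e-4` to `1e4`).
#' @param seed Integer seed (drives the inner fold shuffles).
#' @param inner_folds Number of inner folds (default 10).
#' @param standardize Z-score feature columns with training-fold
#'   statistics before the kernel step (recommended: keeps transition and
#'   mean blocks on the same scale as the tangent blocks).
#' @return Object of class `stacked_result`: `predictions` (data frame
#'   with subject, fold, adjusted trait, stacked / averaged / per-base
#'   out-of-sample predictions), `weights` (fold x J), `lambda`
#'   (fold x J), `fold_r2` (fold x method), `model_tags`, `scheme`,
#'   `seed`.
#' @export
run_nested_stacking <- function(feature_sets, y, confounds = NULL, scheme,
                                grid = default_lambda_grid(), seed = 1,
                                inner_folds = 10, standardize = TRUE) {
  stopifnot(inherits(scheme, "fold_scheme"))
  if (!is.list(feature_sets) || inherits(feature_sets, "feature_matrix"))
    feature_sets <- list(feature_sets)
  J <- length(feature_sets)
  mats <- lapply(feature_sets, function(U)
    if (inherits(U, "feature_matrix")) U$values else as.matrix(U))
  N <- length(scheme$assignment)
  ids <- names(scheme$assignment)
  if (any(vapply(mats, nrow, 0L) != N))
    stop("every feature set must cover all ", N, " subjects")
  stopifnot(length(y) == N)
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    stopifnot(nrow(confounds) == N)
  }
  grid <- sort(unique(as.numeric(grid)))
  tags <- names(feature_sets)
  if (is.null(tags) || any(!nzchar(tags)))
    tags <- sprintf("model%02d", seq_len(J))

  assign_outer <- scheme$assignment
  folds <- sort(unique(assign_outer))
  weights <- matrix(NA_real_, length(folds), J,
                    dimnames = list(NULL, tags))
  lambdas <- matrix(NA_real_, length(folds), J,
                    dimnames = list(NULL, tags))
  pred <- data.frame(subject = ids, fold = as.integer(assign_outer),
                     y_adjusted = NA_real_, stacked = NA_real_,
                     averaged = NA_real_, stringsAsFactors = FALSE)
  base_pred <- matrix(NA_real_, N, J, dimnames = list(NULL, tags))
  methods <- c("stacked", "averaged", tags)
  fold_r2 <- matrix(NA_real_, length(folds), length(methods),
                    dimnames = list(NULL, methods))

  for (fi in seq_along(folds)) {
    f <- folds[fi]
    te <- which(assign_outer == f)
    tr <- which(assign_outer != f)
    if (length(intersect(te, tr)) > 0)
      stop("internal error: train/test overlap")   # defensive

    if (!is.null(confounds)) {
      dm_y <- fit_deconfound(y[tr], confounds[tr, , drop = FALSE])
      y_tr <- apply_deconfound(dm_y, y[tr], confounds[tr, , drop = FALSE])
      y_te <- apply_deconfound(dm_y, y[te], confounds[te, , drop = FALSE])
    } else {
      y_tr <- y[tr]
      y_te <- y[te]
    }

    inner <- make_folds(ids[tr], scheme$groups[tr],
                        n_folds = inner_folds,
                        seed = child_seed(seed, fi))
    in_assign <- inner$assignment
    inner_ids <- sort(unique(in_assign))

    inner_oos <- matrix(NA_real_, length(tr), J)
    test_pred <- matrix(NA_real_, length(te), J)
    for (j in seq_len(J)) {
      U <- mats[[j]]
      if (!is.null(confounds)) {
        dm_U <- fit_deconfound(U[tr, , drop = FALSE],
                               confounds[tr, , drop = FALSE])
        U_tr <- apply_deconfound(dm_U, U[tr, , drop = FALSE],
                                 confounds[tr, , drop = FALSE])
        U_te <- apply_deconfound(dm_U, U[te, , drop = FALSE],
                                 confounds[te, , drop = FALSE])
      } else {
        U_tr <- U[tr, , drop = FALSE]
        U_te <- U[te, , drop = FALSE]
      }
      if (standardize) {
        std <- fit_standardizer(U_tr)
        U_tr <- apply_standardizer(std, U_tr)
        U_te <- apply_standardizer(std, U_te)
      }

      # inner loop 1: lambda selection; predictions cached per fold so
      # inner loop 2 can reuse them at the selected lambda
      mse <- matrix(NA_real_, length(inner_ids), length(grid))
      cache <- vector("list", length(inner_ids))
      for (gi in seq_along(inner_ids)) {
        ite <- in_assign == inner_ids[gi]
        itr <- !ite
        preds <- ridge_sweep(U_tr[itr, , drop = FALSE], y_tr[itr],
                             U_tr[ite, , drop = FALSE], grid)
        mse[gi, ] <- colMeans((y_tr[ite] - preds)^2)
        cache[[gi]] <- preds
      }
      sel <- select_from_cv_curve(mse, grid)
      lambdas[fi, j] <- sel$lambda
      gstar <- which(grid == sel$lambda)

      # inner loop 2 meta-features: inner out-of-sample predictions
      for (gi in seq_along(inner_ids)) {
        ite <- in_assign == inner_ids[gi]
        inner_oos[ite, j] <- cache[[gi]][, gstar]
      }

      # refit on the full outer-training set, predict the test fold
      test_pred[, j] <- ridge_sweep(U_tr, y_tr, U_te, sel$lambda)[, 1]
    }

    w <- stack_weights(inner_oos, y_tr)
    weights[fi, ] <- w$beta
    pred$y_adjusted[te] <- y_te
    pred$stacked[te] <- as.numeric(test_pred %*% w$beta)
    pred$averaged[te] <- rowMeans(test_pred)
    base_pred[te, ] <- test_pred

    fold_r2[fi, "stacked"] <- r_squared(y_te, pred$stacked[te])
    fold_r2[fi, "averaged"] <- r_squared(y_te, pred$averaged[te])
    for (j in seq_len(J)) fold_r2[fi, tags[j]] <- r_squared(y_te, test_pred[, j])
  }

  pred <- cbind(pred, as.data.frame(base_pred))
  structure(list(predictions = pred, weights = weights, lambda = lambdas,
                 fold_r2 = fold_r2, model_tags = tags, scheme = scheme,
                 seed = seed),
            class = "stacked_result")
}

#' Default ridge-penalty grid
#'
#' Seventeen logarithmically spaced values from `1e-4` to `1e4`.
#' @export
default_lambda_grid <- function() 10^seq(-4, 4, length.out = 17)

#' Out-of-sample accuracy of a stacked result
#'
#' Coefficient of determination between the (confound-adjusted) trait and
#' each method's pooled out-of-sample predictions.
#'
#' @param object A `stacked_result`.
#' @param ... Unused.
#' @return Named numeric vector: `stacked`, `averaged`, one entry per
#'   base model.
#' @export
summary.stacked_result <- function(object, ...) {
  p <- object$predictions
  methods <- c("stacked", "averaged", object$model_tags)
  vapply(methods, function(m) r_squared(p$y_adjusted, p[[m]]), 0.0)
}

#' @export
print.stacked_result <- function(x, ...) {
  r2 <- summary(x)
  cat(sprintf("stacked_result: %d subjects, %d base models, %d folds\n",
              nrow(x$predictions), length(x$model_tags),
              x$scheme$n_folds))
  cat(sprintf("  out-of-sample R^2: stacked %.4f | averaged %.4f | ",
              r2[["stacked"]], r2[["averaged"]]))
  cat(sprintf("base mean %.4f (best %.4f)\n",
              mean(r2[x$model_tags]), max(r2[x$model_tags])))
  invisible(x)
}
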