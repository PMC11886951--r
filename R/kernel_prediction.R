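# Linear-kernel construction, confound removal with training-estimated
# parameters, kernel ridge regression, and cross-validated selection of
# the ridge penalty.

#' Linear kernel matrix
#'
#' `K_L(m, n) = U_m . U_n`, the Gram matrix of the feature rows.  With
#' one argument the square (symmetric, positive semi-definite) kernel is
#' returned; with two, the rectangular test-by-train cross-kernel.
#'
#' @param U A `feature_matrix` or plain numeric matrix (subjects in rows).
#' @param U2 Optional second feature set (the training set for a
#'   cross-kernel).
#' @return Numeric kernel matrix.
#' @export
linear_kernel <- function(U, U2 = NULL) {
  A <- if (inherits(U, "feature_matrix")) U$values else as.matrix(U)
  if (anyNA(A)) stop("features contain missing values")
  if (is.null(U2)) {
    K <- tcrossprod(A)
    return((K + t(K)) / 2)
  }
  B <- if (inherits(U2, "feature_matrix")) U2$values else as.matrix(U2)
  if (anyNA(B)) stop("features contain missing values")
  if (ncol(A) != ncol(B)) stop("feature dimension mismatch")
  tcrossprod(A, B)
}

#' Fit / apply confound regression
#'
#' Fits, per column of `values`, an ordinary least-squares regression on
#' `[1, confounds]` using the supplied (training) rows, and stores the
#' coefficients so the fitted nuisance component can later be subtracted
#' from any data -- training or test -- measured with the same confounds.
#' Estimating on training rows only and applying everywhere is what keeps
#' deconfounding leakage-free.
#'
#' @param values `N x P` numeric matrix (or vector) of variables to
#'   residualise.
#' @param confounds `N x C` numeric matrix of confound values.
#' @return `fit_deconfound` returns a `deconfound_model` (regression
#'   coefficients including intercept); `apply_deconfound` returns the
#'   residualised matrix (or vector, matching the input shape).
#' @export
fit_deconfound <- function(values, confounds) {
  v <- as.matrix(values)
  X <- cbind(1, as.matrix(confounds))
  if (nrow(v) != nrow(X)) stop("values and confounds disagree on rows")
  if (anyNA(X)) stop("confounds contain missing values")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    warning("rank-deficient confound matrix; using a ridge-stabilised fit")
    coef <- solve(crossprod(X) + diag(1e-8, ncol(X)), crossprod(X, v))
  } else {
    coef <- qr.coef(qrX, v)
  }
  structure(list(coefficients = coef, n_confounds = ncol(X) - 1L),
            class = "deconfound_model")
}

#' @rdname fit_deconfound
#' @param model A `deconfound_model`.
#' @export
apply_deconfound <- function(model, values, confounds) {
  stopifnot(inherits(model, "deconfound_model"))
  v <- as.matrix(values)
  X <- cbind(1, as.matrix(confounds))
  if (ncol(X) - 1L != model$n_confounds)
    stop("confound count differs from the fitted model")
  out <- v - X %*% model$coefficients
  if (is.null(dim(values))) drop(out) else out
}

#' Kernel ridge regression fit
#'
#' Solves `alpha = (K_L + lambda I)^-1 y` by a symmetric linear solve
#' (never an explicit inverse).  `lambda = 0` is permitted when the
#' kernel is invertible (exact interpolation).
#'
#' @param K_train Square training kernel matrix.
#' @param y Training targets.
#' @param lambda Ridge penalty (`>= 0`).
#' @return Object of class `krr_model` with coefficients `alpha`.
#' @export
krr_fit <- function(K_train, y, lambda) {
  K_train <- as.matrix(K_train)
  stopifnot(nrow(K_train) == ncol(K_train), length(y) == nrow(K_train),
            lambda >= 0)
  Kl <- K_train + diag(lambda, nrow(K_train))
  alpha <- tryCatch(
    solve(Kl, y),
    error = function(e)
      stop("kernel system is singular at lambda = ", lambda,
           "; use lambda > 0", call. = FALSE))
  structure(list(alpha = as.numeric(alpha), lambda = lambda,
                 n_train = nrow(K_train)),
            class = "krr_model")
}

#' Kernel ridge regression prediction
#'
#' @param model A `krr_model`.
#' @param K_cross Rectangular test-by-train kernel whose columns are
#'   ordered exactly as the training subjects used in [krr_fit] (a
#'   mismatch in column count is an error; no silent reordering).
#' @return Numeric vector of predictions `K_cross alpha`.
#' @export
krr_predict <- function(model, K_cross) {
  stopifnot(inherits(model, "krr_model"))
  K_cross <- if (is.null(dim(K_cross))) matrix(K_cross, nrow = 1) else
    as.matrix(K_cross)
  if (ncol(K_cross) != model$n_train)
    stop("K_cross has ", ncol(K_cross), " columns but the model was ",
         "trained on ", model$n_train, " subjects (order must match)")
  as.numeric(K_cross %*% model$alpha)
}

# Shared selection rule: given a folds x lambda matrix of out-of-fold
# MSEs, pick the lambda minimising the mean; ties break to the LARGER
# lambda (heavier regularisation).
select_from_cv_curve <- function(mse, grid) {
  curve <- colMeans(mse)
  best <- max(which(curve <= min(curve) + 1e-12))
  list(lambda = grid[best], cv_curve = curve)
}

#' Cross-validated selection of the ridge penalty
#'
#' For every candidate `lambda`, fits KRR on each training portion of the
#' supplied folds and records the mean out-of-fold squared error; returns
#' the minimiser, breaking ties towards heavier regularisation.
#'
#' @param K Square kernel matrix over the selection cohort.
#' @param y Targets.
#' @param folds A fold scheme from [make_folds] over the same subjects
#'   (or an integer fold-assignment vector).
#' @param grid Strictly positive candidate penalties (duplicates are
#'   removed).
#' @return List with `lambda` (the selected value) and `cv_curve` (mean
#'   out-of-fold MSE per grid value).
#' @export
select_lambda <- function(K, y, folds, grid) {
  K <- as.matrix(K)
  assign <- if (inherits(folds, "fold_scheme")) folds$assignment else
    as.integer(folds)
  stopifnot(length(assign) == nrow(K), length(y) == nrow(K))
  grid <- sort(unique(as.numeric(grid)))
  if (length(grid) < 1 || any(grid <= 0))
    stop("lambda grid must be non-empty and strictly positive")
  fold_ids <- sort(unique(assign))
  if (length(fold_ids) > length(y))
    stop("more folds than subjects")
  mse <- matrix(NA_real_, length(fold_ids), length(grid))
  for (f in seq_along(fold_ids)) {
    te <- assign == fold_ids[f]
    tr <- !te
    e <- eigen(K[tr, tr, drop = FALSE], symmetric = TRUE)
    Qy <- crossprod(e$vectors, y[tr])
    Kc <- K[te, tr, drop = FALSE] %*% e$vectors
    for (g in seq_along(grid)) {
      pred <- Kc %*% (Qy / (e$values + grid[g]))
      mse[f, g] <- mean((y[te] - pred)^2)
    }
  }
  select_from_cv_curve(mse, grid)
}

#' Write / read a kernel matrix as delimited text
#'
#' Stores the kernel with subject identifiers as header row and first
#' column, so row/column order is explicit on disk.
#'
#' @param K Kernel matrix.
#' @param ids Subject identifiers for the rows (and, for a square
#'   kernel, the columns); defaults to existing dimnames.
#' @param path CSV file path.
#' @export
write_kernel <- function(K, path, ids = rownames(K)) {
  K <- as.matrix(K)
  if (is.null(ids)) ids <- sprintf("s%05d", seq_len(nrow(K)))
  col_ids <- if (nrow(K) == ncol(K)) ids else colnames(K)
  if (is.null(col_ids)) col_ids <- sprintf("t%05d", seq_len(ncol(K)))
  df <- data.frame(id = ids, K, check.names = FALSE)
  names(df) <- c("id", col_ids)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kernel
#' @export
read_kernel <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  K <- as.matrix(df[, -1, drop = FALSE])
  rownames(K) <- df$id
  K
}

# --- internal fast primal path ----------------------------------------

# Ridge sweep through the SVD of the training features: predictions for
# every lambda in one pass.  Algebraically identical to the kernel form
# (K = U U') -- the primal-dual equivalence exercised in the tests -- but
# O(N D^2) instead of O(N^3) per training set.
ridge_sweep <- function(U_train, y_train, U_test, grid) {
  sv <- svd(U_train)
  ym <- mean(y_train)
  Wy <- crossprod(sv$u, y_train - ym)
  P <- U_test %*% sv$v
  out <- matrix(ym, nrow(U_test), length(grid))
  for (g in seq_along(grid)) {
    out[, g] <- out[, g] + P %*% (Wy * sv$d / (sv$d^2 + grid[g]))
  }
  out
}

# Z-scoring with training statistics; constant columns pass through
# unscaled.
fit_standardizer <- function(U) {
  mu <- colMeans(U)
  s <- apply(U, 2, sd)
  s[!is.finite(s) | s < 1e-12] <- 1
  list(mean = mu, sd = s)
}

apply_standardizer <- function(std, U) {
  sweep(sweep(U, 2L, std$mean, "-"), 2L, std$sd, "/")
}
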