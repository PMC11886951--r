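# SPD-geometry feature extraction: regularised precision matrices,
# partial correlations, the affine-invariant Riemannian (Karcher) mean,
# tangent-space projection, isometric vectorisation, and assembly of the
# subject-by-feature matrix used for prediction.

# Eigendecomposition-based helpers for symmetric matrices. `floor_ev`
# guards the log/inverse-sqrt maps against non-PD inputs.
sym_eigen <- function(S, name = "matrix") {
  S <- check_symmetric(S, 1e-8, name)
  eigen(S, symmetric = TRUE)
}

logm_sym <- function(S, name = "matrix") {
  e <- sym_eigen(S, name)
  if (min(e$values) <= 0)
    stop(name, " is not positive definite (eigenvalue ",
         format(min(e$values)), ")")
  e$vectors %*% (log(e$values) * t(e$vectors))
}

expm_sym <- function(S, name = "matrix") {
  e <- sym_eigen(S, name)
  e$vectors %*% (exp(e$values) * t(e$vectors))
}

powm_sym <- function(S, p, name = "matrix") {
  e <- sym_eigen(S, name)
  if (min(e$values) <= 0 && p < 0)
    stop(name, " is not positive definite")
  e$vectors %*% (e$values^p * t(e$vectors))
}

#' Precision matrix via Cholesky factorisation
#'
#' Inverts a symmetric positive-definite covariance matrix through its
#' Cholesky factor `Sigma = R' R`, returning
#' `Omega = R^-1 (R^-1)'`, the precision matrix.
#'
#' @param Sigma Symmetric positive-definite matrix.
#' @return The precision (inverse covariance) matrix.
#' @export
cholesky_precision <- function(Sigma) {
  Sigma <- check_symmetric(Sigma, 1e-8, "Sigma")
  R <- chol_or_stop(Sigma, "Sigma")
  Rinv <- backsolve(R, diag(nrow(Sigma)))
  Omega <- tcrossprod(Rinv)
  (Omega + t(Omega)) / 2
}

#' Tikhonov-regularised precision matrix
#'
#' Returns `(Sigma + a I)^-1`.  The ridge term `a >= 0` stabilises the
#' inversion of poorly conditioned (or singular, when `a > 0`) covariance
#' estimates, which is routine for state covariances estimated from short
#' scans.
#'
#' @param Sigma Symmetric positive semi-definite matrix.
#' @param a Non-negative regularisation parameter.
#' @return Symmetric positive-definite precision matrix.
#' @export
regularized_precision <- function(Sigma, a = 0.1) {
  stopifnot(a >= 0)
  Sigma <- check_symmetric(Sigma, 1e-8, "Sigma")
  cholesky_precision(Sigma + diag(a, nrow(Sigma)))
}

#' Partial correlation matrix from a precision matrix
#'
#' Off-diagonal entries are `-p_ij / sqrt(p_ii p_jj)` -- the correlation
#' between two channels after conditioning on all others.  The diagonal
#' is set to 1 by the usual self-correlation convention.
#'
#' @param Omega Precision matrix with strictly positive diagonal.
#' @return Symmetric matrix with unit diagonal and entries in `[-1, 1]`.
#' @export
partial_correlation <- function(Omega) {
  Omega <- check_symmetric(Omega, 1e-8, "Omega")
  d <- diag(Omega)
  if (any(d <= 0)) stop("precision matrix must have a positive diagonal")
  s <- 1 / sqrt(d)
  rho <- -Omega * tcrossprod(s)
  diag(rho) <- 1
  pmin(pmax(rho, -1), 1)
}

#' Riemannian (Karcher) mean of SPD matrices
#'
#' Computes the affine-invariant Riemannian barycentre of a set of
#' symmetric positive-definite matrices by fixed-point iteration: at each
#' step the current estimate `G` is moved along the mean of the log-mapped
#' inputs, `G <- G^1/2 expm(mean_n logm(G^-1/2 C_n G^-1/2)) G^1/2`,
#' until the Frobenius norm of that mean tangent vector (the Riemannian
#' gradient) falls below `tol`.
#'
#' @param mats Non-empty list of SPD matrices of common dimension.
#' @param tol Convergence tolerance on the gradient norm.
#' @param max_iter Maximum fixed-point iterations.
#' @return The SPD mean matrix.
#' @export
riemannian_mean <- function(mats, tol = 1e-10, max_iter = 100) {
  stopifnot(is.list(mats), length(mats) >= 1)
  if (length(mats) == 1) return(check_symmetric(mats[[1]], 1e-8, "input"))
  M <- nrow(mats[[1]])
  G <- Reduce(`+`, mats) / length(mats)  # arithmetic mean as warm start
  for (it in seq_len(max_iter)) {
    e <- sym_eigen(G, "current mean")
    if (min(e$values) <= 0) stop("mean iterate lost positive definiteness")
    Gh <- e$vectors %*% (sqrt(e$values) * t(e$vectors))
    Gih <- e$vectors %*% ((1 / sqrt(e$values)) * t(e$vectors))
    Tm <- matrix(0, M, M)
    for (C in mats) Tm <- Tm + logm_sym(Gih %*% C %*% Gih, "whitened input")
    Tm <- Tm / length(mats)
    gnorm <- sqrt(sum(Tm^2))
    if (gnorm < tol) return((G + t(G)) / 2)
    G <- Gh %*% expm_sym(Tm) %*% Gh
    G <- (G + t(G)) / 2
  }
  stop("Karcher mean did not converge within ", max_iter,
       " iterations (gradient norm ", format(gnorm), ")")
}

#' Tangent-space projection (logarithmic map)
#'
#' Projects an SPD matrix `C` onto the tangent space of the SPD manifold
#' at the reference point `C_G`:
#' `logm(C_G^-1/2 C C_G^-1/2)`.  After this whitening-and-log step,
#' Euclidean operations on the projected matrices approximate Riemannian
#' operations on the originals, which is what makes linear kernels over
#' covariance features geometrically defensible.
#'
#' @param C SPD matrix to project.
#' @param C_G SPD reference point (typically the Riemannian mean of the
#'   cohort).
#' @return Symmetric matrix (a tangent vector at `C_G`).
#' @export
tangent_project <- function(C, C_G) {
  stopifnot(nrow(C) == nrow(C_G))
  Gih <- powm_sym(C_G, -0.5, "reference")
  W <- Gih %*% C %*% Gih
  out <- logm_sym((W + t(W)) / 2, "whitened matrix")
  (out + t(out)) / 2
}

#' Isometric vectorisation of a symmetric matrix
#'
#' Returns the row-major upper triangle (including the diagonal) with
#' off-diagonal entries scaled by `sqrt(2)`, so the Euclidean norm of the
#' vector equals the Frobenius norm of the matrix, and Euclidean
#' distances between vectorised tangent matrices equal Frobenius
#' distances between the matrices themselves.
#'
#' @param S Symmetric matrix (asymmetry beyond `1e-8` is an error).
#' @return Numeric vector of length `M (M + 1) / 2`.
#' @export
vectorize_symmetric <- function(S) {
  S <- check_symmetric(S, 1e-8, "S")
  M <- nrow(S)
  idx <- upper.tri(S, diag = TRUE)
  scale <- matrix(sqrt(2), M, M)
  diag(scale) <- 1
  # row-major upper triangle == column-major of the transpose
  (t(S) * t(scale))[t(idx)]
}

feature_matrix <- function(values, block_index) {
  stopifnot(is.matrix(values), nrow(block_index) == ncol(values))
  if (any(!is.finite(values))) stop("feature matrix contains non-finite entries")
  structure(list(values = values, block_index = block_index),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d subjects x %d features (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$block_index$block), collapse = ", ")))
  invisible(x)
}

# Tangent-project one state's matrices across subjects around their
# Riemannian mean and return the N x M(M+1)/2 block.
project_block <- function(mats, mean_tol = 1e-9) {
  ref <- riemannian_mean(mats, tol = mean_tol)
  Gih <- powm_sym(ref, -0.5, "reference")
  t(vapply(mats, function(C) {
    W <- Gih %*% C %*% Gih
    vectorize_symmetric(logm_sym((W + t(W)) / 2, "whitened matrix"))
  }, numeric(nrow(ref) * (nrow(ref) + 1) / 2)))
}

#' Assemble the subject-by-feature matrix from dual-estimated parameters
#'
#' For every state `k`, each subject's state covariance is turned into a
#' Tikhonov-regularised precision matrix, the Riemannian mean of those
#' matrices across subjects is taken as the tangent reference, and each
#' subject's matrix is log-mapped and vectorised.  The per-state tangent
#' blocks are concatenated and optionally followed by the flattened state
#' means and the row-major transition matrix.
#'
#' @param subjects List of `subject_params` (one per subject, shared `K`
#'   and `M`).
#' @param a Tikhonov regularisation for the precision step.  Default
#'   `NULL` selects `0.1` for `K <= 6` and `0.5` for larger state counts
#'   (higher `K` means fewer time points per state and noisier
#'   covariances).
#' @param use_precision Project regularised precisions (default); when
#'   `FALSE`, project the (regularised) covariances instead.
#' @param include_means,include_transitions Append state-mean and
#'   transition-probability feature blocks.
#' @return A `feature_matrix`: `values` (`N x D`) and `block_index`
#'   (data frame mapping each column to its source block and state).
#' @export
assemble_features <- function(subjects, a = NULL, use_precision = TRUE,
                              include_means = TRUE,
                              include_transitions = TRUE) {
  stopifnot(is.list(subjects), length(subjects) >= 1)
  K <- length(subjects[[1]]$pi)
  M <- ncol(subjects[[1]]$mu)
  ok <- vapply(subjects, function(s)
    length(s$pi) == K && ncol(s$mu) == M, TRUE)
  if (!all(ok)) stop("subjects disagree on K or M")
  if (is.null(a)) a <- if (K <= 6) 0.1 else 0.5

  blocks <- list()
  index <- list()
  for (k in seq_len(K)) {
    mats <- lapply(subjects, function(s) {
      if (use_precision) regularized_precision(s$Sigma[, , k], a)
      else s$Sigma[, , k] + diag(a, M)
    })
    B <- project_block(mats)
    blocks[[length(blocks) + 1L]] <- B
    index[[length(index) + 1L]] <- data.frame(
      block = sprintf("state%d_tangent", k), state = k,
      within = seq_len(ncol(B)))
  }
  if (include_means) {
    B <- t(vapply(subjects, function(s) as.vector(t(s$mu)), numeric(K * M)))
    blocks[[length(blocks) + 1L]] <- B
    index[[length(index) + 1L]] <- data.frame(
      block = "state_means", state = rep(seq_len(K), each = M),
      within = rep(seq_len(M), K))
  }
  if (include_transitions) {
    B <- t(vapply(subjects, function(s) as.vector(t(s$A)), numeric(K * K)))
    blocks[[length(blocks) + 1L]] <- B
    index[[length(index) + 1L]] <- data.frame(
      block = "transitions", state = rep(seq_len(K), each = K),
      within = rep(seq_len(K), K))
  }
  values <- do.call(cbind, blocks)
  idx <- do.call(rbind, index)
  idx$column <- seq_len(nrow(idx))
  feature_matrix(values, idx[, c("column", "block", "state", "within")])
}

#' Static functional-connectivity features
#'
#' The time-averaged branch of the pipeline: each subject's covariance
#' over the whole scan is regularised and inverted, the cohort Riemannian
#' mean of those precisions is used as the tangent reference, and each
#' subject's matrix is log-mapped and vectorised -- the same geometry as
#' the per-state dynamic features, with temporal order discarded.
#'
#' @param dataset List of per-subject `T_n x M` matrices (`T_n >= 2`).
#' @param a Tikhonov regularisation (default 0.1).
#' @return A `feature_matrix` with a single `"static"` block.
#' @export
static_fc_features <- function(dataset, a = 0.1) {
  stopifnot(is.list(dataset), length(dataset) >= 1)
  M <- ncol(dataset[[1]])
  if (!all(vapply(dataset, ncol, 0L) == M))
    stop("all subjects must share the same number of channels")
  if (any(vapply(dataset, nrow, 0L) < 2))
    stop("each subject needs at least 2 time points to estimate covariance")
  mats <- lapply(dataset, function(X) regularized_precision(cov(X), a))
  B <- project_block(mats)
  idx <- data.frame(column = seq_len(ncol(B)), block = "static",
                    state = NA_integer_, within = seq_len(ncol(B)))
  feature_matrix(B, idx)
}

#' Write / read a feature matrix
#'
#' Persists `values` as delimited text (CSV) with a JSON sidecar for the
#' block index.
#'
#' @param fm A `feature_matrix`.
#' @param path CSV output path; the sidecar is written to
#'   `paste0(path, ".blocks.json")`.
#' @export
write_features <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  write.csv(fm$values, path, row.names = FALSE)
  jsonlite::write_json(fm$block_index, paste0(path, ".blocks.json"),
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  values <- as.matrix(read.csv(path, check.names = FALSE))
  idx <- jsonlite::read_json(paste0(path, ".blocks.json"),
                             simplifyVector = TRUE)
  feature_matrix(unname(values), as.data.frame(idx))
}
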