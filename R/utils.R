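# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.  All user-facing randomness in the
# package goes through this so that seeds compose predictably.
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    set.seed(as.integer(seed))
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
  }
  force(expr)
}

# Derive a child seed from a parent seed and a stream index, staying within
# 32-bit integer range.
child_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(stream)) %%
               2147483647)
}

is_square_matrix <- function(x) is.matrix(x) && nrow(x) == ncol(x)

check_symmetric <- function(S, tol = 1e-8, name = "matrix") {
  if (!is_square_matrix(S)) stop(name, " must be a square matrix")
  if (max(abs(S - t(S))) > tol)
    stop(name, " is not symmetric (max asymmetry ",
         format(max(abs(S - t(S)))), ")")
  invisible((S + t(S)) / 2)
}

# Cholesky factor with an informative error; `what` names the offender.
chol_or_stop <- function(S, what = "matrix") {
  out <- tryCatch(chol(S), error = function(e) {
    stop(what, " is not positive definite (Cholesky factorisation failed)",
         call. = FALSE)
  })
  out
}

# Log density of rows of X under N(mu, Sigma); returns length-T vector.
mvn_logdensity <- function(X, mu, Sigma, chol_R = NULL) {
  M <- ncol(X)
  R <- if (is.null(chol_R)) chol_or_stop(Sigma, "covariance") else chol_R
  Xc <- sweep(X, 2L, mu, "-")
  W <- backsolve(R, t(Xc), transpose = TRUE)
  -0.5 * (M * log(2 * pi) + 2 * sum(log(diag(R))) + colSums(W^2))
}

# Sample n draws from N(mu, Sigma) (rows), using the current RNG stream.
mvn_sample <- function(n, mu, Sigma) {
  M <- length(mu)
  R <- chol_or_stop(Sigma, "covariance")
  Z <- matrix(rnorm(n * M), n, M)
  sweep(Z %*% R, 2L, mu, "+")
}

# All permutations of 1..n (n <= 8); used for state matching.
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1L)) {
    for (i in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = i - 1L)
    }
  }
  out
}

#' Match estimated HMM states to reference states
#'
#' Finds the permutation of estimated states minimising the total distance
#' to a set of reference states, by exhaustive enumeration (practical for
#' the small state counts used here, `K <= 8`).  Distance between a pair
#' of states is the Euclidean distance between their mean vectors plus the
#' Frobenius distance between their covariance matrices.
#'
#' State identity in a fitted HMM is arbitrary (label switching), so any
#' comparison against generating parameters must first align the labels.
#'
#' @param est,ref [hmm_params] objects with equal `K` and `M`.
#' @return An integer permutation `p` such that state `p[k]` of `est`
#'   corresponds to state `k` of `ref`.
#' @export
match_states <- function(est, ref) {
  K <- length(ref$pi)
  if (K > 8) stop("exhaustive state matching supports K <= 8")
  D <- matrix(0, K, K)
  for (i in seq_len(K)) {
    for (j in seq_len(K)) {
      D[i, j] <- sqrt(sum((ref$mu[i, ] - est$mu[j, ])^2)) +
        sqrt(sum((ref$Sigma[, , i] - est$Sigma[, , j])^2))
    }
  }
  perms <- all_permutations(K)
  costs <- vapply(perms, function(p) sum(D[cbind(seq_len(K), p)]), 0.0)
  unlist(perms[[which.min(costs)]])
}
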