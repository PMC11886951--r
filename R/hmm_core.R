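# Gaussian hidden Markov model: parameter containers, sampling,
# forward-backward inference, group-level MAP-EM fitting with a Dirichlet
# self-transition prior, and subject-level dual estimation.

#' HMM parameter set
#'
#' Bundles the parameters of a `K`-state Gaussian hidden Markov model over
#' `M` channels (e.g., parcellated brain regions): initial state
#' probabilities `pi`, row-stochastic transition matrix `A`, state mean
#' vectors `mu` (K x M) and state covariance matrices `Sigma`
#' (M x M x K).  Each state is a Gaussian observation model whose mean can
#' be read as regional amplitude and whose covariance as within-state
#' functional connectivity.
#'
#' @param pi Length-`K` probability vector.
#' @param A `K x K` row-stochastic matrix.
#' @param mu `K x M` matrix of state means.
#' @param Sigma `M x M x K` array of symmetric positive-definite state
#'   covariances (a single matrix is accepted when `K = 1`).
#' @return An object of class `hmm_params`.
#' @export
hmm_params <- function(pi, A, mu, Sigma) {
  pi <- as.numeric(pi)
  A <- as.matrix(A)
  mu <- as.matrix(mu)
  if (length(dim(Sigma)) == 2L) Sigma <- array(Sigma, c(dim(Sigma), 1L))
  K <- length(pi)
  M <- ncol(mu)
  if (!all(dim(A) == c(K, K))) stop("A must be K x K")
  if (nrow(mu) != K) stop("mu must have K rows")
  if (!all(dim(Sigma) == c(M, M, K))) stop("Sigma must be M x M x K")
  if (any(pi < 0) || abs(sum(pi) - 1) > 1e-10)
    stop("pi must be a probability vector summing to 1")
  if (any(A < 0) || any(abs(rowSums(A) - 1) > 1e-10))
    stop("rows of A must be non-negative and sum to 1 (within 1e-10)")
  for (k in seq_len(K)) {
    check_symmetric(Sigma[, , k], 1e-8, sprintf("Sigma[state %d]", k))
    tryCatch(chol(Sigma[, , k]), error = function(e) {
      stop(sprintf("covariance of state %d is not positive definite", k),
           call. = FALSE)
    })
  }
  structure(list(pi = pi, A = A, mu = mu, Sigma = Sigma),
            class = "hmm_params")
}

#' @export
print.hmm_params <- function(x, ...) {
  cat(sprintf("Gaussian HMM parameters: K = %d states, M = %d channels\n",
              length(x$pi), ncol(x$mu)))
  cat("transition diagonal:", paste(signif(diag(x$A), 3), collapse = " "),
      "\n")
  invisible(x)
}

#' HMM fitting hyperparameters
#'
#' @param K Number of hidden states.  The default `K = 6` is a common
#'   choice for resting-state fMRI work, balancing state granularity
#'   against the risk of states visited by only a few subjects.
#' @param delta Non-negative concentration of the Dirichlet prior on the
#'   self-transition (diagonal) entries of the transition matrix, entering
#'   the M-step as `delta` pseudo-counts on each diagonal cell.  Larger
#'   values favour temporally persistent states and hence slower state
#'   dynamics; `delta = 10` is the conventional default.
#' @param model_mean When `FALSE` all state means are pinned at zero, so
#'   states are distinguished by covariance (functional connectivity)
#'   alone.
#' @param max_iter Maximum EM iterations.
#' @param tol Convergence tolerance on the relative change of the
#'   penalised log-likelihood between iterations.
#' @param batch_size Optional number of subjects per mini-batch.  When
#'   set, each EM iteration accumulates expectations over a random subject
#'   subset (scaled up to the full cohort), trading the monotone
#'   convergence guarantee for speed -- this is the stochastic-update
#'   variability source deliberately retained in the model.
#' @return A list of class `hmm_control`.
#' @export
hmm_control <- function(K = 6, delta = 10, model_mean = TRUE,
                        max_iter = 100, tol = 1e-5, batch_size = NULL) {
  stopifnot(K >= 1, delta >= 0, max_iter >= 1, tol > 0)
  if (!is.null(batch_size)) stopifnot(batch_size >= 1)
  structure(list(K = as.integer(K), delta = delta,
                 model_mean = isTRUE(model_mean),
                 max_iter = as.integer(max_iter), tol = tol,
                 batch_size = batch_size),
            class = "hmm_control")
}

#' Sample a timeseries from an HMM
#'
#' Draws a hidden state path from the Markov chain (`states[1] ~ pi`,
#' `states[t] ~ A[states[t-1], ]`) and then one Gaussian observation per
#' time point from the active state's observation model.
#'
#' @param params An [hmm_params] object.
#' @param T_len Number of time points.
#' @param seed Optional integer seed; the same seed reproduces the draw
#'   exactly without disturbing the caller's RNG state.
#' @return List with `timeseries` (`T x M` matrix) and `states`
#'   (length-`T` integer path).
#' @export
sample_timeseries <- function(params, T_len, seed = NULL) {
  stopifnot(inherits(params, "hmm_params"), T_len >= 1)
  K <- length(params$pi)
  M <- ncol(params$mu)
  with_local_seed(seed, {
    states <- integer(T_len)
    states[1] <- sample.int(K, 1L, prob = params$pi)
    if (T_len > 1) {
      for (t in 2:T_len) {
        states[t] <- sample.int(K, 1L, prob = params$A[states[t - 1], ])
      }
    }
    X <- matrix(0, T_len, M)
    for (k in seq_len(K)) {
      idx <- which(states == k)
      if (length(idx))
        X[idx, ] <- tryCatch(
          mvn_sample(length(idx), params$mu[k, ], params$Sigma[, , k]),
          error = function(e)
            stop(sprintf("covariance of state %d could not be factorised", k),
                 call. = FALSE))
    }
    list(timeseries = X, states = states)
  })
}

# Per-timepoint log emission densities under each state (T x K).
emission_logdensity <- function(params, X) {
  K <- length(params$pi)
  logB <- matrix(0, nrow(X), K)
  for (k in seq_len(K)) {
    logB[, k] <- mvn_logdensity(X, params$mu[k, ], params$Sigma[, , k])
  }
  logB
}

#' Forward-backward state inference
#'
#' Computes the per-timepoint state posteriors (the soft quantities used
#' by the Baum-Welch algorithm) for a fixed parameter set, using scaled
#' forward-backward recursions.
#'
#' @param params An [hmm_params] object.
#' @param X `T x M` timeseries matrix (`M` must match `params`).
#' @param with_xi Return the full `(T-1) x K x K` pairwise transition
#'   posteriors (`xi`) in addition to their sum over time.
#' @return Object of class `state_posteriors`: `gamma` (`T x K` state
#'   probabilities), `xi` (or `NULL`), `xi_sum` (`K x K`), and `loglik`.
#' @export
forward_backward <- function(params, X, with_xi = TRUE) {
  stopifnot(inherits(params, "hmm_params"))
  X <- as.matrix(X)
  if (nrow(X) < 1) stop("timeseries must contain at least one time point")
  if (ncol(X) != ncol(params$mu))
    stop("timeseries has ", ncol(X), " columns but the model expects ",
         ncol(params$mu))
  K <- length(params$pi)
  logB <- emission_logdensity(params, X)
  out <- .fb_core(logB, params$pi, params$A, with_xi && nrow(X) > 1)
  xi <- NULL
  if (with_xi) {
    if (nrow(X) > 1) {
      xi <- array(out$xi, c(nrow(X) - 1L, K, K))
    } else {
      xi <- array(0, c(0L, K, K))
    }
  }
  structure(list(gamma = out$gamma, xi = xi, xi_sum = out$xi_sum,
                 loglik = out$loglik),
            class = "state_posteriors")
}

# E-step accumulation across a list of subjects; returns sufficient
# statistics and the summed data log-likelihood.
accumulate_estep <- function(params, dataset) {
  K <- length(params$pi)
  M <- ncol(params$mu)
  Nk <- numeric(K)
  first <- numeric(K)
  xi_sum <- matrix(0, K, K)
  Sx <- matrix(0, M, K)
  Sxx <- array(0, c(M, M, K))
  loglik <- 0
  for (X in dataset) {
    logB <- emission_logdensity(params, X)
    fb <- .fb_core(logB, params$pi, params$A, FALSE)
    g <- fb$gamma
    Nk <- Nk + colSums(g)
    first <- first + g[1, ]
    xi_sum <- xi_sum + fb$xi_sum
    Sx <- Sx + crossprod(X, g)
    for (k in seq_len(K)) Sxx[, , k] <- Sxx[, , k] + crossprod(X * g[, k], X)
    loglik <- loglik + fb$loglik
  }
  list(Nk = Nk, first = first, xi_sum = xi_sum, Sx = Sx, Sxx = Sxx,
       loglik = loglik)
}

# M-step given accumulated statistics; MAP update for A adds `delta`
# pseudo-counts to the self-transition cell of each row.  States whose
# occupancy falls below M + 1 time points get their covariance reset to
# the pooled covariance (state collapse guard).
mstep_update <- function(stats, delta, model_mean, pooled_cov, n_chains) {
  K <- length(stats$Nk)
  M <- nrow(stats$Sx)
  pi <- stats$first / sum(stats$first)
  A <- stats$xi_sum + diag(delta, K)
  A <- A / rowSums(A)
  mu <- matrix(0, K, M)
  Sigma <- array(0, c(M, M, K))
  collapsed <- logical(K)
  for (k in seq_len(K)) {
    Nk <- stats$Nk[k]
    if (Nk < M + 1) {
      collapsed[k] <- TRUE
      Sigma[, , k] <- pooled_cov
      next
    }
    if (model_mean) mu[k, ] <- stats$Sx[, k] / Nk
    S <- stats$Sxx[, , k] / Nk - tcrossprod(mu[k, ])
    S <- (S + t(S)) / 2
    ok <- tryCatch({ chol(S); TRUE }, error = function(e) FALSE)
    if (!ok) S <- S + diag(1e-8 * max(mean(diag(S)), 1), M)
    Sigma[, , k] <- S
  }
  list(params = hmm_params(pi, A, mu, Sigma), collapsed = collapsed)
}

# Seeded initial parameters: k-means centres on a data subsample when
# means are modelled, otherwise random contiguous-block state assignment
# (covariance-only states carry no mean signal for k-means to find).
init_group_hmm <- function(dataset, control) {
  Xall <- do.call(rbind, dataset)
  M <- ncol(Xall)
  K <- control$K
  n_sub <- min(nrow(Xall), 10000L)
  idx <- sort(sample.int(nrow(Xall), n_sub))
  Xs <- Xall[idx, , drop = FALSE]
  assign <- if (control$model_mean && K > 1) {
    kmeans(Xs, centers = K, nstart = 1, iter.max = 10)$cluster
  } else {
    block <- ceiling(seq_len(n_sub) / 50)
    sample.int(K, max(block), replace = TRUE)[block]
  }
  pooled <- cov(Xall)
  mu <- matrix(0, K, M)
  Sigma <- array(0, c(M, M, K))
  for (k in seq_len(K)) {
    rows <- which(assign == k)
    if (length(rows) > M + 1) {
      if (control$model_mean) mu[k, ] <- colMeans(Xs[rows, , drop = FALSE])
      S <- cov(Xs[rows, , drop = FALSE]) * (1 + 0.05 * runif(1))
      ok <- tryCatch({ chol(S); TRUE }, error = function(e) FALSE)
      Sigma[, , k] <- if (ok) S else pooled
    } else {
      Sigma[, , k] <- pooled * (1 + 0.05 * runif(1))
    }
  }
  A <- matrix(0.1 / max(K - 1, 1), K, K)
  diag(A) <- if (K > 1) 0.9 else 1
  hmm_params(rep(1 / K, K), A, mu, Sigma)
}

#' Fit a group-level Gaussian HMM
#'
#' Runs MAP-EM (Baum-Welch) on the pooled timeseries of a cohort: every
#' subject shares one set of state distributions, estimated at the group
#' level.  The M-step for the transition matrix adds `delta` pseudo-counts
#' to each diagonal cell, the maximum-a-posteriori update under a
#' Dirichlet prior concentrated on self-transitions.  With
#' `batch_size` set, each iteration uses a random subject subset (scaled
#' to the cohort), reproducing the run-to-run variability of stochastic
#' inference; in full-batch mode the penalised log-likelihood trace is
#' non-decreasing.
#'
#' @param dataset List of per-subject `T_n x M` matrices (shared `M`).
#' @param control An [hmm_control] object.
#' @param seed Integer seed governing initialisation (and batching).
#' @return Object of class `group_hmm`: `params` ([hmm_params]),
#'   `loglik_trace` (penalised log-likelihood per iteration, evaluated at
#'   the parameters entering that iteration's E-step), `converged`,
#'   `collapsed` (states ever reset by the occupancy floor), `control`,
#'   `seed`.
#' @export
fit_group_hmm <- function(dataset, control = hmm_control(), seed = 1) {
  stopifnot(is.list(dataset), length(dataset) >= 1)
  dataset <- lapply(dataset, as.matrix)
  M <- ncol(dataset[[1]])
  if (!all(vapply(dataset, ncol, 0L) == M))
    stop("all subjects must share the same number of channels")
  total_T <- sum(vapply(dataset, nrow, 0L))
  if (total_T <= control$K * M)
    stop("too few time points (", total_T, ") for K*M = ", control$K * M,
         " covariance parameters")
  pooled <- cov(do.call(rbind, dataset))
  N <- length(dataset)
  batch <- control$batch_size
  if (!is.null(batch)) batch <- min(batch, N)

  with_local_seed(seed, {
    params <- init_group_hmm(dataset, control)
    # refine the raw initialisation with one full M-step
    st <- accumulate_estep(params, dataset)
    params <- mstep_update(st, control$delta, control$model_mean, pooled, N)$params

    trace <- numeric(0)
    converged <- FALSE
    any_collapsed <- logical(control$K)
    for (it in seq_len(control$max_iter)) {
      subset <- if (is.null(batch)) dataset else
        dataset[sample.int(N, batch)]
      st <- accumulate_estep(params, subset)
      scale <- N / length(subset)
      if (scale != 1) {
        st$Nk <- st$Nk * scale; st$first <- st$first * scale
        st$xi_sum <- st$xi_sum * scale; st$Sx <- st$Sx * scale
        st$Sxx <- st$Sxx * scale; st$loglik <- st$loglik * scale
      }
      pen <- st$loglik +
        if (control$delta > 0) control$delta * sum(log(diag(params$A))) else 0
      trace <- c(trace, pen)
      up <- mstep_update(st, control$delta, control$model_mean, pooled, N)
      if (any(up$collapsed)) {
        warning("state collapse: covariance of state(s) ",
                paste(which(up$collapsed), collapse = ", "),
                " reset to the pooled covariance")
        any_collapsed <- any_collapsed | up$collapsed
      }
      params <- up$params
      if (it > 1 && is.null(batch)) {
        if (abs(trace[it] - trace[it - 1]) <
            control$tol * (1 + abs(trace[it]))) {
          converged <- TRUE
          break
        }
      }
    }
    if (!converged && is.null(batch))
      warning("EM did not converge within ", control$max_iter, " iterations")
    structure(list(params = params, loglik_trace = trace,
                   converged = converged, collapsed = any_collapsed,
                   control = control, seed = seed),
              class = "group_hmm")
  })
}

#' @export
print.group_hmm <- function(x, ...) {
  cat(sprintf(
    "group_hmm: K = %d, delta = %g, %d EM iterations (%sconverged)\n",
    x$control$K, x$control$delta, length(x$loglik_trace),
    if (x$converged) "" else "not "))
  invisible(x)
}

#' Subject-level dual estimation
#'
#' Derives subject-specific HMM parameters from a fixed group-level
#' model: state posteriors are computed under the group parameters, then
#' the state means, covariances, transition rows and initial
#' probabilities are re-estimated from the subject's posterior-weighted
#' statistics blended with the group values using `prior_strength`
#' pseudo-observations.  States the subject never visits therefore
#' inherit the group parameters, and `prior_strength = Inf` returns the
#' group parameters exactly.
#'
#' @param group An [hmm_params] object (or a `group_hmm` fit).
#' @param X The subject's `T x M` timeseries.
#' @param prior_strength Non-negative pseudo-observation count for the
#'   blend; defaults to `M` (one pseudo-observation per channel).
#' @return Object of class `subject_params` (an [hmm_params] with an
#'   added `occupancy` vector: total posterior mass per state, summing to
#'   `T`).
#' @export
dual_estimate <- function(group, X, prior_strength = NULL) {
  if (inherits(group, "group_hmm")) group <- group$params
  stopifnot(inherits(group, "hmm_params"))
  X <- as.matrix(X)
  if (nrow(X) == 0) stop("subject timeseries has zero length")
  K <- length(group$pi)
  M <- ncol(group$mu)
  if (is.null(prior_strength)) prior_strength <- M
  stopifnot(prior_strength >= 0)

  fb <- forward_backward(group, X, with_xi = FALSE)
  occupancy <- colSums(fb$gamma)

  if (is.infinite(prior_strength)) {
    out <- group
    out$occupancy <- occupancy
    class(out) <- c("subject_params", "hmm_params")
    return(out)
  }

  ps <- prior_strength
  g <- fb$gamma
  pi <- (g[1, ] + ps * group$pi) / (1 + ps)
  A <- fb$xi_sum + ps * group$A
  A <- A / rowSums(A)
  mu <- matrix(0, K, M)
  Sigma <- array(0, c(M, M, K))
  group_mean_modelled <- any(group$mu != 0)
  for (k in seq_len(K)) {
    Nk <- occupancy[k]
    denom <- Nk + ps
    if (denom == 0) {
      mu[k, ] <- group$mu[k, ]
      Sigma[, , k] <- group$Sigma[, , k]
      warning("state ", k, " unvisited with prior_strength = 0; ",
              "group parameters retained")
      next
    }
    Sx <- crossprod(X, g[, k])[, 1]
    if (group_mean_modelled) {
      mu[k, ] <- (Sx + ps * group$mu[k, ]) / denom
    }  # covariance-only models keep means pinned at zero
    Xc <- sweep(X, 2L, mu[k, ], "-")
    Sw <- crossprod(Xc * g[, k], Xc)
    dm <- group$mu[k, ] - mu[k, ]
    S <- (Sw + ps * (group$Sigma[, , k] + tcrossprod(dm))) / denom
    S <- (S + t(S)) / 2
    ok <- tryCatch({ chol(S); TRUE }, error = function(e) FALSE)
    if (!ok) S <- S + diag(1e-8 * max(mean(diag(S)), 1), M)
    Sigma[, , k] <- S
  }
  out <- hmm_params(pi, A, mu, Sigma)
  out$occupancy <- occupancy
  class(out) <- c("subject_params", "hmm_params")
  out
}

#' Write / read HMM parameters
#'
#' Serialises an [hmm_params] object (plus optional metadata such as the
#' fitting seed and convergence flag) to a single JSON document at full
#' numeric precision, so a round trip reproduces the parameters exactly
#' to printed precision.
#'
#' @param params An [hmm_params] or `group_hmm` object.
#' @param path Output file path.
#' @return `read_hmm_params` returns an [hmm_params]; the metadata fields
#'   are attached as attribute `"meta"`.
#' @export
write_hmm_params <- function(params, path) {
  meta <- list()
  if (inherits(params, "group_hmm")) {
    meta <- list(delta = params$control$delta, seed = params$seed,
                 converged = params$converged)
    params <- params$params
  }
  K <- length(params$pi)
  doc <- c(list(K = K, M = ncol(params$mu)), meta,
           list(pi = params$pi, A = params$A, mu = params$mu,
                Sigma = lapply(seq_len(K), function(k) params$Sigma[, , k])))
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_hmm_params
#' @export
read_hmm_params <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  K <- doc$K
  M <- doc$M
  Sigma <- array(0, c(M, M, K))
  for (k in seq_len(K)) {
    # jsonlite may simplify the list of state covariances into a
    # K x M x M array; support both representations
    Sk <- if (is.list(doc$Sigma)) doc$Sigma[[k]] else doc$Sigma[k, , ]
    Sigma[, , k] <- (Sk + t(Sk)) / 2
  }
  out <- hmm_params(doc$pi, matrix(doc$A, K, K), matrix(doc$mu, K, M),
                    Sigma)
  attr(out, "meta") <- doc[setdiff(names(doc),
                                   c("K", "M", "pi", "A", "mu", "Sigma"))]
  out
}
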