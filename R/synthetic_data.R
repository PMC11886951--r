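# Synthetic cohort generator: state-switching Gaussian timeseries with
# subject-specific parameter deviations, family structure, confound
# effects, and traits coupled to subject-level dynamics.  This is the
# test bed for the whole pipeline: every downstream claim is exercised on
# cohorts whose generating parameters are known exactly.

#' Cohort specification
#'
#' @param N Number of subjects.
#' @param M Number of channels (regions).
#' @param T_len Time points per subject.
#' @param K_true Number of generating states.
#' @param separation Scale of the mean/covariance differences between
#'   states (0 makes all states identical).
#' @param stickiness Diagonal dominance of the generating transition
#'   matrix (`A = stickiness * I + (1 - stickiness) * random stochastic`);
#'   1 gives an absorbing identity matrix.
#' @param subject_sd Scale of per-subject deviations from the group
#'   parameters (0 makes all subjects exact copies).
#' @param family_sizes Probability weights over family sizes `1, 2, ...`;
#'   e.g. `c(0.7, 0.2, 0.1)` for singletons/pairs/triples.
#' @param family_share Weight of the family-shared component of the
#'   subject deviations (1 makes deviations identical within family).
#' @param n_confounds Number of standard-normal confound variables.
#' @param confound_strength Scale with which confounds shift the subject
#'   state means (0 decouples confounds from the brain data).
#' @param seed Integer seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(N = 100, M = 5, T_len = 500, K_true = 3,
                        separation = 1, stickiness = 0.9,
                        subject_sd = 0.15, family_sizes = 1,
                        family_share = 0.5, n_confounds = 2,
                        confound_strength = 0, seed = 1) {
  stopifnot(N >= 1, M >= 1, T_len >= 1, K_true >= 1,
            separation >= 0, stickiness >= 0, stickiness <= 1,
            subject_sd >= 0, family_share >= 0, family_share <= 1,
            n_confounds >= 0, confound_strength >= 0)
  structure(list(N = as.integer(N), M = as.integer(M),
                 T_len = as.integer(T_len), K_true = as.integer(K_true),
                 separation = separation, stickiness = stickiness,
                 subject_sd = subject_sd, family_sizes = family_sizes,
                 family_share = family_share,
                 n_confounds = as.integer(n_confounds),
                 confound_strength = confound_strength,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Cohort presets emulating the two canonical acquisition regimes
#'
#' `"hcp_like"`: few subjects with long scans and family structure (the
#' regime where dynamic features are well estimated per subject).
#' `"ukb_like"`: many unrelated subjects with short scans (the regime
#' where static connectivity is the more reliable per-subject estimate).
#' Sizes are scaled to desk-top problem sizes while preserving the
#' many-short versus few-long contrast.
#'
#' @param name `"hcp_like"` or `"ukb_like"`.
#' @param ... Overrides passed to [cohort_spec].
#' @export
cohort_preset <- function(name = c("hcp_like", "ukb_like"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    hcp_like = list(N = 120, M = 6, T_len = 600, K_true = 3,
                    separation = 1, stickiness = 0.92, subject_sd = 0.2,
                    family_sizes = c(0.5, 0.3, 0.2), family_share = 0.5,
                    n_confounds = 2, confound_strength = 0.2),
    ukb_like = list(N = 1000, M = 6, T_len = 100, K_true = 3,
                    separation = 1, stickiness = 0.9, subject_sd = 0.2,
                    family_sizes = 1, family_share = 0,
                    n_confounds = 2, confound_strength = 0.2))
  do.call(cohort_spec, utils::modifyList(base, list(...)))
}

# Random orthogonal matrix (QR of a Gaussian matrix, sign-fixed).
random_rotation <- function(M) {
  qrd <- qr(matrix(rnorm(M * M), M, M))
  Q <- qr.Q(qrd)
  Q %*% diag(sign(diag(qr.R(qrd))), M)
}

# One Dirichlet draw with parameter vector `alpha` (gamma representation).
rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = pmax(alpha, 1e-8), rate = 1)
  if (sum(g) == 0) g <- rep(1, length(alpha))
  g / sum(g)
}

#' Generate group-level HMM parameters
#'
#' State means are drawn at pairwise distances proportional to
#' `separation`; state covariances are randomly rotated SPD matrices
#' whose eigenvalue spread also grows with `separation` (at
#' `separation = 0` every state is standard normal); the transition
#' matrix mixes the identity with a random row-stochastic matrix with
#' weight `stickiness`.
#'
#' @param spec A [cohort_spec].
#' @return An [hmm_params] object.
#' @export
generate_group_params <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_local_seed(spec$seed, {
    K <- spec$K_true
    M <- spec$M
    mu <- spec$separation * matrix(rnorm(K * M), K, M)
    Sigma <- array(0, c(M, M, K))
    spread <- 0.35 * min(spec$separation, 2)
    for (k in seq_len(K)) {
      Q <- random_rotation(M)
      ev <- exp(rnorm(M, 0, spread))
      Sigma[, , k] <- Q %*% (ev * t(Q))
      Sigma[, , k] <- (Sigma[, , k] + t(Sigma[, , k])) / 2
    }
    S <- t(vapply(seq_len(K), function(k) rdirichlet1(rep(1, K)),
                  numeric(K)))
    A <- spec$stickiness * diag(K) + (1 - spec$stickiness) * S
    A <- A / rowSums(A)
    hmm_params(rep(1 / K, K), A, mu, Sigma)
  })
}

# Draw a family-size partition of N subjects from the size distribution.
draw_families <- function(N, family_sizes) {
  sizes <- integer(0)
  total <- 0L
  smax <- length(family_sizes)
  while (total < N) {
    s <- if (smax == 1) 1L else
      sample.int(smax, 1L, prob = family_sizes)
    s <- min(s, N - total)
    sizes <- c(sizes, s)
    total <- total + s
  }
  rep(seq_along(sizes), sizes)
}

# Perturb one subject's parameters around the group values.  The mean
# gets an additive Gaussian deviation (plus the confound shift), the
# covariance a congruence transform by I + E with small symmetric E
# (which keeps it SPD for small E; retried if not), and each transition
# row a Dirichlet resample centred on the group row.
perturb_subject <- function(group, sd_scale, fam, conf_shift,
                            family_share) {
  K <- length(group$pi)
  M <- ncol(group$mu)
  w <- family_share
  mu <- group$mu
  Sigma <- group$Sigma
  A <- group$A
  if (sd_scale > 0) {
    for (k in seq_len(K)) {
      eps <- w * fam$mu_eps[, k] + (1 - w) * rnorm(M)
      mu[k, ] <- mu[k, ] + sd_scale * eps
      for (try in 1:20) {
        Esub <- matrix(rnorm(M * M), M, M)
        Esub <- (Esub + t(Esub)) / 2
        E <- 0.5 * sd_scale * (w * fam$sig_eps[, , k] + (1 - w) * Esub)
        B <- diag(M) + E
        S <- B %*% group$Sigma[, , k] %*% t(B)
        S <- (S + t(S)) / 2
        ok <- tryCatch({ chol(S); TRUE }, error = function(e) FALSE)
        if (ok) { Sigma[, , k] <- S; break }
        if (try == 20) stop("covariance perturbation failed to stay PD")
      }
      conc <- 50 / sd_scale
      row_sub <- rdirichlet1(conc * group$A[k, ])
      row <- w * fam$A_rows[k, ] + (1 - w) * row_sub
      A[k, ] <- row / sum(row)
    }
  }
  if (!is.null(conf_shift)) mu <- sweep(mu, 2L, conf_shift, "+")
  hmm_params(group$pi, A, mu, Sigma)
}

#' Generate a synthetic cohort
#'
#' Each subject receives its own perturbed copy of the group parameters
#' (deviations partially shared within families), an optional
#' confound-driven shift of the state means, and a sampled timeseries of
#' `T_len` points.
#'
#' @param group Group-level [hmm_params] (typically from
#'   [generate_group_params]).
#' @param spec The [cohort_spec].
#' @return List: `timeseries` (list of `T x M` matrices), `subject_params`
#'   (list of the true per-subject [hmm_params]), `families` (integer
#'   labels), `confounds` (`N x n_confounds` matrix), `confound_loadings`
#'   (the fixed `M x n_confounds` map from confounds to mean shifts),
#'   `ids`.
#' @export
generate_cohort <- function(group, spec) {
  stopifnot(inherits(group, "hmm_params"), inherits(spec, "cohort_spec"))
  K <- length(group$pi)
  M <- ncol(group$mu)
  with_local_seed(child_seed(spec$seed, 1L), {
    families <- draw_families(spec$N, spec$family_sizes)
    confounds <- matrix(rnorm(spec$N * spec$n_confounds), spec$N)
    loadings <- if (spec$n_confounds > 0)
      matrix(rnorm(M * spec$n_confounds), M) / sqrt(M) else NULL

    fam_comp <- lapply(seq_len(max(families)), function(f) list(
      mu_eps = matrix(rnorm(M * K), M, K),
      sig_eps = {
        a <- array(rnorm(M * M * K), c(M, M, K))
        for (k in seq_len(K)) a[, , k] <- (a[, , k] + t(a[, , k])) / 2
        a
      },
      A_rows = t(vapply(seq_len(K), function(k)
        rdirichlet1((50 / max(spec$subject_sd, 1e-6)) * group$A[k, ]),
        numeric(K)))))

    subject_params <- vector("list", spec$N)
    timeseries <- vector("list", spec$N)
    for (n in seq_len(spec$N)) {
      shift <- if (spec$confound_strength > 0 && spec$n_confounds > 0)
        spec$confound_strength * as.numeric(loadings %*% confounds[n, ])
      else NULL
      subject_params[[n]] <- perturb_subject(
        group, spec$subject_sd, fam_comp[[families[n]]], shift,
        spec$family_share)
      timeseries[[n]] <- sample_timeseries(subject_params[[n]],
                                           spec$T_len)$timeseries
    }
    list(timeseries = timeseries, subject_params = subject_params,
         families = families, confounds = confounds,
         confound_loadings = loadings,
         ids = sprintf("s%05d", seq_len(spec$N)))
  })
}

#' Trait specification
#'
#' @param coupling Named numeric vector/list of block weights:
#'   `tangent` (state-covariance tangent directions), `means` (state
#'   means), `transitions` (transition entries), `static` (static
#'   covariance tangent directions).  All zero gives a pure-noise trait.
#' @param noise_sd Residual noise scale.
#' @param confound_effect Scale of the direct confound contribution to
#'   the trait.
#' @param n_traits Number of traits to draw (each with fresh random
#'   coupling directions).
#' @return A list of class `trait_spec`.
#' @export
trait_spec <- function(coupling = c(tangent = 1, means = 0.5,
                                    transitions = 0.5, static = 0),
                       noise_sd = 1, confound_effect = 0, n_traits = 1) {
  coupling <- unlist(coupling)
  known <- c("tangent", "means", "transitions", "static")
  if (length(coupling) && !all(names(coupling) %in% known))
    stop("unknown coupling block(s): ",
         paste(setdiff(names(coupling), known), collapse = ", "))
  full <- stats::setNames(numeric(4), known)
  full[names(coupling)] <- coupling
  stopifnot(noise_sd >= 0, n_traits >= 1)
  structure(list(coupling = full, noise_sd = noise_sd,
                 confound_effect = confound_effect,
                 n_traits = as.integer(n_traits)),
            class = "trait_spec")
}

# True static covariance of a subject's HMM under the stationary state
# distribution: law of total covariance over states.
true_static_cov <- function(p) {
  K <- length(p$pi)
  ev <- eigen(t(p$A))
  i <- which.min(abs(ev$values - 1))
  st <- abs(Re(ev$vectors[, i]))
  st <- st / sum(st)
  m <- colSums(st * p$mu)
  S <- matrix(0, ncol(p$mu), ncol(p$mu))
  for (k in seq_len(K))
    S <- S + st[k] * (p$Sigma[, , k] + tcrossprod(p$mu[k, ]))
  S <- S - tcrossprod(m)
  (S + t(S)) / 2
}

#' Generate traits coupled to the true subject dynamics
#'
#' Each trait is a linear functional of the subjects' TRUE features --
#' computed through the same SPD tangent pathway the pipeline uses, but
#' on the generating (noise-free) subject parameters -- plus an optional
#' direct confound contribution and Gaussian noise.  The attainable
#' (oracle) R-squared, the fraction of trait variance carried by the
#' feature signal, is recorded per trait so pipeline accuracies can be
#' judged against what the signal supports.
#'
#' @param cohort Output of [generate_cohort] (uses `subject_params` and
#'   `confounds`).
#' @param tspec A [trait_spec].
#' @param seed Integer seed for the coupling directions and noise.
#' @return List: `traits` (`N x n_traits` matrix), `oracle_r2`,
#'   `confound_r2` (per-trait variance fractions).
#' @export
generate_traits <- function(cohort, tspec, seed = 1) {
  stopifnot(inherits(tspec, "trait_spec"))
  params <- cohort$subject_params
  N <- length(params)
  cpl <- tspec$coupling
  blocks <- list()
  if (cpl[["tangent"]] != 0 || cpl[["means"]] != 0 ||
      cpl[["transitions"]] != 0) {
    fm <- assemble_features(params, include_means = TRUE,
                            include_transitions = TRUE)
    bl <- fm$block_index$block
    blocks$tangent <- fm$values[, grepl("tangent", bl), drop = FALSE]
    blocks$means <- fm$values[, bl == "state_means", drop = FALSE]
    blocks$transitions <- fm$values[, bl == "transitions", drop = FALSE]
  }
  if (cpl[["static"]] != 0) {
    mats <- lapply(params, function(p)
      regularized_precision(true_static_cov(p), 0.1))
    blocks$static <- project_block(mats)
  }
  with_local_seed(seed, {
    traits <- matrix(0, N, tspec$n_traits)
    oracle_r2 <- confound_r2 <- numeric(tspec$n_traits)
    for (j in seq_len(tspec$n_traits)) {
      signal <- numeric(N)
      for (b in names(blocks)) {
        if (cpl[[b]] == 0) next
        Z <- scale(blocks[[b]])
        Z[, attr(Z, "scaled:scale") < 1e-10] <- 0
        wdir <- rnorm(ncol(Z)) / sqrt(ncol(Z))
        signal <- signal + cpl[[b]] * as.numeric(Z %*% wdir)
      }
      conf_part <- if (tspec$confound_effect != 0 &&
                       !is.null(cohort$confounds) &&
                       ncol(cohort$confounds) > 0) {
        tspec$confound_effect *
          as.numeric(cohort$confounds %*% rnorm(ncol(cohort$confounds)))
      } else numeric(N)
      noise <- rnorm(N, 0, tspec$noise_sd)
      tr <- signal + conf_part + noise
      traits[, j] <- tr
      vt <- var(tr)
      oracle_r2[j] <- if (vt > 0) var(signal) / vt else 0
      confound_r2[j] <- if (vt > 0) var(conf_part) / vt else 0
    }
    colnames(traits) <- sprintf("trait%02d", seq_len(tspec$n_traits))
    list(traits = traits, oracle_r2 = oracle_r2, confound_r2 = confound_r2)
  })
}
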