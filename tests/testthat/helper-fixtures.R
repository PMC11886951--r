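# Small fixtures built in code at test time.

# Well-separated K-state Gaussian HMM for recovery tests.
make_test_hmm <- function(K = 2, M = 2, sep = 4, stay = 0.9) {
  mu <- matrix(0, K, M)
  if (K > 1) for (k in seq_len(K)) mu[k, ] <- sep * (k - (K + 1) / 2)
  A <- matrix((1 - stay) / max(K - 1, 1), K, K)
  diag(A) <- if (K > 1) stay else 1
  Sigma <- array(0, c(M, M, K))
  for (k in seq_len(K)) Sigma[, , k] <- diag(M)
  hmm_params(rep(1 / K, K), A, mu, Sigma)
}

# Tiny cohort + trait for pipeline tests; returns everything the
# stacking layer needs.
make_test_cohort <- function(N = 80, M = 4, T_len = 120, K_true = 2,
                             seed = 1, confound_strength = 0,
                             family_sizes = 1,
                             coupling = c(tangent = 1, means = 0.5,
                                          transitions = 0.3, static = 0.5),
                             noise_sd = 1, confound_effect = 0) {
  spec <- cohort_spec(N = N, M = M, T_len = T_len, K_true = K_true,
                      separation = 1, stickiness = 0.9, subject_sd = 0.2,
                      family_sizes = family_sizes, n_confounds = 2,
                      confound_strength = confound_strength, seed = seed)
  group <- generate_group_params(spec)
  cohort <- generate_cohort(group, spec)
  gen <- generate_traits(cohort,
                         trait_spec(coupling = coupling,
                                    noise_sd = noise_sd,
                                    confound_effect = confound_effect),
                         seed = seed + 1)
  c(cohort, list(group = group, spec = spec, trait = gen$traits[, 1],
                 oracle_r2 = gen$oracle_r2))
}
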