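# Gaussian HMM core: sampling, forward-backward, group fitting, dual
# estimation.

test_that("sampling follows the generative process", {
  # absorbing identity transition matrix: the chain never leaves state 1
  p <- hmm_params(c(1, 0), diag(2), matrix(0, 2, 2),
                  array(rep(diag(2), 2), c(2, 2, 2)))
  s <- sample_timeseries(p, 100, seed = 1)
  expect_true(all(s$states == 1))

  # single-state model: standard-normal draws with a stable mean
  p1 <- hmm_params(1, matrix(1, 1, 1), matrix(0, 1, 3),
                   array(diag(3), c(3, 3, 1)))
  s1 <- sample_timeseries(p1, 5, seed = 2)
  expect_equal(dim(s1$timeseries), c(5L, 3L))
  big <- sample_timeseries(p1, 20000, seed = 3)
  expect_lt(max(abs(colMeans(big$timeseries))), 0.03)

  # long-run empirical transition frequencies match A entrywise
  K <- 3
  A <- matrix(0.1, K, K); diag(A) <- 0.8
  p3 <- hmm_params(rep(1 / 3, 3), A, matrix(c(-4, 0, 4), 3, 2),
                   array(rep(diag(2), 3), c(2, 2, 3)))
  s3 <- sample_timeseries(p3, 50000, seed = 4)
  trans <- table(factor(s3$states[-50000], 1:3),
                 factor(s3$states[-1], 1:3))
  Ahat <- trans / rowSums(trans)
  expect_lt(max(abs(Ahat - A)), 0.01)

  # identical seed, identical draw; seed is local to the call
  expect_identical(sample_timeseries(p3, 50, seed = 9),
                   sample_timeseries(p3, 50, seed = 9))
})

test_that("sampling rejects a non-PD state covariance with its index", {
  Sigma <- array(diag(2), c(2, 2, 2))
  Sigma[, , 2] <- matrix(c(1, 2, 2, 1), 2, 2)  # indefinite
  expect_error(
    hmm_params(c(.5, .5), matrix(.5, 2, 2), matrix(0, 2, 2), Sigma),
    "state 2")
})

test_that("forward-backward matches certainty and dominance limits", {
  # K = 1: all mass on the single state, loglik = sum of log densities
  p1 <- hmm_params(1, matrix(1, 1, 1), matrix(0, 1, 2),
                   array(diag(2), c(2, 2, 1)))
  X <- matrix(rnorm(20), 10, 2)
  fb <- forward_backward(p1, X)
  expect_equal(fb$gamma, matrix(1, 10, 1))
  ll_manual <- sum(mvtnorm_logd <- -0.5 * (2 * log(2 * pi) + rowSums(X^2)))
  expect_equal(fb$loglik, ll_manual, tolerance = 1e-10)

  # far-separated states: data from state 1 only -> near-certain gamma
  p <- make_test_hmm(K = 2, M = 2, sep = 10)
  X1 <- sample_timeseries(
    hmm_params(c(1, 0), diag(2), p$mu, p$Sigma), 200, seed = 5)$timeseries
  fb2 <- forward_backward(p, X1)
  expect_true(all(fb2$gamma[, 1] >= 0.99))
})

test_that("forward-backward equals exhaustive path enumeration", {
  set.seed(7)
  for (K in 2:3) {
    A <- t(vapply(seq_len(K), function(k) {
      a <- runif(K) + 0.1; a / sum(a)
    }, numeric(K)))
    pi <- runif(K) + 0.1; pi <- pi / sum(pi)
    mu <- matrix(rnorm(K * 2), K, 2)
    Sigma <- array(0, c(2, 2, K))
    for (k in seq_len(K)) Sigma[, , k] <- rand_spd(2)
    p <- hmm_params(pi, A, mu, Sigma)
    X <- matrix(rnorm(12), 6, 2)
    fb <- forward_backward(p, X)
    oracle <- fb_bruteforce(p, X)
    expect_lt(max(abs(fb$gamma - oracle$gamma)), 1e-10)
    expect_lt(max(abs(fb$xi - oracle$xi)), 1e-10)
    expect_equal(fb$loglik, oracle$loglik, tolerance = 1e-10)
  }
})

test_that("xi marginalises back to gamma and rows are normalised", {
  p <- make_test_hmm(K = 3, M = 2, sep = 2)
  X <- sample_timeseries(p, 300, seed = 11)$timeseries
  fb <- forward_backward(p, X)
  expect_lt(max(abs(rowSums(fb$gamma) - 1)), 1e-8)
  slice_sums <- apply(fb$xi, 1, sum)
  expect_lt(max(abs(slice_sums - 1)), 1e-8)
  marg <- apply(fb$xi, c(1, 2), sum)
  expect_lt(max(abs(marg - fb$gamma[-nrow(X), ])), 1e-8)
})

test_that("K = 1 EM reduces to pooled mean and ML covariance", {
  set.seed(21)
  ds <- list(matrix(rnorm(600, 1), 200, 3), matrix(rnorm(300, 1), 100, 3))
  fit <- fit_group_hmm(ds, hmm_control(K = 1, max_iter = 5), seed = 1)
  Xall <- do.call(rbind, ds)
  expect_equal(fit$params$mu[1, ], colMeans(Xall), tolerance = 1e-8)
  mle_cov <- crossprod(sweep(Xall, 2, colMeans(Xall))) / nrow(Xall)
  expect_equal(fit$params$Sigma[, , 1], mle_cov, tolerance = 1e-8)
})

test_that("full-batch EM has a non-decreasing penalised log-likelihood", {
  for (seed in 1:5) {
    co <- make_test_cohort(N = 4, M = 3, T_len = 150, K_true = 2,
                           seed = seed)
    fit <- suppressWarnings(fit_group_hmm(
      co$timeseries, hmm_control(K = 2, delta = 10, max_iter = 25),
      seed = seed))
    expect_true(all(diff(fit$loglik_trace) >= -1e-6))
  }
})

test_that("a strongly separated 3-state model is recovered", {
  truth <- make_test_hmm(K = 3, M = 3, sep = 3, stay = 0.85)
  ds <- lapply(1:6, function(i)
    sample_timeseries(truth, 2500, seed = 30 + i)$timeseries)
  fit <- fit_group_hmm(ds, hmm_control(K = 3, delta = 0, max_iter = 50),
                       seed = 2)
  perm <- match_states(fit$params, truth)
  A_hat <- fit$params$A[perm, perm]
  expect_lt(max(rowSums(abs(A_hat - truth$A))), 0.05)
  expect_lt(max(abs(fit$params$mu[perm, ] - truth$mu)), 0.1)
})

test_that("larger delta yields a more persistent fitted transition matrix", {
  co <- make_test_cohort(N = 5, M = 3, T_len = 200, K_true = 2, seed = 3)
  f0 <- suppressWarnings(fit_group_hmm(
    co$timeseries, hmm_control(K = 2, delta = 0, max_iter = 20), seed = 7))
  fbig <- suppressWarnings(fit_group_hmm(
    co$timeseries, hmm_control(K = 2, delta = 1e5, max_iter = 20), seed = 7))
  expect_true(all(diag(fbig$params$A) > diag(f0$params$A)))
})

test_that("dual estimation blends towards the group as the prior grows", {
  co <- make_test_cohort(N = 3, M = 3, T_len = 200, K_true = 2, seed = 4)
  fit <- suppressWarnings(fit_group_hmm(
    co$timeseries, hmm_control(K = 2, max_iter = 15), seed = 5))
  sub_inf <- dual_estimate(fit$params, co$timeseries[[1]],
                           prior_strength = Inf)
  expect_equal(sub_inf$A, fit$params$A, tolerance = 1e-8)
  expect_equal(sub_inf$mu, fit$params$mu, tolerance = 1e-8)
  expect_equal(sub_inf$Sigma, fit$params$Sigma, tolerance = 1e-8)
  expect_equal(sum(sub_inf$occupancy), nrow(co$timeseries[[1]]),
               tolerance = 1e-6)
})

test_that("dual estimation is self-consistent on long group-model data", {
  truth <- make_test_hmm(K = 2, M = 2, sep = 4, stay = 0.9)
  X <- sample_timeseries(truth, 50000, seed = 41)$timeseries
  sub <- dual_estimate(truth, X, prior_strength = 0)
  expect_lt(max(rowSums(abs(sub$A - truth$A))), 0.05)
  expect_equal(sum(sub$occupancy), 50000, tolerance = 1e-6)
})

test_that("dual estimation tracks a targeted mean shift, leaves rest alone", {
  truth <- make_test_hmm(K = 3, M = 2, sep = 8, stay = 0.8)
  shifted <- truth
  shifted$mu[2, ] <- shifted$mu[2, ] + 1
  # subject only ever visits states 1 and 2
  shifted$A[1, ] <- c(.8, .2, 0)
  shifted$A[2, ] <- c(.2, .8, 0)
  shifted$pi <- c(.5, .5, 0)
  X <- sample_timeseries(shifted, 5000, seed = 42)$timeseries
  sub <- dual_estimate(truth, X, prior_strength = 2)
  expect_lt(max(abs(sub$mu[2, ] - shifted$mu[2, ])), 0.2)
  # state 3 is unvisited: parameters stay at the group values
  expect_equal(sub$mu[3, ], truth$mu[3, ], tolerance = 0.05)
  expect_lt(sub$occupancy[3], 1)
  expect_error(dual_estimate(truth, X[0, , drop = FALSE]), "zero length")
})

test_that("sample -> fit -> resample closes on summary statistics", {
  truth <- make_test_hmm(K = 2, M = 2, sep = 4, stay = 0.85)
  ds <- lapply(1:4, function(i)
    sample_timeseries(truth, 2000, seed = 50 + i)$timeseries)
  fit <- fit_group_hmm(ds, hmm_control(K = 2, delta = 0, max_iter = 40),
                       seed = 3)
  res <- lapply(1:4, function(i)
    sample_timeseries(fit$params, 2000, seed = 60 + i)$timeseries)
  lag1 <- function(ds) mean(vapply(ds, function(X) {
    Xc <- scale(X, scale = FALSE)
    sum(diag(crossprod(Xc[-1, ], Xc[-nrow(Xc), ]) / (nrow(Xc) - 1)))
  }, 0.0))
  v_orig <- vapply(ds, function(X) sum(diag(cov(X))), 0.0)
  v_res <- vapply(res, function(X) sum(diag(cov(X))), 0.0)
  se <- sd(v_orig) / sqrt(length(v_orig)) + sd(v_res) / sqrt(length(v_res))
  expect_lt(abs(mean(v_orig) - mean(v_res)), 3 * max(se, 0.1))
  expect_lt(abs(lag1(ds) - lag1(res)) / abs(lag1(ds)), 0.2)
})

test_that("HMM parameters survive a JSON round trip", {
  truth <- make_test_hmm(K = 3, M = 4, sep = 1.3)
  truth$A <- matrix(c(.7, .2, .1, .15, .7, .15, .05, .15, .8), 3, 3,
                    byrow = TRUE)
  path <- tempfile(fileext = ".json")
  write_hmm_params(truth, path)
  back <- read_hmm_params(path)
  expect_equal(back$pi, truth$pi)
  expect_equal(back$A, truth$A)
  expect_equal(back$mu, truth$mu)
  expect_equal(back$Sigma, truth$Sigma)
  unlink(path)
})

test_that("fit_group_hmm validates its inputs", {
  expect_error(fit_group_hmm(list(matrix(0, 5, 2), matrix(0, 5, 3)),
                             hmm_control(K = 1)),
               "same number of channels")
  expect_error(fit_group_hmm(list(matrix(rnorm(8), 4, 2)),
                             hmm_control(K = 3)),
               "too few time points")
})
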