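# SPD geometry: precisions, partial correlation, Karcher mean, tangent
# projection, vectorisation, feature assembly.

test_that("cholesky_precision inverts SPD matrices", {
  expect_equal(cholesky_precision(diag(3)), diag(3))
  expect_equal(cholesky_precision(diag(c(2, 4))), diag(c(0.5, 0.25)))
  set.seed(1)
  S <- rand_spd(4)
  Om <- cholesky_precision(S)
  expect_lt(max(abs(Om %*% S - diag(4))), 1e-8)
  # cofactor-expansion oracle for the inverse
  adj <- sapply(1:4, function(j) sapply(1:4, function(i)
    (-1)^(i + j) * det(S[-i, -j, drop = FALSE])))
  expect_equal(Om, t(adj) / det(S), tolerance = 1e-8)
  expect_error(cholesky_precision(matrix(c(1, 2, 2, 1), 2, 2)),
               "positive definite")
})

test_that("regularized_precision applies the ridge before inverting", {
  expect_equal(regularized_precision(diag(2), a = 1), 0.5 * diag(2))
  set.seed(2)
  S <- rand_spd(3)
  expect_equal(regularized_precision(S, a = 0), cholesky_precision(S))
  # singular input is fine once a > 0
  expect_equal(regularized_precision(diag(c(3, 0)), a = 1),
               diag(c(0.25, 1)))
})

test_that("partial correlation normalises the precision matrix", {
  expect_equal(partial_correlation(diag(c(2, 3, 4))), diag(3))
  rho <- partial_correlation(matrix(c(1, -0.5, -0.5, 1), 2, 2))
  expect_equal(rho[1, 2], 0.5)
  # regression-residual oracle on a known 3-variable Gaussian
  set.seed(3)
  S <- rand_spd(3)
  Om <- cholesky_precision(S)
  X <- mvn_oracle <- {
    R <- chol(S)
    matrix(rnorm(3 * 50000), 50000, 3) %*% R
  }
  res1 <- lm(X[, 1] ~ X[, 3])$residuals
  res2 <- lm(X[, 2] ~ X[, 3])$residuals
  rho_an <- partial_correlation(Om)[1, 2]
  expect_equal(rho_an, cor(res1, res2), tolerance = 0.02)
  # analytic residual oracle (no sampling): conditional covariance
  Scond <- S[1:2, 1:2] - S[1:2, 3, drop = FALSE] %*%
    solve(S[3, 3]) %*% S[3, 1:2, drop = FALSE]
  expect_equal(rho_an, Scond[1, 2] / sqrt(Scond[1, 1] * Scond[2, 2]),
               tolerance = 1e-8)
  expect_true(all(abs(partial_correlation(cholesky_precision(rand_spd(5)))) <=
                    1 + 1e-12))
  expect_error(partial_correlation(matrix(c(-1, 0, 0, 1), 2, 2)),
               "positive diagonal")
})

test_that("riemannian_mean satisfies its defining properties", {
  set.seed(4)
  S <- rand_spd(3)
  expect_equal(riemannian_mean(list(S)), S)
  # commuting case reduces to the geometric mean
  expect_equal(riemannian_mean(list(diag(3), 4 * diag(3)), tol = 1e-12),
               2 * diag(3), tolerance = 1e-8)
  mats <- lapply(1:3, function(i) rand_spd(3))
  G <- riemannian_mean(mats, tol = 1e-8)
  Gih <- statestack:::powm_sym(G, -0.5)
  grad <- Reduce(`+`, lapply(mats, function(C)
    statestack:::logm_sym(Gih %*% C %*% Gih)))
  expect_lt(sqrt(sum(grad^2)), 1e-6)
  # local perturbations do not lower the Frechet variance
  fvar <- function(G0) sum(vapply(mats, function(C) {
    L <- statestack:::logm_sym(
      statestack:::powm_sym(G0, -0.5) %*% C %*%
        statestack:::powm_sym(G0, -0.5))
    sum(L^2)
  }, 0.0))
  f0 <- fvar(G)
  for (i in 1:20) {
    E <- matrix(rnorm(9, 0, 0.01), 3, 3)
    expect_gte(fvar(G + (E + t(E)) / 2), f0 - 1e-8)
  }
})

test_that("Karcher mean is affine invariant", {
  set.seed(5)
  mats <- lapply(1:4, function(i) rand_spd(3))
  W <- matrix(rnorm(9), 3, 3) + diag(3)
  G <- riemannian_mean(mats, tol = 1e-11)
  Gw <- riemannian_mean(lapply(mats, function(C) W %*% C %*% t(W)),
                        tol = 1e-11)
  expect_lt(max(abs(Gw - W %*% G %*% t(W))), 1e-6)
})

test_that("tangent projection round-trips through the exponential map", {
  set.seed(6)
  S <- rand_spd(3)
  expect_lt(max(abs(tangent_project(S, S))), 1e-10)
  expect_equal(tangent_project(diag(c(exp(1), exp(2))), diag(2)),
               diag(c(1, 2)))
  for (M in c(2, 5, 10)) {
    C <- rand_spd(M); G <- rand_spd(M)
    Tp <- tangent_project(C, G)
    Gh <- statestack:::powm_sym(G, 0.5)
    back <- Gh %*% statestack:::expm_sym(Tp) %*% Gh
    expect_lt(max(abs(back - C)), 1e-8)
  }
})

test_that("vectorisation is the isometric upper triangle", {
  expect_equal(vectorize_symmetric(matrix(c(1, 2, 2, 3), 2, 2)),
               c(1, 2 * sqrt(2), 3))
  expect_equal(vectorize_symmetric(matrix(0, 3, 3)), rep(0, 6))
  set.seed(7)
  S <- rand_spd(5)
  v <- vectorize_symmetric(S)
  expect_equal(sqrt(sum(v^2)), sqrt(sum(S^2)), tolerance = 1e-12)
  # row-major ordering
  S3 <- matrix(c(1, 4, 5, 4, 2, 6, 5, 6, 3), 3, 3)
  expect_equal(vectorize_symmetric(S3) / c(1, sqrt(2), sqrt(2), 1, sqrt(2), 1),
               c(1, 4, 5, 2, 6, 3))
  expect_error(vectorize_symmetric(matrix(c(1, 2, 3, 4), 2, 2)),
               "not symmetric")
})

test_that("assemble_features lays out blocks as documented", {
  truth <- make_test_hmm(K = 2, M = 3, sep = 2)
  sub <- dual_estimate(truth,
                       sample_timeseries(truth, 400, seed = 8)$timeseries)
  subs <- list(sub, sub, sub)
  fm <- assemble_features(subs)
  # identical subjects: tangent blocks exactly zero, rows identical
  tangent_cols <- grepl("tangent", fm$block_index$block)
  expect_lt(max(abs(fm$values[, tangent_cols])), 1e-8)
  expect_equal(fm$values[1, ], fm$values[3, ])
  # dimensional accounting
  expect_equal(ncol(fm$values),
               2 * 6 + 2 * 3 + 4)  # K tangent blocks + means + transitions
  fm1 <- assemble_features(list(sub), include_means = FALSE,
                           include_transitions = FALSE)
  expect_equal(ncol(fm1$values), 2 * (3 * 4 / 2))  # K tangent blocks only
  # K = 1: exactly one tangent block of M(M+1)/2 columns
  one <- dual_estimate(make_test_hmm(K = 1, M = 3),
                       matrix(rnorm(300), 100, 3))
  fm_one <- assemble_features(list(one, one), include_means = FALSE,
                              include_transitions = FALSE)
  expect_equal(ncol(fm_one$values), 3 * 4 / 2)
  expect_error(assemble_features(list(sub, make_test_hmm(K = 3, M = 3))),
               "disagree")
})

test_that("a planted covariance difference lands in its state's block", {
  set.seed(9)
  base <- make_test_hmm(K = 2, M = 3, sep = 2)
  subs <- lapply(1:40, function(n) {
    p <- base
    if (n > 20) {
      # group B: state 1 covariance scaled
      p$Sigma[, , 1] <- p$Sigma[, , 1] * 1.8
    }
    p$Sigma[, , 2] <- p$Sigma[, , 2] * exp(rnorm(1, 0, 0.05))
    p
  })
  fm <- assemble_features(subs, a = 0.01, include_means = FALSE,
                          include_transitions = FALSE)
  b1 <- fm$values[, fm$block_index$state == 1, drop = FALSE]
  b2 <- fm$values[, fm$block_index$state == 2, drop = FALSE]
  lab <- rep(1:2, each = 20)
  km1 <- kmeans(b1, 2, nstart = 5)$cluster
  agree <- function(cl) max(mean((cl == 1) == (lab == 1)),
                            mean((cl == 2) == (lab == 1)))
  expect_gte(agree(km1), 0.95)
  # state-2 block carries no group signal
  km2 <- kmeans(b2, 2, nstart = 5)$cluster
  expect_lte(agree(km2), 0.8)
})

test_that("static FC features separate groups with distinct covariance", {
  set.seed(10)
  Sg1 <- rand_spd(3); Sg2 <- Sg1 * 1.6
  ds <- c(lapply(1:15, function(i) mvn_fix <- {
    R <- chol(Sg1); matrix(rnorm(3 * 3000), 3000, 3) %*% R
  }), lapply(1:15, function(i) {
    R <- chol(Sg2); matrix(rnorm(3 * 3000), 3000, 3) %*% R
  }))
  fm <- static_fc_features(ds, a = 0.01)
  km <- kmeans(fm$values, 2, nstart = 5)$cluster
  lab <- rep(1:2, each = 15)
  expect_gte(max(mean((km == 1) == (lab == 1)),
                 mean((km == 2) == (lab == 1))), 0.95)
  # identical inputs give all-zero tangent features
  same <- lapply(1:4, function(i) ds[[1]])
  expect_lt(max(abs(static_fc_features(same, a = 0.01)$values)), 1e-8)
  expect_error(static_fc_features(list(matrix(0, 1, 3))), "at least 2")
})

test_that("feature matrices are deterministic and round-trip to disk", {
  co <- make_test_cohort(N = 10, M = 3, T_len = 100, seed = 11)
  fit <- suppressWarnings(fit_group_hmm(co$timeseries,
                                        hmm_control(K = 2, max_iter = 10),
                                        seed = 1))
  subs <- lapply(co$timeseries, function(X) dual_estimate(fit$params, X))
  fm1 <- assemble_features(subs)
  fm2 <- assemble_features(subs)
  expect_identical(fm1$values, fm2$values)
  expect_identical(fm1$block_index, fm2$block_index)
  path <- tempfile(fileext = ".csv")
  write_features(fm1, path)
  back <- read_features(path)
  expect_equal(back$values, fm1$values)
  expect_equal(back$block_index$block, fm1$block_index$block)
  unlink(c(path, paste0(path, ".blocks.json")))
})
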