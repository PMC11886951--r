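# Independent oracles used to pin down expected values.  Each one is a
# deliberately naive implementation (enumeration, explicit formulas,
# grid search) kept free of the package's own computational paths.

# State posteriors by brute-force enumeration over all K^T hidden paths.
fb_bruteforce <- function(params, X) {
  K <- length(params$pi)
  T_len <- nrow(X)
  dens <- sapply(seq_len(K), function(k) {
    R <- chol(params$Sigma[, , k])
    Xc <- sweep(X, 2L, params$mu[k, ], "-")
    W <- backsolve(R, t(Xc), transpose = TRUE)
    exp(-0.5 * (ncol(X) * log(2 * pi) + 2 * sum(log(diag(R))) +
                  colSums(W^2)))
  })
  dens <- matrix(dens, T_len, K)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_len)))
  joint <- apply(paths, 1, function(q) {
    pr <- params$pi[q[1]] * dens[1, q[1]]
    if (T_len > 1) {
      for (t in 2:T_len) pr <- pr * params$A[q[t - 1], q[t]] * dens[t, q[t]]
    }
    pr
  })
  Z <- sum(joint)
  gamma <- matrix(0, T_len, K)
  for (t in seq_len(T_len)) {
    for (k in seq_len(K)) gamma[t, k] <- sum(joint[paths[, t] == k]) / Z
  }
  xi <- array(0, c(max(T_len - 1, 0), K, K))
  if (T_len > 1) {
    for (t in seq_len(T_len - 1)) {
      for (i in seq_len(K)) for (j in seq_len(K)) {
        xi[t, i, j] <- sum(joint[paths[, t] == i & paths[, t + 1] == j]) / Z
      }
    }
  }
  list(gamma = gamma, xi = xi, loglik = log(Z))
}

# Explicit primal-form ridge prediction (the dual of KRR with a linear
# kernel): w = (U'U + lambda I)^-1 U'y.
primal_ridge_predict <- function(U_tr, y, U_te, lambda) {
  w <- solve(crossprod(U_tr) + diag(lambda, ncol(U_tr)), crossprod(U_tr, y))
  as.numeric(U_te %*% w)
}

# 1-D grid search over the two-model simplex.  The objective at
# beta = (b, 1-b) is quadratic in b, so the grid is evaluated through its
# exact expansion (same grid, vectorised arithmetic).
grid_simplex2 <- function(Yhat, y, step = 1e-6) {
  b <- seq(0, 1, by = step)
  d <- Yhat[, 1] - Yhat[, 2]
  e <- Yhat[, 2] - y
  obj <- sum(d^2) * b^2 + 2 * sum(d * e) * b + sum(e^2)
  c(b[which.min(obj)], 1 - b[which.min(obj)])
}

# Step-by-step transcription of the corrected repeated k-fold statistic
# (with the squared deviation in the variance).
ttest_transcribe <- function(x, k, r, n1, n2) {
  m <- (1 / (k * r)) * sum(x)
  s2 <- (1 / (k * r - 1)) * sum((x - m)^2)
  tstat <- m / sqrt((1 / (k * r) + n2 / n1) * s2)
  list(t = tstat, p = 2 * stats::pt(-abs(tstat), df = k * r - 1))
}

# Textbook Levene W on mean-centred absolute deviations.
levene_transcribe <- function(groups) {
  g <- length(groups)
  z <- lapply(groups, function(v) abs(v - mean(v)))
  ni <- lengths(z)
  N <- sum(ni)
  zdd <- mean(unlist(z))
  zid <- vapply(z, mean, 0.0)
  W <- ((N - g) / (g - 1)) *
    sum(ni * (zid - zdd)^2) /
    sum(unlist(lapply(z, function(v) (v - mean(v))^2)))
  list(W = W, p = stats::pf(W, g - 1, N - g, lower.tail = FALSE))
}

# Brute-force step-up FDR definition: adjusted p_i = min over all
# thresholds t >= p_i of t * m / (#{p <= t}), capped at 1.
bh_bruteforce <- function(p) {
  m <- length(p)
  vapply(seq_len(m), function(i) {
    cand <- p[p >= p[i]]
    min(1, min(vapply(cand, function(t) t * m / sum(p <= t), 0.0)))
  }, 0.0)
}

# Random SPD matrix with controlled condition number.
rand_spd <- function(M, spread = 1) {
  Q <- qr.Q(qr(matrix(rnorm(M * M), M, M)))
  ev <- exp(runif(M, -spread, spread))
  S <- Q %*% (ev * t(Q))
  (S + t(S)) / 2
}
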