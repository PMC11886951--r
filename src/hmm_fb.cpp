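#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward recursions for a discrete-state HMM.
//
// logB: T x K matrix of per-timepoint log emission densities.
// pi:   length-K initial state probabilities.
// A:    K x K row-stochastic transition matrix.
// with_xi: also return the full (T-1) x K x K pairwise posteriors
//          (stored as a (T-1) x (K*K) matrix, column index i + K*j).
//
// Returns gamma (T x K), xi_sum (K x K, summed over t), loglik, and
// optionally xi.  Scaling follows Rabiner; each row of logB is shifted
// by its max before exponentiation so the scale factors stay finite.
// [[Rcpp::export(name = ".fb_core")]]
List fb_core(NumericMatrix logB, NumericVector pi, NumericMatrix A,
             bool with_xi) {
  const int T = logB.nrow(), K = logB.ncol();
  NumericMatrix B(T, K), alpha(T, K), beta(T, K), gamma(T, K);
  NumericVector shift(T), c(T);

  for (int t = 0; t < T; ++t) {
    double m = logB(t, 0);
    for (int k = 1; k < K; ++k) if (logB(t, k) > m) m = logB(t, k);
    shift[t] = m;
    for (int k = 0; k < K; ++k) B(t, k) = std::exp(logB(t, k) - m);
  }

  // forward
  double c0 = 0.0;
  for (int k = 0; k < K; ++k) { alpha(0, k) = pi[k] * B(0, k); c0 += alpha(0, k); }
  if (!(c0 > 0.0) || !std::isfinite(c0))
    stop("forward recursion underflowed at t=1 (zero total likelihood)");
  c[0] = c0;
  for (int k = 0; k < K; ++k) alpha(0, k) /= c0;
  for (int t = 1; t < T; ++t) {
    double ct = 0.0;
    for (int j = 0; j < K; ++j) {
      double s = 0.0;
      for (int i = 0; i < K; ++i) s += alpha(t - 1, i) * A(i, j);
      double a = s * B(t, j);
      alpha(t, j) = a;
      ct += a;
    }
    if (!(ct > 0.0) || !std::isfinite(ct))
      stop("forward recursion underflowed at t=%d (zero total likelihood)", t + 1);
    c[t] = ct;
    for (int j = 0; j < K; ++j) alpha(t, j) /= ct;
  }

  // backward
  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int i = 0; i < K; ++i) {
      double s = 0.0;
      for (int j = 0; j < K; ++j) s += A(i, j) * B(t + 1, j) * beta(t + 1, j);
      beta(t, i) = s / c[t + 1];
    }
  }

  for (int t = 0; t < T; ++t) {
    double s = 0.0;
    for (int k = 0; k < K; ++k) { gamma(t, k) = alpha(t, k) * beta(t, k); s += gamma(t, k); }
    for (int k = 0; k < K; ++k) gamma(t, k) /= s;
  }

  NumericMatrix xi_sum(K, K);
  NumericMatrix xi;
  if (with_xi && T > 1) xi = NumericMatrix(T - 1, K * K);
  for (int t = 0; t + 1 < T; ++t) {
    double s = 0.0;
    for (int i = 0; i < K; ++i)
      for (int j = 0; j < K; ++j)
        s += alpha(t, i) * A(i, j) * B(t + 1, j) * beta(t + 1, j);
    for (int i = 0; i < K; ++i)
      for (int j = 0; j < K; ++j) {
        double v = alpha(t, i) * A(i, j) * B(t + 1, j) * beta(t + 1, j) / s;
        xi_sum(i, j) += v;
        if (with_xi) xi(t, i + K * j) = v;
      }
  }

  double ll = 0.0;
  for (int t = 0; t < T; ++t) ll += std::log(c[t]) + shift[t];
  if (!std::isfinite(ll))
    stop("log-likelihood is not finite despite scaling");

  if (with_xi)
    return List::create(_["gamma"] = gamma, _["xi_sum"] = xi_sum,
                        _["loglik"] = ll, _["xi"] = xi);
  return List::create(_["gamma"] = gamma, _["xi_sum"] = xi_sum,
                      _["loglik"] = ll);
}
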