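#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward pass for a Gaussian-emission HMM.
// B: n x K emission density matrix (floored upstream), pi: K initial
// probabilities, P: K x K row-stochastic transition matrix.
// Returns log-likelihood, per-sample posteriors gamma, summed transition
// expectations xi (K x K), and gamma at t = 1 (for the initial-state update).
// [[Rcpp::export(name = ".hmm_fwdbwd")]]
List hmm_fwdbwd(NumericMatrix B, NumericVector pi, NumericMatrix P) {
  const int n = B.nrow(), K = B.ncol();
  NumericMatrix alpha(n, K), beta(n, K);
  NumericVector c(n);

  double s = 0.0;
  for (int k = 0; k < K; ++k) { alpha(0, k) = pi[k] * B(0, k); s += alpha(0, k); }
  if (s <= 0) s = 1e-300;
  c[0] = s;
  for (int k = 0; k < K; ++k) alpha(0, k) /= s;

  for (int t = 1; t < n; ++t) {
    s = 0.0;
    for (int j = 0; j < K; ++j) {
      double a = 0.0;
      for (int i = 0; i < K; ++i) a += alpha(t - 1, i) * P(i, j);
      a *= B(t, j);
      alpha(t, j) = a;
      s += a;
    }
    if (s <= 0) s = 1e-300;
    c[t] = s;
    for (int j = 0; j < K; ++j) alpha(t, j) /= s;
  }

  for (int k = 0; k < K; ++k) beta(n - 1, k) = 1.0;
  for (int t = n - 2; t >= 0; --t) {
    for (int i = 0; i < K; ++i) {
      double b = 0.0;
      for (int j = 0; j < K; ++j) b += P(i, j) * B(t + 1, j) * beta(t + 1, j);
      beta(t, i) = b / c[t + 1];
    }
  }

  NumericMatrix gamma(n, K), xi(K, K);
  for (int t = 0; t < n; ++t) {
    double g = 0.0;
    for (int k = 0; k < K; ++k) { gamma(t, k) = alpha(t, k) * beta(t, k); g += gamma(t, k); }
    if (g <= 0) g = 1e-300;
    for (int k = 0; k < K; ++k) gamma(t, k) /= g;
  }
  for (int t = 0; t < n - 1; ++t) {
    for (int i = 0; i < K; ++i)
      for (int j = 0; j < K; ++j)
        xi(i, j) += alpha(t, i) * P(i, j) * B(t + 1, j) * beta(t + 1, j) / c[t + 1];
  }

  double ll = 0.0;
  for (int t = 0; t < n; ++t) ll += std::log(c[t]);

  return List::create(_["loglik"] = ll, _["gamma"] = gamma, _["xi"] = xi);
}

// Viterbi maximum-likelihood path in log space.
// logB: n x K log emission matrix; logpi, logP log-transformed parameters.
// Returns the 1-based state path.
// [[Rcpp::export(name = ".hmm_viterbi")]]
IntegerVector hmm_viterbi(NumericMatrix logB, NumericVector logpi,
                          NumericMatrix logP) {
  const int n = logB.nrow(), K = logB.ncol();
  NumericMatrix delta(n, K);
  IntegerMatrix psi(n, K);
  for (int k = 0; k < K; ++k) delta(0, k) = logpi[k] + logB(0, k);
  for (int t = 1; t < n; ++t) {
    for (int j = 0; j < K; ++j) {
      double best = R_NegInf; int arg = 0;
      for (int i = 0; i < K; ++i) {
        double v = delta(t - 1, i) + logP(i, j);
        if (v > best) { best = v; arg = i; }
      }
      delta(t, j) = best + logB(t, j);
      psi(t, j) = arg;
    }
  }
  IntegerVector path(n);
  int arg = 0; double best = R_NegInf;
  for (int k = 0; k < K; ++k) if (delta(n - 1, k) > best) { best = delta(n - 1, k); arg = k; }
  path[n - 1] = arg + 1;
  for (int t = n - 1; t > 0; --t) {
    arg = psi(t, arg);
    path[t - 1] = arg + 1;
  }
  return path;
}

// Viterbi path log-probability (for the path-likelihood inequality check).
// [[Rcpp::export(name = ".hmm_path_loglik")]]
double hmm_path_loglik(IntegerVector path, NumericMatrix logB,
                       NumericVector logpi, NumericMatrix logP) {
  const int n = logB.nrow();
  double ll = logpi[path[0] - 1] + logB(0, path[0] - 1);
  for (int t = 1; t < n; ++t)
    ll += logP(path[t - 1] - 1, path[t] - 1) + logB(t, path[t] - 1);
  return ll;
}
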