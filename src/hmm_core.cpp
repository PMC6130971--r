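#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward pass for a discrete-time HMM.
//
// logB    : T x K matrix of per-frame emission log-densities
// init    : length-K initial state probabilities
// trans   : K x K row-stochastic transition matrix
//
// Returns the log-likelihood, the T x K posterior state probabilities
// (gamma) and the K x K matrix of expected transition counts (xi summed
// over t). Emission densities are rescaled per frame by their row maximum
// before exponentiation so that near-noiseless traces (very large |logB|)
// do not underflow; the offset cancels in gamma/xi and is restored in the
// log-likelihood.
// [[Rcpp::export]]
List fk_forward_backward(NumericMatrix logB, NumericVector init,
                         NumericMatrix trans) {
  const int T = logB.nrow(), K = logB.ncol();
  NumericMatrix B(T, K);
  NumericVector off(T);
  for (int t = 0; t < T; ++t) {
    double m = logB(t, 0);
    for (int k = 1; k < K; ++k)
      if (logB(t, k) > m) m = logB(t, k);
    off[t] = m;
    for (int k = 0; k < K; ++k) B(t, k) = std::exp(logB(t, k) - m);
  }

  NumericMatrix alpha(T, K), beta(T, K);
  NumericVector c(T);

  double s = 0.0;
  for (int k = 0; k < K; ++k) {
    alpha(0, k) = init[k] * B(0, k);
    s += alpha(0, k);
  }
  c[0] = s;
  for (int k = 0; k < K; ++k) alpha(0, k) /= s;

  for (int t = 1; t < T; ++t) {
    s = 0.0;
    for (int j = 0; j < K; ++j) {
      double a = 0.0;
      for (int i = 0; i < K; ++i) a += alpha(t - 1, i) * trans(i, j);
      a *= B(t, j);
      alpha(t, j) = a;
      s += a;
    }
    c[t] = s;
    for (int j = 0; j < K; ++j) alpha(t, j) /= s;
  }

  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int i = 0; i < K; ++i) {
      double b = 0.0;
      for (int j = 0; j < K; ++j) b += trans(i, j) * B(t + 1, j) * beta(t + 1, j);
      beta(t, i) = b / c[t + 1];
    }
  }

  NumericMatrix gamma(T, K);
  for (int t = 0; t < T; ++t) {
    double g = 0.0;
    for (int k = 0; k < K; ++k) {
      gamma(t, k) = alpha(t, k) * beta(t, k);
      g += gamma(t, k);
    }
    for (int k = 0; k < K; ++k) gamma(t, k) /= g;
  }

  NumericMatrix xi(K, K);
  for (int t = 0; t < T - 1; ++t)
    for (int i = 0; i < K; ++i)
      for (int j = 0; j < K; ++j)
        xi(i, j) += alpha(t, i) * trans(i, j) * B(t + 1, j) * beta(t + 1, j) / c[t + 1];

  double ll = 0.0;
  for (int t = 0; t < T; ++t) ll += std::log(c[t]) + off[t];

  return List::create(_["loglik"] = ll, _["gamma"] = gamma, _["xi_sum"] = xi);
}

// Viterbi decoding in log space; returns a 1-based state path of length T.
// [[Rcpp::export]]
IntegerVector fk_viterbi(NumericMatrix logB, NumericVector log_init,
                         NumericMatrix log_trans) {
  const int T = logB.nrow(), K = logB.ncol();
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);
  for (int k = 0; k < K; ++k) delta(0, k) = log_init[k] + logB(0, k);
  for (int t = 1; t < T; ++t) {
    for (int j = 0; j < K; ++j) {
      double best = R_NegInf;
      int arg = 0;
      for (int i = 0; i < K; ++i) {
        double v = delta(t - 1, i) + log_trans(i, j);
        if (v > best) { best = v; arg = i; }
      }
      delta(t, j) = best + logB(t, j);
      psi(t, j) = arg;
    }
  }
  IntegerVector path(T);
  int best = 0;
  for (int k = 1; k < K; ++k)
    if (delta(T - 1, k) > delta(T - 1, best)) best = k;
  path[T - 1] = best + 1;
  for (int t = T - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1] - 1) + 1;
  return path;
}
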