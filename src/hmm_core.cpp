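#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Scaled forward-backward recursions.  Works with *unnormalized* transition
// weights (exp of expected log-parameters in the variational E-step, or
// proper probabilities in plain Baum-Welch); the log-normalizer lnZ absorbs
// the scaling and is the quantity the ELBO needs.
//
// logPi: K, logA: K x K, logB: T x K (log emission weights).
// Returns gamma (T x K, rows sum to 1), xiSum (K x K, expected transition
// counts summed over t), lnZ.
// [[Rcpp::export]]
List cpp_forward_backward(NumericVector logPi, NumericMatrix logA,
    NumericMatrix logB) {
  const int T = logB.nrow(), K = logB.ncol();
  NumericMatrix A(K, K);
  for (int j = 0; j < K; ++j)
    for (int k = 0; k < K; ++k) A(j, k) = std::exp(logA(j, k));

  NumericMatrix alpha(T, K), beta(T, K), B(T, K);
  NumericVector c(T), shift(T);
  double lnZ = 0.0;

  for (int t = 0; t < T; ++t) {
    double m = logB(t, 0);
    for (int k = 1; k < K; ++k) if (logB(t, k) > m) m = logB(t, k);
    shift[t] = m;
    for (int k = 0; k < K; ++k) B(t, k) = std::exp(logB(t, k) - m);
  }

  // forward
  double csum = 0.0;
  for (int k = 0; k < K; ++k) {
    alpha(0, k) = std::exp(logPi[k]) * B(0, k);
    csum += alpha(0, k);
  }
  c[0] = csum;
  for (int k = 0; k < K; ++k) alpha(0, k) /= csum;
  lnZ += std::log(csum) + shift[0];
  for (int t = 1; t < T; ++t) {
    csum = 0.0;
    for (int k = 0; k < K; ++k) {
      double s = 0.0;
      for (int j = 0; j < K; ++j) s += alpha(t - 1, j) * A(j, k);
      double v = s * B(t, k);
      alpha(t, k) = v;
      csum += v;
    }
    c[t] = csum;
    for (int k = 0; k < K; ++k) alpha(t, k) /= csum;
    lnZ += std::log(csum) + shift[t];
  }

  // backward (scaled by the forward normalizers)
  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int j = 0; j < K; ++j) {
      double s = 0.0;
      for (int k = 0; k < K; ++k) s += A(j, k) * B(t + 1, k) * beta(t + 1, k);
      beta(t, j) = s / c[t + 1];
    }
  }

  NumericMatrix gamma(T, K), xiSum(K, K);
  for (int t = 0; t < T; ++t) {
    double g = 0.0;
    for (int k = 0; k < K; ++k) { gamma(t, k) = alpha(t, k) * beta(t, k); g += gamma(t, k); }
    for (int k = 0; k < K; ++k) gamma(t, k) /= g;
  }
  for (int t = 1; t < T; ++t) {
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k)
        xiSum(j, k) += alpha(t - 1, j) * A(j, k) * B(t, k) * beta(t, k) / c[t];
  }

  return List::create(_["gamma"] = gamma, _["xiSum"] = xiSum, _["lnZ"] = lnZ);
}

// Viterbi decoding; ties broken toward the lower state index.
// [[Rcpp::export]]
IntegerVector cpp_viterbi(NumericVector logPi, NumericMatrix logA,
    NumericMatrix logB) {
  const int T = logB.nrow(), K = logB.ncol();
  NumericMatrix d(T, K);
  IntegerMatrix back(T, K);
  for (int k = 0; k < K; ++k) d(0, k) = logPi[k] + logB(0, k);
  for (int t = 1; t < T; ++t) {
    for (int k = 0; k < K; ++k) {
      double best = d(t - 1, 0) + logA(0, k);
      int arg = 0;
      for (int j = 1; j < K; ++j) {
        double v = d(t - 1, j) + logA(j, k);
        if (v > best) { best = v; arg = j; }   // strict >: lower index wins ties
      }
      d(t, k) = best + logB(t, k);
      back(t, k) = arg;
    }
  }
  IntegerVector path(T);
  int arg = 0;
  double best = d(T - 1, 0);
  for (int k = 1; k < K; ++k) if (d(T - 1, k) > best) { best = d(T - 1, k); arg = k; }
  path[T - 1] = arg + 1;
  for (int t = T - 2; t >= 0; --t) {
    arg = back(t + 1, arg);
    path[t] = arg + 1;
  }
  return path;
}
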