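#include <Rcpp.h>
using namespace Rcpp;

// Numerically stable log(sum(exp(x))) over a row segment.
static inline double logsumexp(const double* x, int n) {
  double m = R_NegInf;
  for (int i = 0; i < n; ++i) if (x[i] > m) m = x[i];
  if (!R_finite(m)) return m;
  double s = 0.0;
  for (int i = 0; i < n; ++i) s += std::exp(x[i] - m);
  return m + std::log(s);
}

// Forward-backward pass in log space for a single observation sequence.
// logB: T x K matrix of per-state observation log-densities.
// Returns posterior state probabilities (gamma), expected transition counts
// summed over time (xi_sum, linear scale), and the sequence log-likelihood.
// [[Rcpp::export]]
List hmm_forward_backward_cpp(NumericMatrix logB, NumericMatrix logA,
                              NumericVector logpi) {
  const int T = logB.nrow(), K = logB.ncol();
  NumericMatrix la(T, K), lb(T, K);
  std::vector<double> buf(K);

  for (int k = 0; k < K; ++k) la(0, k) = logpi[k] + logB(0, k);
  for (int t = 1; t < T; ++t) {
    for (int k = 0; k < K; ++k) {
      for (int j = 0; j < K; ++j) buf[j] = la(t - 1, j) + logA(j, k);
      la(t, k) = logsumexp(buf.data(), K) + logB(t, k);
    }
  }
  for (int k = 0; k < K; ++k) buf[k] = la(T - 1, k);
  const double loglik = logsumexp(buf.data(), K);

  for (int k = 0; k < K; ++k) lb(T - 1, k) = 0.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int k = 0; k < K; ++k) {
      for (int j = 0; j < K; ++j)
        buf[j] = logA(k, j) + logB(t + 1, j) + lb(t + 1, j);
      lb(t, k) = logsumexp(buf.data(), K);
    }
  }

  NumericMatrix gamma(T, K);
  for (int t = 0; t < T; ++t)
    for (int k = 0; k < K; ++k)
      gamma(t, k) = std::exp(la(t, k) + lb(t, k) - loglik);

  NumericMatrix xi_sum(K, K);
  for (int t = 0; t + 1 < T; ++t)
    for (int i = 0; i < K; ++i)
      for (int j = 0; j < K; ++j)
        xi_sum(i, j) += std::exp(la(t, i) + logA(i, j) + logB(t + 1, j) +
                                 lb(t + 1, j) - loglik);

  return List::create(_["gamma"] = gamma, _["xi_sum"] = xi_sum,
                      _["loglik"] = loglik);
}

// Forward pass only: sequence log-likelihood under the model.
// [[Rcpp::export]]
double hmm_loglik_cpp(NumericMatrix logB, NumericMatrix logA,
                      NumericVector logpi) {
  const int T = logB.nrow(), K = logB.ncol();
  std::vector<double> prev(K), cur(K), buf(K);
  for (int k = 0; k < K; ++k) prev[k] = logpi[k] + logB(0, k);
  for (int t = 1; t < T; ++t) {
    for (int k = 0; k < K; ++k) {
      for (int j = 0; j < K; ++j) buf[j] = prev[j] + logA(j, k);
      cur[k] = logsumexp(buf.data(), K) + logB(t, k);
    }
    prev = cur;
  }
  return logsumexp(prev.data(), K);
}

// Viterbi most-likely joint path (0-based state indices).
// [[Rcpp::export]]
IntegerVector hmm_viterbi_cpp(NumericMatrix logB, NumericMatrix logA,
                              NumericVector logpi) {
  const int T = logB.nrow(), K = logB.ncol();
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);

  for (int k = 0; k < K; ++k) delta(0, k) = logpi[k] + logB(0, k);
  for (int t = 1; t < T; ++t) {
    for (int k = 0; k < K; ++k) {
      double best = R_NegInf;
      int arg = 0;
      for (int j = 0; j < K; ++j) {
        const double v = delta(t - 1, j) + logA(j, k);
        if (v > best) { best = v; arg = j; }
      }
      delta(t, k) = best + logB(t, k);
      psi(t, k) = arg;
    }
  }

  IntegerVector path(T);
  double best = R_NegInf;
  for (int k = 0; k < K; ++k)
    if (delta(T - 1, k) > best) { best = delta(T - 1, k); path[T - 1] = k; }
  for (int t = T - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  return path;
}
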