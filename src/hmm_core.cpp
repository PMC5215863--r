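#include <Rcpp.h>
using namespace Rcpp;

// log-space recursions: simpler correctness argument than scaling factors
// when emission log-densities carry a probability floor.

static inline double logsumexp(const double* x, int n) {
  double m = R_NegInf;
  for (int i = 0; i < n; ++i) if (x[i] > m) m = x[i];
  if (!R_FINITE(m)) return m;
  double s = 0.0;
  for (int i = 0; i < n; ++i) s += std::exp(x[i] - m);
  return m + std::log(s);
}

// Forward-backward in log space.
// log_emis: T x K matrix of per-bin log emission densities.
// Returns gamma (T x K posteriors), xi_sum (K x K expected transition
// counts), and the total log-likelihood.
// [[Rcpp::export]]
List fb_core(NumericMatrix log_emis, NumericVector log_pi, NumericMatrix log_A) {
  const int T = log_emis.nrow(), K = log_emis.ncol();
  NumericMatrix la(T, K), lb(T, K), gamma(T, K);
  NumericMatrix xi(K, K);
  std::vector<double> buf(K);

  for (int k = 0; k < K; ++k) la(0, k) = log_pi[k] + log_emis(0, k);
  for (int t = 1; t < T; ++t)
    for (int k = 0; k < K; ++k) {
      for (int j = 0; j < K; ++j) buf[j] = la(t - 1, j) + log_A(j, k);
      la(t, k) = logsumexp(buf.data(), K) + log_emis(t, k);
    }

  for (int k = 0; k < K; ++k) lb(T - 1, k) = 0.0;
  for (int t = T - 2; t >= 0; --t)
    for (int k = 0; k < K; ++k) {
      for (int j = 0; j < K; ++j)
        buf[j] = log_A(k, j) + log_emis(t + 1, j) + lb(t + 1, j);
      lb(t, k) = logsumexp(buf.data(), K);
    }

  for (int k = 0; k < K; ++k) buf[k] = la(T - 1, k);
  const double ll = logsumexp(buf.data(), K);

  for (int t = 0; t < T; ++t) {
    for (int k = 0; k < K; ++k) buf[k] = la(t, k) + lb(t, k);
    const double z = logsumexp(buf.data(), K);
    for (int k = 0; k < K; ++k) gamma(t, k) = std::exp(buf[k] - z);
  }

  // expected transition counts pooled over t (log-domain accumulation
  // per cell would be O(TK^2 log); plain sums of exp are fine here since
  // every term is <= 1 after subtracting ll)
  for (int t = 0; t + 1 < T; ++t)
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k)
        xi(j, k) += std::exp(la(t, j) + log_A(j, k) + log_emis(t + 1, k) +
                             lb(t + 1, k) - ll);

  return List::create(_["gamma"] = gamma, _["xi_sum"] = xi,
                      _["log_likelihood"] = ll);
}

// Viterbi decoding; ties broken toward the lower state index (strict >
// while scanning states in ascending order).
// [[Rcpp::export]]
IntegerVector viterbi_core(NumericMatrix log_emis, NumericVector log_pi,
                           NumericMatrix log_A) {
  const int T = log_emis.nrow(), K = log_emis.ncol();
  NumericMatrix delta(T, K);
  IntegerMatrix back(T, K);

  for (int k = 0; k < K; ++k) delta(0, k) = log_pi[k] + log_emis(0, k);
  for (int t = 1; t < T; ++t)
    for (int k = 0; k < K; ++k) {
      double best = delta(t - 1, 0) + log_A(0, k);
      int arg = 0;
      for (int j = 1; j < K; ++j) {
        const double v = delta(t - 1, j) + log_A(j, k);
        if (v > best) { best = v; arg = j; }
      }
      delta(t, k) = best + log_emis(t, k);
      back(t, k) = arg;
    }

  IntegerVector path(T);
  int arg = 0;
  double best = delta(T - 1, 0);
  for (int k = 1; k < K; ++k)
    if (delta(T - 1, k) > best) { best = delta(T - 1, k); arg = k; }
  path[T - 1] = arg + 1;
  for (int t = T - 2; t >= 0; --t) {
    arg = back(t + 1, arg);
    path[t] = arg + 1;
  }
  return path;
}
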