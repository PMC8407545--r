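#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward over a sequence of bins grouped into independent
// chains (chromosomes). Emission log-densities come in as an n x K matrix;
// the chain restarts from the initial distribution at every chain boundary.

// [[Rcpp::export]]
List hmm_forward_backward(NumericMatrix log_emiss, NumericMatrix trans,
                          NumericVector init, IntegerVector chain) {
  const int n = log_emiss.nrow(), K = log_emiss.ncol();
  NumericMatrix alpha(n, K), beta(n, K), gamma(n, K);
  NumericVector scale(n);
  double loglik = 0.0;

  for (int t = 0; t < n; ++t) {
    double mx = R_NegInf;
    for (int k = 0; k < K; ++k) mx = std::max(mx, log_emiss(t, k));
    double s = 0.0;
    for (int k = 0; k < K; ++k) {
      double prior;
      if (t == 0 || chain[t] != chain[t - 1]) {
        prior = init[k];
      } else {
        prior = 0.0;
        for (int j = 0; j < K; ++j) prior += alpha(t - 1, j) * trans(j, k);
      }
      double a = prior * std::exp(log_emiss(t, k) - mx);
      alpha(t, k) = a;
      s += a;
    }
    scale[t] = s;
    loglik += std::log(s) + mx;
    for (int k = 0; k < K; ++k) alpha(t, k) /= s;
  }

  for (int t = n - 1; t >= 0; --t) {
    if (t == n - 1 || chain[t] != chain[t + 1]) {
      for (int k = 0; k < K; ++k) beta(t, k) = 1.0;
    } else {
      double mx = R_NegInf;
      for (int k = 0; k < K; ++k) mx = std::max(mx, log_emiss(t + 1, k));
      for (int k = 0; k < K; ++k) {
        double b = 0.0;
        for (int j = 0; j < K; ++j)
          b += trans(k, j) * std::exp(log_emiss(t + 1, j) - mx) * beta(t + 1, j);
        beta(t, k) = b;
      }
      double s = 0.0;
      for (int k = 0; k < K; ++k) s += beta(t, k);
      if (s > 0) for (int k = 0; k < K; ++k) beta(t, k) /= s;
    }
  }

  for (int t = 0; t < n; ++t) {
    double s = 0.0;
    for (int k = 0; k < K; ++k) {
      gamma(t, k) = alpha(t, k) * beta(t, k);
      s += gamma(t, k);
    }
    for (int k = 0; k < K; ++k) gamma(t, k) /= s;
  }

  return List::create(_["gamma"] = gamma, _["loglik"] = loglik);
}

// Viterbi decoding with the same chain-restart convention; returns 1-based
// state indices.

// [[Rcpp::export]]
IntegerVector hmm_viterbi(NumericMatrix log_emiss, NumericMatrix trans,
                          NumericVector init, IntegerVector chain) {
  const int n = log_emiss.nrow(), K = log_emiss.ncol();
  NumericMatrix delta(n, K);
  IntegerMatrix psi(n, K);
  NumericVector lt(K * K), li(K);
  for (int j = 0; j < K; ++j) {
    li[j] = std::log(init[j]);
    for (int k = 0; k < K; ++k) lt[j * K + k] = std::log(trans(j, k));
  }

  for (int t = 0; t < n; ++t) {
    for (int k = 0; k < K; ++k) {
      if (t == 0 || chain[t] != chain[t - 1]) {
        delta(t, k) = li[k] + log_emiss(t, k);
        psi(t, k) = -1;
      } else {
        double best = R_NegInf; int arg = 0;
        for (int j = 0; j < K; ++j) {
          double v = delta(t - 1, j) + lt[j * K + k];
          if (v > best) { best = v; arg = j; }
        }
        delta(t, k) = best + log_emiss(t, k);
        psi(t, k) = arg;
      }
    }
  }

  IntegerVector path(n);
  for (int t = n - 1; t >= 0; --t) {
    if (t == n - 1 || chain[t] != chain[t + 1]) {
      double best = R_NegInf; int arg = 0;
      for (int k = 0; k < K; ++k)
        if (delta(t, k) > best) { best = delta(t, k); arg = k; }
      path[t] = arg;
    } else {
      path[t] = psi(t + 1, path[t + 1]);
    }
  }
  for (int t = 0; t < n; ++t) path[t] += 1;
  return path;
}
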