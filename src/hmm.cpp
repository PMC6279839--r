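#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward recursions for a discrete-time HMM with a dense
// log-emission matrix. Emissions are max-shifted per window before
// exponentiation so the recursion stays in (0,1]-scaled space even for
// sequences of 1e5+ windows and Poisson means up to 1e3.
//
// logb: n x K log emission probabilities, pi: length-K initial distribution,
// A: K x K row-stochastic transition matrix.
// Returns filtered (alpha-hat), smoothed gamma, summed transition posteriors
// xi_sum and the total log-likelihood.
// [[Rcpp::export]]
List hmm_forward_backward_cpp(NumericMatrix logb, NumericVector pi,
                              NumericMatrix A) {
  const int n = logb.nrow(), K = logb.ncol();
  NumericMatrix b(n, K);
  NumericVector m(n);
  for (int t = 0; t < n; ++t) {
    double mx = logb(t, 0);
    for (int j = 1; j < K; ++j) mx = std::max(mx, logb(t, j));
    m[t] = mx;
    for (int j = 0; j < K; ++j) b(t, j) = std::exp(logb(t, j) - mx);
  }

  NumericMatrix alpha(n, K), beta(n, K), gamma(n, K), xi(K, K);
  NumericVector c(n);

  double s = 0.0;
  for (int j = 0; j < K; ++j) { alpha(0, j) = pi[j] * b(0, j); s += alpha(0, j); }
  if (s <= 0.0) stop("zero likelihood at window 1: emissions impossible under the model");
  c[0] = s;
  for (int j = 0; j < K; ++j) alpha(0, j) /= s;

  for (int t = 1; t < n; ++t) {
    s = 0.0;
    for (int j = 0; j < K; ++j) {
      double a = 0.0;
      for (int i = 0; i < K; ++i) a += alpha(t - 1, i) * A(i, j);
      a *= b(t, j);
      alpha(t, j) = a;
      s += a;
    }
    if (s <= 0.0) stop("zero likelihood at window %d: emissions impossible under the model", t + 1);
    c[t] = s;
    for (int j = 0; j < K; ++j) alpha(t, j) /= s;
  }

  for (int j = 0; j < K; ++j) beta(n - 1, j) = 1.0;
  for (int t = n - 2; t >= 0; --t) {
    for (int i = 0; i < K; ++i) {
      double v = 0.0;
      for (int j = 0; j < K; ++j) v += A(i, j) * b(t + 1, j) * beta(t + 1, j);
      beta(t, i) = v / c[t + 1];
    }
  }

  for (int t = 0; t < n; ++t) {
    double g = 0.0;
    for (int j = 0; j < K; ++j) { gamma(t, j) = alpha(t, j) * beta(t, j); g += gamma(t, j); }
    for (int j = 0; j < K; ++j) gamma(t, j) /= g;
  }

  for (int t = 0; t < n - 1; ++t)
    for (int i = 0; i < K; ++i)
      for (int j = 0; j < K; ++j)
        xi(i, j) += alpha(t, i) * A(i, j) * b(t + 1, j) * beta(t + 1, j) / c[t + 1];

  double ll = 0.0;
  for (int t = 0; t < n; ++t) ll += std::log(c[t]) + m[t];

  return List::create(_["filtered"] = alpha, _["gamma"] = gamma,
                      _["xi_sum"] = xi, _["loglik"] = ll);
}

// Viterbi decoding in log space. Ties broken towards the lower state index.
// Returns the 1-based most likely state path.
// [[Rcpp::export]]
IntegerVector hmm_viterbi_cpp(NumericMatrix logb, NumericVector logpi,
                              NumericMatrix logA) {
  const int n = logb.nrow(), K = logb.ncol();
  NumericMatrix delta(n, K);
  IntegerMatrix psi(n, K);

  for (int j = 0; j < K; ++j) delta(0, j) = logpi[j] + logb(0, j);
  for (int t = 1; t < n; ++t) {
    for (int j = 0; j < K; ++j) {
      double best = R_NegInf;
      int arg = 0;
      for (int i = 0; i < K; ++i) {
        const double v = delta(t - 1, i) + logA(i, j);
        if (v > best) { best = v; arg = i; }
      }
      delta(t, j) = best + logb(t, j);
      psi(t, j) = arg;
    }
  }

  IntegerVector path(n);
  double best = R_NegInf;
  int arg = 0;
  for (int j = 0; j < K; ++j)
    if (delta(n - 1, j) > best) { best = delta(n - 1, j); arg = j; }
  path[n - 1] = arg + 1;
  for (int t = n - 2; t >= 0; --t) {
    arg = psi(t + 1, arg);
    path[t] = arg + 1;
  }
  return path;
}
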