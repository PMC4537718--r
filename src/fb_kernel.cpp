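#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward pass for a two-state HMM.
//
// pi:   length-2 initial distribution
// A:    2x2 row-stochastic transition matrix
// emis: N x 2 matrix of emission likelihoods, emis(n, i) = P(o_n | s_n = i)
//
// Returns posterior state probabilities gamma (N x 2), the summed
// two-slice posteriors xi_sum (2x2, summed over n = 1..N-1), the
// log-likelihood, and optionally the full per-step xi as an (N-1) x 4
// matrix with columns (0->0, 0->1, 1->0, 1->1).
// [[Rcpp::export(name = ".fb_kernel")]]
List fb_kernel(NumericVector pi, NumericMatrix A, NumericMatrix emis,
               bool full_xi) {
  const int N = emis.nrow();
  if (N < 1) stop("chain length must be >= 1");
  NumericMatrix alpha(N, 2), beta(N, 2), gamma(N, 2);
  NumericVector cvec(N);

  double a0 = pi[0] * emis(0, 0);
  double a1 = pi[1] * emis(0, 1);
  double c = a0 + a1;
  if (!(c > 0.0))
    stop("zero-probability observation at bin 1 (clip emissions upstream)");
  alpha(0, 0) = a0 / c;
  alpha(0, 1) = a1 / c;
  cvec[0] = c;
  for (int n = 1; n < N; ++n) {
    a0 = (alpha(n - 1, 0) * A(0, 0) + alpha(n - 1, 1) * A(1, 0)) * emis(n, 0);
    a1 = (alpha(n - 1, 0) * A(0, 1) + alpha(n - 1, 1) * A(1, 1)) * emis(n, 1);
    c = a0 + a1;
    if (!(c > 0.0))
      stop("zero-probability observation at bin " + std::to_string(n + 1));
    alpha(n, 0) = a0 / c;
    alpha(n, 1) = a1 / c;
    cvec[n] = c;
  }

  beta(N - 1, 0) = 1.0;
  beta(N - 1, 1) = 1.0;
  for (int n = N - 2; n >= 0; --n) {
    const double e0 = emis(n + 1, 0) * beta(n + 1, 0);
    const double e1 = emis(n + 1, 1) * beta(n + 1, 1);
    beta(n, 0) = (A(0, 0) * e0 + A(0, 1) * e1) / cvec[n + 1];
    beta(n, 1) = (A(1, 0) * e0 + A(1, 1) * e1) / cvec[n + 1];
  }

  for (int n = 0; n < N; ++n) {
    const double g0 = alpha(n, 0) * beta(n, 0);
    const double g1 = alpha(n, 1) * beta(n, 1);
    const double s = g0 + g1;
    gamma(n, 0) = g0 / s;
    gamma(n, 1) = g1 / s;
  }

  NumericMatrix xi_sum(2, 2);
  NumericMatrix xi(full_xi && N > 1 ? N - 1 : 0, 4);
  for (int n = 0; n < N - 1; ++n) {
    for (int i = 0; i < 2; ++i) {
      for (int j = 0; j < 2; ++j) {
        const double v = alpha(n, i) * A(i, j) * emis(n + 1, j) *
                         beta(n + 1, j) / cvec[n + 1];
        xi_sum(i, j) += v;
        if (full_xi) xi(n, 2 * i + j) = v;
      }
    }
  }

  double ll = 0.0;
  for (int n = 0; n < N; ++n) ll += std::log(cvec[n]);

  List out = List::create(_["gamma"] = gamma, _["xi_sum"] = xi_sum,
                          _["log_lik"] = ll);
  if (full_xi) out["xi"] = xi;
  return out;
}
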