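#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward E-step for the K-class HBD mixture HMM on one
// chromosome block.
//
// emis: L x K emission probabilities, stay: (L-1) x K per-interval
// stay-in-class probabilities exp(-R_k d_t), M: mixing coefficients.
// Transition: stay on the diagonal plus (1 - stay_j) * M_k re-entry.
//
// Returns the log-likelihood, the posterior matrix gamma (L x K), the
// expected jump landings per class and the expected jump count (for the EM
// update of M; the initial draw of the block is counted by the caller via
// gamma's first row).
// [[Rcpp::export]]
List hbd_fb(NumericMatrix emis, NumericMatrix stay, NumericVector M) {
  const int L = emis.nrow(), K = emis.ncol();
  NumericMatrix alpha(L, K), beta(L, K), gamma(L, K);
  NumericVector cscale(L), jump_to(K);
  double ll = 0.0, jump_n = 0.0;

  // forward
  double s = 0.0;
  for (int k = 0; k < K; ++k) {
    alpha(0, k) = M[k] * emis(0, k);
    s += alpha(0, k);
  }
  cscale[0] = s;
  for (int k = 0; k < K; ++k) alpha(0, k) /= s;
  for (int t = 1; t < L; ++t) {
    double jump_mass = 0.0;
    for (int k = 0; k < K; ++k)
      jump_mass += alpha(t - 1, k) * (1.0 - stay(t - 1, k));
    s = 0.0;
    for (int k = 0; k < K; ++k) {
      double a = (alpha(t - 1, k) * stay(t - 1, k) + jump_mass * M[k]) *
                 emis(t, k);
      alpha(t, k) = a;
      s += a;
    }
    cscale[t] = s;
    for (int k = 0; k < K; ++k) alpha(t, k) /= s;
  }
  for (int t = 0; t < L; ++t) ll += std::log(cscale[t]);

  // backward
  for (int k = 0; k < K; ++k) beta(L - 1, k) = 1.0;
  for (int t = L - 2; t >= 0; --t) {
    double mb = 0.0;
    for (int k = 0; k < K; ++k) mb += M[k] * beta(t + 1, k) * emis(t + 1, k);
    for (int k = 0; k < K; ++k)
      beta(t, k) = (stay(t, k) * beta(t + 1, k) * emis(t + 1, k) +
                    (1.0 - stay(t, k)) * mb) / cscale[t + 1];
  }

  // posteriors and expected jumps
  for (int t = 0; t < L; ++t) {
    double g = 0.0;
    for (int k = 0; k < K; ++k) {
      gamma(t, k) = alpha(t, k) * beta(t, k);
      g += gamma(t, k);
    }
    for (int k = 0; k < K; ++k) gamma(t, k) /= g;
  }
  for (int t = 0; t < L - 1; ++t) {
    double leave = 0.0;
    for (int k = 0; k < K; ++k) leave += alpha(t, k) * (1.0 - stay(t, k));
    for (int k = 0; k < K; ++k) {
      double x = leave * M[k] * emis(t + 1, k) * beta(t + 1, k) /
                 cscale[t + 1];
      jump_to[k] += x;
      jump_n += x;
    }
  }
  return List::create(_["ll"] = ll, _["gamma"] = gamma,
                      _["jump_to"] = jump_to, _["jump_n"] = jump_n);
}
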