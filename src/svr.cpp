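// Epsilon-insensitive support vector regression in the kernel dual, solved
// by cyclic coordinate descent on beta_i = alpha_i - alpha_i^* in [-C, C]
// (liblinear-style; the offset is handled by centring y on the training
// mean, so there is no equality constraint).  Deterministic, no RNG.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector svr_dual_cd_cpp(const NumericMatrix& K, const NumericVector& y,
                              double C, double eps, int max_passes,
                              double tol) {
  const int n = K.nrow();
  NumericVector beta(n), f(n);   // f = K beta
  for (int pass = 0; pass < max_passes; ++pass) {
    double max_delta = 0;
    for (int i = 0; i < n; ++i) {
      const double kii = K(i, i);
      if (kii <= 0) continue;
      const double z = (y[i] - (f[i] - kii * beta[i])) / kii;
      double nb = 0.0;
      const double shrink = eps / kii;
      if (z > shrink) nb = z - shrink;
      else if (z < -shrink) nb = z + shrink;
      nb = std::min(C, std::max(-C, nb));
      const double d = nb - beta[i];
      if (d != 0) {
        for (int r = 0; r < n; ++r) f[r] += K(r, i) * d;
        beta[i] = nb;
        max_delta = std::max(max_delta, std::fabs(d));
      }
    }
    if (max_delta < tol) break;
  }
  return beta;
}
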