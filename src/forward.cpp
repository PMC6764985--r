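#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward recursion for a 2-state HMM over one segment.
// emis: n x 2 matrix of per-step emission probabilities (missing data
// already folded in as 1), tpm: 2x2 row-stochastic matrix, delta: initial
// distribution. Scaled forward variables are floored at 1e-300 before the
// log so pathological parameter proposals stay finite.
// [[Rcpp::export]]
double forward_loglik_cpp(const NumericMatrix& emis,
                          const NumericMatrix& tpm,
                          const NumericVector& delta) {
  const int n = emis.nrow();
  if (n == 0) return 0.0;
  double phi0 = delta[0] * emis(0, 0);
  double phi1 = delta[1] * emis(0, 1);
  double s = phi0 + phi1;
  if (s < 1e-300) s = 1e-300;
  double ll = std::log(s);
  phi0 /= s; phi1 /= s;
  const double g00 = tpm(0, 0), g01 = tpm(0, 1), g10 = tpm(1, 0), g11 = tpm(1, 1);
  for (int t = 1; t < n; ++t) {
    const double a0 = (phi0 * g00 + phi1 * g10) * emis(t, 0);
    const double a1 = (phi0 * g01 + phi1 * g11) * emis(t, 1);
    double sc = a0 + a1;
    if (sc < 1e-300) sc = 1e-300;
    ll += std::log(sc);
    phi0 = a0 / sc; phi1 = a1 / sc;
  }
  return ll;
}
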