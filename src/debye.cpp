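#include <Rcpp.h>
#include <cmath>

// Debye double sum over precomputed pair distances:
//   I(s) = self + 2 * sum_k wprod_k * sin(s * d_k) / (s * d_k)
// with self = sum_i w_i^2 and the s -> 0 limit sin(x)/x -> 1.
// [[Rcpp::export]]
Rcpp::NumericVector debye_sum(Rcpp::NumericVector dists,
                              Rcpp::NumericVector wprod,
                              double self,
                              Rcpp::NumericVector s) {
  const R_xlen_t np = dists.size();
  const R_xlen_t ns = s.size();
  if (wprod.size() != np)
    Rcpp::stop("dists and wprod must have equal length");
  Rcpp::NumericVector out(ns);
  for (R_xlen_t i = 0; i < ns; ++i) {
    const double si = s[i];
    double acc = 0.0;
    if (si <= 0.0) {
      for (R_xlen_t k = 0; k < np; ++k) acc += wprod[k];
    } else {
      for (R_xlen_t k = 0; k < np; ++k) {
        const double x = si * dists[k];
        acc += (x < 1e-12) ? wprod[k] : wprod[k] * std::sin(x) / x;
      }
    }
    out[i] = self + 2.0 * acc;
  }
  return out;
}
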