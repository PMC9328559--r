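// Lee-Seung multiplicative-update NMF (squared Frobenius objective).
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// One factorization from given nonnegative initial factors. Stops when the
// relative decrease of ||V - WH||_F^2 between iterations falls below tol.
// [[Rcpp::export(name = ".nmf_mu")]]
Rcpp::List nmf_mu(const arma::mat& V, arma::mat W, arma::mat H,
                  int max_iter = 1000, double tol = 1e-6) {
  const double eps = 1e-12;
  double prev = accu(square(V - W * H));
  double obj = prev;
  int it = 0;
  for (it = 1; it <= max_iter; ++it) {
    H %= (W.t() * V) / (W.t() * W * H + eps);
    W %= (V * H.t()) / (W * (H * H.t()) + eps);
    obj = accu(square(V - W * H));
    if (prev - obj >= 0.0 && (prev - obj) <= tol * prev) break;
    prev = obj;
  }
  return Rcpp::List::create(Rcpp::Named("W") = W, Rcpp::Named("H") = H,
                            Rcpp::Named("obj") = obj,
                            Rcpp::Named("iters") = std::min(it, max_iter));
}
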