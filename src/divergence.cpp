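// Nearest-neighbour search with temporal exclusion and mean-log-divergence
// tracking for the Rosenstein local divergence exponent.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// states: N x d delay-embedded state matrix.
// excl:   temporal exclusion window (|i - j| > excl for a valid neighbour).
// horizon: number of offsets tracked (0 .. horizon-1).
// Returns per-offset mean log distance and the number of surviving pairs.
// Pairs with zero initial distance carry no divergence information and are
// skipped; distances hitting exactly zero later are clamped to a tiny value.
// [[Rcpp::export(name = ".divergence_curve_cpp")]]
Rcpp::List divergence_curve_cpp(const arma::mat& states, int excl, int horizon) {
  const int N = states.n_rows;
  const int d = states.n_cols;
  if (N < 2) Rcpp::stop("need at least two state points");

  std::vector<int> nn(N, -1);
  for (int i = 0; i < N; ++i) {
    double best = datum::inf;
    int bestj = -1;
    for (int j = 0; j < N; ++j) {
      if (std::abs(i - j) <= excl) continue;
      double d2 = 0.0;
      for (int c = 0; c < d; ++c) {
        const double diff = states(i, c) - states(j, c);
        d2 += diff * diff;
        if (d2 >= best) break;
      }
      if (d2 < best) { best = d2; bestj = j; }
    }
    nn[i] = bestj;
  }

  vec sumlog(horizon, fill::zeros);
  ivec count(horizon, fill::zeros);
  const double floor2 = 1e-300;
  for (int i = 0; i < N; ++i) {
    const int j = nn[i];
    if (j < 0) continue;
    // skip coincident pairs: no measurable divergence
    double d0 = 0.0;
    for (int c = 0; c < d; ++c) {
      const double diff = states(i, c) - states(j, c);
      d0 += diff * diff;
    }
    if (d0 <= 0.0) continue;
    const int kmax = std::min(horizon, N - std::max(i, j));
    for (int k = 0; k < kmax; ++k) {
      double d2 = 0.0;
      for (int c = 0; c < d; ++c) {
        const double diff = states(i + k, c) - states(j + k, c);
        d2 += diff * diff;
      }
      if (d2 < floor2) d2 = floor2;
      sumlog(k) += 0.5 * std::log(d2);
      count(k) += 1;
    }
  }
  if (count(0) == 0) Rcpp::stop("all neighbours excluded or coincident");
  vec curve(horizon);
  for (int k = 0; k < horizon; ++k)
    curve(k) = count(k) > 0 ? sumlog(k) / count(k) : datum::nan;
  return Rcpp::List::create(Rcpp::Named("curve") = curve,
                            Rcpp::Named("n_pairs") = count);
}
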