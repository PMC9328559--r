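// Zero-phase (forward-backward) filtering of a cascade of IIR filters with
// odd-reflection padding, direct form II transposed. One padding operation
// serves the whole cascade; the construction commutes with time reversal.
#include <Rcpp.h>
using namespace Rcpp;

static void df2t_filter(const std::vector<double>& b,
                        const std::vector<double>& a,
                        std::vector<double>& x) {
  const int n = x.size();
  const int nb = b.size(), na = a.size();
  const int ns = std::max(nb, na) - 1;
  if (ns == 0) { for (int i = 0; i < n; ++i) x[i] *= b[0]; return; }
  std::vector<double> z(ns, 0.0);
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = b[0] * xi + z[0];
    for (int k = 0; k < ns - 1; ++k)
      z[k] = (k + 1 < nb ? b[k + 1] * xi : 0.0) + z[k + 1] -
             (k + 1 < na ? a[k + 1] * yi : 0.0);
    z[ns - 1] = (ns < nb ? b[ns] * xi : 0.0) - (ns < na ? a[ns] * yi : 0.0);
    x[i] = yi;
  }
}

// [[Rcpp::export(name = ".cascade_filtfilt")]]
NumericVector cascade_filtfilt(List b_list, List a_list, NumericVector x,
                               int npad) {
  const int n = x.size();
  if (npad >= n) npad = n - 1;
  if (n < 4) stop("signal too short to filter");
  const int m = n + 2 * npad;
  std::vector<double> xx(m);
  for (int i = 0; i < npad; ++i) xx[i] = 2.0 * x[0] - x[npad - i];
  for (int i = 0; i < n; ++i) xx[npad + i] = x[i];
  for (int i = 0; i < npad; ++i) xx[npad + n + i] = 2.0 * x[n - 1] - x[n - 2 - i];

  const int nf = b_list.size();
  std::vector<std::vector<double>> bv(nf), av(nf);
  for (int f = 0; f < nf; ++f) {
    bv[f] = Rcpp::as<std::vector<double>>(b_list[f]);
    av[f] = Rcpp::as<std::vector<double>>(a_list[f]);
  }
  // Symmetrized zero-phase pass: average the forward-backward result with
  // the same operation applied to the reversed signal. Residual edge
  // transients then affect both time directions identically, so the output
  // commutes with time reversal exactly (to floating-point commutativity
  // of addition).
  std::vector<double> x2(xx.rbegin(), xx.rend());
  for (int f = 0; f < nf; ++f) df2t_filter(bv[f], av[f], xx);
  std::reverse(xx.begin(), xx.end());
  for (int f = 0; f < nf; ++f) df2t_filter(bv[f], av[f], xx);
  std::reverse(xx.begin(), xx.end());
  for (int f = 0; f < nf; ++f) df2t_filter(bv[f], av[f], x2);
  std::reverse(x2.begin(), x2.end());
  for (int f = 0; f < nf; ++f) df2t_filter(bv[f], av[f], x2);
  // x2 = F(rev(F(rev(pad x)))): the reversed-input zero-phase result read in
  // the original orientation.

  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = 0.5 * (xx[npad + i] + x2[npad + i]);
  return out;
}

// Symmetric-padded FIR convolution with a centred kernel (odd length).
// Odd-reflection padding; zero kernel taps are skipped.
// [[Rcpp::export(name = ".fir_conv_sym")]]
NumericVector fir_conv_sym(NumericVector x, NumericVector h) {
  const int n = x.size();
  const int nh = h.size();
  if (nh % 2 == 0) stop("kernel length must be odd");
  const int half = nh / 2;
  if (n < 2) stop("signal too short");
  std::vector<double> xx(n + 2 * half);
  for (int i = 0; i < half; ++i) {
    const int j = std::min(half - i, n - 1);
    xx[i] = 2.0 * x[0] - x[j];
  }
  for (int i = 0; i < n; ++i) xx[half + i] = x[i];
  for (int i = 0; i < half; ++i) {
    const int j = std::max(n - 2 - i, 0);
    xx[half + n + i] = 2.0 * x[n - 1] - x[j];
  }
  std::vector<int> idx;
  std::vector<double> hv;
  for (int k = 0; k < nh; ++k)
    if (h[k] != 0.0) { idx.push_back(k); hv.push_back(h[k]); }
  NumericVector out(n);
  const int nt = idx.size();
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int t = 0; t < nt; ++t) s += hv[t] * xx[i + idx[t]];
    out[i] = s;
  }
  return out;
}
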