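#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// One causal IIR pass per column with zero initial conditions:
// y[t] = sum_k b[k] x[t-k] - sum_{m>=1} a[m] y[t-m]  (a[0] assumed 1).
// Matches stats::filter(convolution, sides = 1 with zero-prepend) followed
// by stats::filter(recursive), as used by signal::filter with zero init.
// [[Rcpp::export]]
NumericMatrix iir_filter_cols(NumericVector b, NumericVector a,
                              NumericMatrix x) {
  const int n = x.nrow(), nc = x.ncol();
  const int nb = b.size(), na = a.size();
  NumericMatrix y(n, nc);
  for (int c = 0; c < nc; ++c) {
    for (int t = 0; t < n; ++t) {
      double acc = 0.0;
      const int kmax = (t + 1 < nb) ? t + 1 : nb;
      for (int k = 0; k < kmax; ++k) acc += b[k] * x(t - k, c);
      const int mmax = (t < na - 1) ? t : na - 1;
      for (int m = 1; m <= mmax; ++m) acc -= a[m] * y(t - m, c);
      y(t, c) = acc;
    }
  }
  return y;
}

// All-pairs PLI (measure = 0) or dPLI (measure = 1) from a channels x
// samples matrix of instantaneous phases. Uses
// sign(wrapped(ph_j - ph_i)) = sign(sin(ph_j - ph_i)), with sign(0) = 0
// (equivalently a Heaviside step with H(0) = 0.5 for the dPLI).
// [[Rcpp::export]]
NumericMatrix phase_pair_matrix(NumericMatrix ph, int measure) {
  const int n = ph.nrow(), T = ph.ncol();
  std::vector<double> si(n * T), co(n * T);
  for (int i = 0; i < n; ++i)
    for (int t = 0; t < T; ++t) {
      si[i * T + t] = std::sin(ph(i, t));
      co[i * T + t] = std::cos(ph(i, t));
    }
  NumericMatrix m(n, n);
  for (int i = 0; i < n - 1; ++i) {
    const double *si_i = &si[i * T], *co_i = &co[i * T];
    for (int j = i + 1; j < n; ++j) {
      const double *si_j = &si[j * T], *co_j = &co[j * T];
      double acc = 0.0;
      for (int t = 0; t < T; ++t) {
        const double v = si_j[t] * co_i[t] - co_j[t] * si_i[t];
        acc += (v > 0.0) - (v < 0.0);
      }
      const double mean = acc / T;
      if (measure == 0) {
        m(i, j) = m(j, i) = std::fabs(mean);
      } else {
        const double d = (mean + 1.0) / 2.0;   // dPLI of j relative to i
        m(j, i) = d;
        m(i, j) = 1.0 - d;
      }
    }
  }
  return m;
}
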