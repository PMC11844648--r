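#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

static void iir_inplace(const std::vector<double>& b,
                        const std::vector<double>& a,
                        std::vector<double>& x) {
  // direct-form II transposed, a[0] assumed 1
  const int nb = b.size(), na = a.size();
  const int ns = std::max(nb, na);
  std::vector<double> z(ns, 0.0);
  for (size_t i = 0; i < x.size(); ++i) {
    double xn = x[i];
    double yn = b[0] * xn + z[0];
    for (int k = 1; k < ns; ++k) {
      double bk = (k < nb) ? b[k] : 0.0;
      double ak = (k < na) ? a[k] : 0.0;
      z[k - 1] = bk * xn - ak * yn + ((k < ns - 1) ? z[k] : 0.0);
    }
    x[i] = yn;
  }
}

// Zero-phase IIR filtering: zero-padded forward pass, then a backward pass,
// as in the classic filtfilt construction. Coefficients come from the filter
// design (e.g. a Butterworth band-pass); this kernel only runs the loop at
// C speed, which matters for 10-minute multichannel recordings.
// [[Rcpp::export(name = ".filtfilt_iir")]]
NumericVector filtfilt_iir(const NumericVector& b, const NumericVector& a,
                           const NumericVector& x) {
  if (a[0] == 0) stop("a[0] must be non-zero");
  const double a0 = a[0];
  std::vector<double> bb(b.begin(), b.end()), aa(a.begin(), a.end());
  for (size_t i = 0; i < bb.size(); ++i) bb[i] /= a0;
  for (size_t i = 0; i < aa.size(); ++i) aa[i] /= a0;
  const int n = x.size();
  const int pad = 2 * std::max(bb.size(), aa.size());
  std::vector<double> w(n + pad, 0.0);
  std::copy(x.begin(), x.end(), w.begin());
  iir_inplace(bb, aa, w);
  std::reverse(w.begin(), w.end());
  iir_inplace(bb, aa, w);
  std::reverse(w.begin(), w.end());
  NumericVector out(n);
  std::copy(w.begin(), w.begin() + n, out.begin());
  return out;
}

// Apply the zero-phase filter to every row of a channels x samples matrix,
// reusing one C++ buffer so no per-row R temporaries accumulate between
// garbage collections. The input is modified in place when unshared.
// [[Rcpp::export(name = ".filtfilt_rows")]]
SEXP filtfilt_rows(SEXP ms, const NumericVector& b, const NumericVector& a) {
  if (MAYBE_SHARED(ms)) ms = Rf_duplicate(ms);
  NumericMatrix m(ms);
  if (a[0] == 0) stop("a[0] must be non-zero");
  const double a0 = a[0];
  std::vector<double> bb(b.begin(), b.end()), aa(a.begin(), a.end());
  for (size_t i = 0; i < bb.size(); ++i) bb[i] /= a0;
  for (size_t i = 0; i < aa.size(); ++i) aa[i] /= a0;
  const int nr = m.nrow(), nc = m.ncol();
  const int pad = 2 * std::max(bb.size(), aa.size());
  std::vector<double> w(nc + pad);
  for (int r = 0; r < nr; ++r) {
    std::fill(w.begin(), w.end(), 0.0);
    for (int j = 0; j < nc; ++j) w[j] = m(r, j);
    iir_inplace(bb, aa, w);
    std::reverse(w.begin(), w.end());
    iir_inplace(bb, aa, w);
    for (int j = 0; j < nc; ++j) m(r, j) = w[nc + pad - 1 - j];
  }
  return m;
}
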