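#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Per-column median of a channels x samples matrix. Even channel counts use
// the mean of the two middle order statistics. A 10-minute 16-channel session
// has ~14.6M columns, which rules out apply() in R.
// [[Rcpp::export(name = ".col_medians")]]
NumericVector col_medians(const NumericMatrix& x) {
  const int nr = x.nrow(), nc = x.ncol();
  NumericVector out(nc);
  std::vector<double> buf(nr);
  const int lo = (nr - 1) / 2, hi = nr / 2;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) buf[i] = x(i, j);
    std::nth_element(buf.begin(), buf.begin() + lo, buf.end());
    double m = buf[lo];
    if (hi != lo) {
      double second = *std::min_element(buf.begin() + lo + 1, buf.end());
      m = (m + second) / 2.0;
    }
    out[j] = m;
  }
  return out;
}

// Common-median referencing in a single pass. The input is modified in
// place when it is not shared with other bindings (session matrices are
// ~2 GB, so avoidable copies matter); a shared input is duplicated first,
// preserving R's copy-on-modify semantics.
// [[Rcpp::export(name = ".subtract_col_medians")]]
SEXP subtract_col_medians(SEXP xs) {
  if (MAYBE_SHARED(xs)) xs = Rf_duplicate(xs);
  NumericMatrix x(xs);
  const int nr = x.nrow(), nc = x.ncol();
  std::vector<double> buf(nr);
  const int lo = (nr - 1) / 2, hi = nr / 2;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) buf[i] = x(i, j);
    std::nth_element(buf.begin(), buf.begin() + lo, buf.end());
    double m = buf[lo];
    if (hi != lo) {
      double second = *std::min_element(buf.begin() + lo + 1, buf.end());
      m = (m + second) / 2.0;
    }
    for (int i = 0; i < nr; ++i) x(i, j) -= m;
  }
  return x;
}

// Streaming finiteness check (no logical temporaries).
// [[Rcpp::export(name = ".all_finite")]]
bool all_finite(const NumericMatrix& x) {
  const R_xlen_t n = x.size();
  const double* p = REAL(SEXP(x));
  for (R_xlen_t i = 0; i < n; ++i)
    if (!R_finite(p[i])) return false;
  return true;
}
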