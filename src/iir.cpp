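#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

//' Direct-form II transposed IIR filter (internal)
//'
//' Single forward pass of the difference equation with zero initial
//' conditions; zero-phase application is built on top of this in R by
//' filtering twice with time reversal.
//'
//' @param b,a filter coefficient vectors (a[1] must be 1)
//' @param x input signal
//' @return filtered signal
//' @keywords internal
//' Zero-phase IIR filter (internal)
//'
//' Forward pass followed by a time-reversed pass, both with zero initial
//' conditions.
//'
//' @param b,a filter coefficient vectors (a[1] must be 1)
//' @param x input signal
//' @return zero-phase filtered signal
//' @keywords internal
// [[Rcpp::export]]
NumericVector iir_filtfilt(NumericVector b, NumericVector a, NumericVector x) {
  const int nb = b.size(), na = a.size(), n = x.size();
  const int nk = std::max(nb, na);
  std::vector<double> bb(nk, 0.0), aa(nk, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  std::vector<double> z(nk, 0.0), fwd(n);
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = bb[0] * xi + z[0];
    for (int k = 1; k < nk; ++k) z[k - 1] = bb[k] * xi + z[k] - aa[k] * yi;
    fwd[i] = yi;
  }
  std::fill(z.begin(), z.end(), 0.0);
  NumericVector y(n);
  for (int i = n - 1; i >= 0; --i) {
    const double xi = fwd[i];
    const double yi = bb[0] * xi + z[0];
    for (int k = 1; k < nk; ++k) z[k - 1] = bb[k] * xi + z[k] - aa[k] * yi;
    y[i] = yi;
  }
  return y;
}

//' Direct-form II transposed IIR filter (internal)
//'
//' Single forward pass of the difference equation with zero initial
//' conditions.
//'
//' @param b,a filter coefficient vectors (a[1] must be 1)
//' @param x input signal
//' @return filtered signal
//' @keywords internal
// [[Rcpp::export]]
NumericVector iir_filter(NumericVector b, NumericVector a, NumericVector x) {
  const int nb = b.size(), na = a.size(), n = x.size();
  const int nk = std::max(nb, na);
  std::vector<double> bb(nk, 0.0), aa(nk, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  std::vector<double> z(nk, 0.0);
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = bb[0] * xi + z[0];
    for (int k = 1; k < nk; ++k) {
      z[k - 1] = bb[k] * xi + z[k] - aa[k] * yi;
    }
    y[i] = yi;
  }
  return y;
}
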