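#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {
// direct-form II transposed IIR, a[0] assumed 1 (normalized upstream)
void df2t(const std::vector<double>& b, const std::vector<double>& a,
          double* x, int n, bool reverse) {
  const int nb = b.size(), na = a.size();
  const int ns = std::max(nb, na) - 1;
  std::vector<double> z(ns, 0.0);
  for (int k = 0; k < n; ++k) {
    int i = reverse ? n - 1 - k : k;
    double xi = x[i];
    double yi = (nb > 0 ? b[0] * xi : 0.0) + (ns > 0 ? z[0] : 0.0);
    for (int s = 0; s < ns; ++s) {
      double bn = (s + 1 < nb) ? b[s + 1] : 0.0;
      double an = (s + 1 < na) ? a[s + 1] : 0.0;
      double znext = (s + 1 < ns) ? z[s + 1] : 0.0;
      z[s] = bn * xi - an * yi + znext;
    }
    x[i] = yi;
  }
}
}

//' Zero-phase (forward-backward) IIR filtering with normalized
//' coefficients; numerator b, denominator a (a[1] == 1).
//' @noRd
// [[Rcpp::export]]
NumericVector cpp_filtfilt(NumericVector b, NumericVector a, NumericVector x) {
  int n = x.size();
  NumericVector y = clone(x);
  if (n == 0) return y;
  if (a.size() == 0 || a[0] == 0) stop("invalid denominator");
  std::vector<double> bb(b.begin(), b.end()), aa(a.begin(), a.end());
  for (auto& v : bb) v /= aa[0];
  for (auto& v : aa) v /= aa[0];
  df2t(bb, aa, REAL(y), n, false);
  df2t(bb, aa, REAL(y), n, true);
  return y;
}
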