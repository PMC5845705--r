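#include <Rcpp.h>
#include <algorithm>
#include <cstring>
#include <vector>
using namespace Rcpp;

//' Median of each column (used for the across-electrode median at every
//' sample of a voltage matrix stored electrodes x samples).
//' @noRd
// [[Rcpp::export]]
NumericVector cpp_col_median(NumericMatrix x) {
  const int nr = x.nrow(), nc = x.ncol();
  NumericVector out(nc);
  std::vector<double> buf(nr);
  const double* px = REAL(x);
  const int h = nr / 2;
  for (int j = 0; j < nc; ++j) {
    std::memcpy(buf.data(), px + static_cast<size_t>(j) * nr,
                nr * sizeof(double));
    std::nth_element(buf.begin(), buf.begin() + h, buf.end());
    double m = buf[h];
    if (nr % 2 == 0) {
      double lo = *std::max_element(buf.begin(), buf.begin() + h);
      m = (m + lo) / 2.0;
    }
    out[j] = m;
  }
  return out;
}
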