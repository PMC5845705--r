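#include <Rcpp.h>
using namespace Rcpp;

//' Subtract a per-column value from every row (single allocation).
//' @noRd
// [[Rcpp::export]]
NumericMatrix cpp_subtract_col(NumericMatrix x, NumericVector m) {
  const int nr = x.nrow(), nc = x.ncol();
  if (m.size() != nc) stop("length(m) must equal ncol(x)");
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    double mj = m[j];
    for (int i = 0; i < nr; ++i) out(i, j) = x(i, j) - mj;
  }
  return out;
}
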