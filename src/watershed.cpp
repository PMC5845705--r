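#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

namespace {
struct QItem {
  double value;
  long order;   // FIFO tie-break
  int idx;
};
struct QCmp {
  bool operator()(const QItem& a, const QItem& b) const {
    if (a.value != b.value) return a.value > b.value;  // min-heap on value
    return a.order > b.order;                          // then FIFO
  }
};
}

//' Meyer flooding watershed from imposed markers.
//'
//' `surface` is the landscape (flooded from low to high), `seeds` holds
//' positive integer labels at marker pixels and 0 elsewhere. Pixels where
//' two catchment basins meet become watershed lines (label 0 in the output);
//' pixels unreachable from any marker also stay 0.
//' @noRd
// [[Rcpp::export]]
IntegerMatrix cpp_marker_watershed(NumericMatrix surface, IntegerMatrix seeds) {
  const int nr = surface.nrow(), nc = surface.ncol();
  if (seeds.nrow() != nr || seeds.ncol() != nc)
    stop("surface and seeds must have the same dimensions");
  const int WSHED = -1, INQUEUE = -2;
  std::vector<int> lab(static_cast<size_t>(nr) * nc, 0);
  std::priority_queue<QItem, std::vector<QItem>, QCmp> pq;
  long order = 0;

  const int dr[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nnb = 8;

  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (seeds(r, c) > 0) lab[r + static_cast<size_t>(c) * nr] = seeds(r, c);

  // queue unlabeled neighbours of every marker pixel
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (lab[r + static_cast<size_t>(c) * nr] <= 0) continue;
      for (int k = 0; k < nnb; ++k) {
        int rr = r + dr[k], cc = c + dc[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        size_t q = rr + static_cast<size_t>(cc) * nr;
        if (lab[q] == 0) {
          lab[q] = INQUEUE;
          pq.push({surface(rr, cc), order++, static_cast<int>(q)});
        }
      }
    }
  }

  while (!pq.empty()) {
    QItem it = pq.top();
    pq.pop();
    int r = it.idx % nr, c = it.idx / nr;
    int found = 0;
    bool conflict = false;
    for (int k = 0; k < nnb; ++k) {
      int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      int l = lab[rr + static_cast<size_t>(cc) * nr];
      if (l > 0) {
        if (found == 0) found = l;
        else if (found != l) conflict = true;
      }
    }
    size_t q = it.idx;
    if (conflict || found == 0) {
      lab[q] = WSHED;
      continue;
    }
    lab[q] = found;
    for (int k = 0; k < nnb; ++k) {
      int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      size_t p = rr + static_cast<size_t>(cc) * nr;
      if (lab[p] == 0) {
        lab[p] = INQUEUE;
        pq.push({surface(rr, cc), order++, static_cast<int>(p)});
      }
    }
  }

  IntegerMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      int l = lab[r + static_cast<size_t>(c) * nr];
      out(r, c) = l > 0 ? l : 0;
    }
  return out;
}
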