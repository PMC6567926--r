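#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labeling of a binary mask by breadth-first search.
// Labels are assigned in column-major scan order, so label 1 is the
// component whose first pixel comes first in column-major order; this makes
// downstream bookkeeping deterministic.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  const int d4i[] = {-1, 1, 0, 0}, d4j[] = {0, 0, -1, 1};
  const int d8i[] = {-1, 1, 0, 0, -1, -1, 1, 1},
            d8j[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nd = (connectivity == 8) ? 8 : 4;
  const int *di = (connectivity == 8) ? d8i : d4i;
  const int *dj = (connectivity == 8) ? d8j : d4j;
  std::vector<int> qi, qj;
  qi.reserve(256); qj.reserve(256);
  int cur = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (mask(i, j) == TRUE && lab(i, j) == 0) {
        ++cur;
        qi.clear(); qj.clear();
        qi.push_back(i); qj.push_back(j);
        lab(i, j) = cur;
        for (size_t h = 0; h < qi.size(); ++h) {
          const int ci = qi[h], cj = qj[h];
          for (int d = 0; d < nd; ++d) {
            const int ni = ci + di[d], nj = cj + dj[d];
            if (ni >= 0 && ni < nr && nj >= 0 && nj < nc &&
                mask(ni, nj) == TRUE && lab(ni, nj) == 0) {
              lab(ni, nj) = cur;
              qi.push_back(ni); qj.push_back(nj);
            }
          }
        }
      }
    }
  }
  return lab;
}
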