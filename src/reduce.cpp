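#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Left-to-right Z2 column reduction of a boundary matrix in CSC form.
//
// ptr: length n+1, 0-based offsets into idx; idx: 0-based row positions,
// sorted ascending within each column.  Repeatedly adds (symmetric
// difference over Z2) an earlier column with the same lowest row until the
// column is empty or its lowest row is unclaimed.  Returns the lowest row
// of each reduced column, -1 for columns reduced to zero.
// [[Rcpp::export]]
IntegerVector reduce_boundary(IntegerVector ptr, IntegerVector idx, int n) {
  std::vector<std::vector<int>> cols(n);
  std::vector<int> low(n, -1), owner(n, -1);
  std::vector<int> merged;
  for (int j = 0; j < n; ++j) {
    std::vector<int> col(idx.begin() + ptr[j], idx.begin() + ptr[j + 1]);
    while (!col.empty()) {
      int l = col.back();
      int o = owner[l];
      if (o < 0) {
        owner[l] = j;
        low[j] = l;
        break;
      }
      merged.clear();
      std::set_symmetric_difference(col.begin(), col.end(),
                                    cols[o].begin(), cols[o].end(),
                                    std::back_inserter(merged));
      col.swap(merged);
    }
    cols[j] = std::move(col);
  }
  return wrap(low);
}
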