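#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Row-reduction over GF(2) with explicit pivot bookkeeping.
//
// Rows are bit-packed into 64-bit words so that a row operation is a
// word-level XOR sweep; this keeps connectome-scale boundary matrices
// (thousands of rows/columns) within seconds.
//
// Columns are scanned greedily in `col_order`; a column becomes a pivot iff
// it is independent of the previous pivots, and its pivot row is the first
// still-unused row in `row_priority` holding a 1 in the current (reduced)
// column. Full Gauss-Jordan elimination is performed, so on exit every pivot
// column is a unit vector and dependent columns are supported only on pivot
// rows. Columns of M outside `col_order` are never pivot candidates but are
// carried through the row operations (used for right-hand sides of solves).

// [[Rcpp::export(name = ".gf2_reduce_cpp")]]
List gf2_reduce_cpp(IntegerMatrix M, IntegerVector col_order,
                    IntegerVector row_priority) {
  const int nr = M.nrow(), nc = M.ncol();
  const int nw = (nc + 63) / 64;
  std::vector<std::vector<uint64_t>> R(nr, std::vector<uint64_t>(nw, 0));
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) {
      int v = M(i, j);
      if (v != 0 && v != 1) stop("matrix entries must be 0 or 1");
      if (v) R[i][j / 64] |= (uint64_t(1) << (j % 64));
    }

  std::vector<bool> used(nr, false);
  std::vector<int> piv_rows, piv_cols;
  piv_rows.reserve(std::min(nr, nc));
  piv_cols.reserve(std::min(nr, nc));

  for (int t = 0; t < col_order.size(); ++t) {
    const int j = col_order[t] - 1;
    if (j < 0 || j >= nc) stop("column index out of range");
    const int w = j / 64;
    const uint64_t bit = uint64_t(1) << (j % 64);
    int p = -1;
    for (int s = 0; s < row_priority.size(); ++s) {
      const int r = row_priority[s] - 1;
      if (r < 0 || r >= nr) stop("row index out of range");
      if (!used[r] && (R[r][w] & bit)) { p = r; break; }
    }
    if (p < 0) continue;  // dependent column
    used[p] = true;
    piv_rows.push_back(p + 1);
    piv_cols.push_back(j + 1);
    for (int r = 0; r < nr; ++r) {
      if (r != p && (R[r][w] & bit)) {
        uint64_t* a = R[r].data();
        const uint64_t* b = R[p].data();
        for (int q = 0; q < nw; ++q) a[q] ^= b[q];
      }
    }
  }

  IntegerMatrix out(nr, nc);
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j)
      out(i, j) = (R[i][j / 64] >> (j % 64)) & 1;

  return List::create(_["rank"] = (int)piv_rows.size(),
                      _["pivot_rows"] = wrap(piv_rows),
                      _["pivot_cols"] = wrap(piv_cols),
                      _["reduced"] = out);
}
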