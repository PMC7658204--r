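#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// 3D connected-component labeling by breadth-first flood fill.
// mask: logical vector in column-major (x fastest) order; dims: nx, ny, nz.
// connectivity: 6 (faces), 18 (faces+edges) or 26 (faces+edges+corners).
// Returns integer labels, 0 = background, components numbered 1.. in order
// of first (smallest linear index) encounter; callers re-order as needed.
// [[Rcpp::export]]
IntegerVector ccl3d_cpp(LogicalVector mask, IntegerVector dims, int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;

  std::vector<int> dx, dy, dz;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        int m = std::abs(a) + std::abs(b) + std::abs(c);
        if (m == 0) continue;
        if ((connectivity == 6 && m > 1) || (connectivity == 18 && m > 2)) continue;
        dx.push_back(a); dy.push_back(b); dz.push_back(c);
      }
  const int noff = (int)dx.size();

  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> stack;
  int cur = 0;

  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || labels[s] != 0) continue;
    ++cur;
    labels[s] = cur;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int k = (int)(v / ((R_xlen_t)nx * ny));
      int rem = (int)(v - (R_xlen_t)k * nx * ny);
      int j = rem / nx;
      int i = rem - j * nx;
      for (int o = 0; o < noff; ++o) {
        int ii = i + dx[o], jj = j + dy[o], kk = k + dz[o];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
        R_xlen_t w = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
        if (mask[w] && labels[w] == 0) {
          labels[w] = cur;
          stack.push_back(w);
        }
      }
    }
  }
  return labels;
}

// For each point (row) of a, the Euclidean distance to its nearest point in b.
// Points are physical coordinates in mm. Plain O(n*m) scan with running-min
// early exit; surfaces in this package are small enough (1e4-ish points).
// [[Rcpp::export]]
NumericVector nn_dists_cpp(NumericMatrix a, NumericMatrix b) {
  const int n = a.nrow(), m = b.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double ax = a(i, 0), ay = a(i, 1), az = a(i, 2);
    double best = R_PosInf;
    for (int j = 0; j < m; ++j) {
      double d0 = ax - b(j, 0), d1 = ay - b(j, 1), d2 = az - b(j, 2);
      double d = d0 * d0 + d1 * d1 + d2 * d2;
      if (d < best) best = d;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
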