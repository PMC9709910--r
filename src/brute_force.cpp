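#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Minimum-image distance for an orthorhombic box.
static inline double mi_dist(const NumericMatrix &p, int i, int j,
                             const NumericVector &box) {
  double s = 0.0;
  for (int k = 0; k < 3; ++k) {
    double d = p(j, k) - p(i, k);
    d -= box[k] * std::round(d / box[k]);
    s += d * d;
  }
  return std::sqrt(s);
}

// Exhaustive ordered-4-tuple unit-cell scan. om / pt are the oleic-mid and
// palmitic-tail coordinate matrices (n x 3, nm). Bands are inclusive.
// Returns a k x 4 matrix of 1-based row indices.
// [[Rcpp::export(name = "bf_unit_cells")]]
IntegerMatrix bf_unit_cells(NumericMatrix om, NumericMatrix pt,
                            NumericVector box, double p1_lo, double p1_hi,
                            NumericVector p2_lo, NumericVector p2_hi) {
  const int n = om.nrow();
  std::vector<int> rows;
  for (int m1 = 0; m1 < n; ++m1) {
    for (int m2 = 0; m2 < n; ++m2) {
      if (m2 == m1) continue;
      double p1a = mi_dist(om, m1, m2, box);
      if (p1a < p1_lo || p1a > p1_hi) continue;
      double d12 = mi_dist(pt, m1, m2, box);
      if (d12 < p2_lo[0] || d12 > p2_hi[0]) continue;
      for (int m3 = 0; m3 < n; ++m3) {
        if (m3 == m1 || m3 == m2) continue;
        double d13 = mi_dist(pt, m1, m3, box);
        if (d13 < p2_lo[1] || d13 > p2_hi[1]) continue;
        if (!(d12 < d13)) continue;  // condition (c), first inequality
        for (int m4 = 0; m4 < n; ++m4) {
          if (m4 == m1 || m4 == m2 || m4 == m3) continue;
          double p1b = mi_dist(om, m3, m4, box);
          if (p1b < p1_lo || p1b > p1_hi) continue;
          double d14 = mi_dist(pt, m1, m4, box);
          if (d14 < p2_lo[2] || d14 > p2_hi[2]) continue;
          double d24 = mi_dist(pt, m2, m4, box);
          if (d24 < p2_lo[3] || d24 > p2_hi[3]) continue;
          double d34 = mi_dist(pt, m3, m4, box);
          if (d34 < p2_lo[4] || d34 > p2_hi[4]) continue;
          if (!(d24 > d34)) continue;  // condition (c), second inequality
          rows.push_back(m1 + 1);
          rows.push_back(m2 + 1);
          rows.push_back(m3 + 1);
          rows.push_back(m4 + 1);
        }
      }
    }
  }
  const int k = rows.size() / 4;
  IntegerMatrix out(k, 4);
  for (int r = 0; r < k; ++r)
    for (int c = 0; c < 4; ++c) out(r, c) = rows[4 * r + c];
  return out;
}
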