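#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Nearest-neighbor distances from each query point to a reference set.
// The reference points are sorted by x; for each query we expand outward
// from the x-insertion point, always taking the side with the smaller
// x-gap, and stop once that gap alone exceeds the best distance found so
// far (x-gaps grow monotonically outward, so nothing further can win).
// Exact; O(n log n) typical, O(n^2) only for degenerate x layouts.
// [[Rcpp::export(name = ".nn_dist_cpp")]]
NumericVector nn_dist_cpp(NumericVector qx, NumericVector qy,
                          NumericVector rx, NumericVector ry) {
  const int nq = qx.size(), nr = rx.size();
  NumericVector out(nq);
  if (nr == 0) {
    std::fill(out.begin(), out.end(), NA_REAL);
    return out;
  }
  std::vector<int> ord(nr);
  for (int i = 0; i < nr; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return rx[a] < rx[b]; });
  std::vector<double> sx(nr), sy(nr);
  for (int i = 0; i < nr; ++i) { sx[i] = rx[ord[i]]; sy[i] = ry[ord[i]]; }

  for (int q = 0; q < nq; ++q) {
    const double x = qx[q], y = qy[q];
    int hi = std::lower_bound(sx.begin(), sx.end(), x) - sx.begin();
    int lo = hi - 1;
    double best2 = R_PosInf;
    while (lo >= 0 || hi < nr) {
      const double dl = (lo >= 0) ? x - sx[lo] : R_PosInf;
      const double dr = (hi < nr) ? sx[hi] - x : R_PosInf;
      if (dl <= dr) {
        if (dl * dl > best2) break;
        const double dy = y - sy[lo];
        const double d2 = dl * dl + dy * dy;
        if (d2 < best2) best2 = d2;
        --lo;
      } else {
        if (dr * dr > best2) break;
        const double dy = y - sy[hi];
        const double d2 = dr * dr + dy * dy;
        if (d2 < best2) best2 = d2;
        ++hi;
      }
    }
    out[q] = std::sqrt(best2);
  }
  return out;
}
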