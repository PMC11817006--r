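#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Dense Lucas-Kanade flow restricted to a rectangle, averaged.
// Gradients are central differences on the mean of the two frames;
// each pixel solves the 2x2 normal equations over a flat
// (2*win+1)^2 window.  Pixels whose structure tensor is
// ill-conditioned (flat patches, pure aperture) are skipped; if no
// pixel qualifies the flow is reported as 0.  Coordinates are
// 0-based, ROI half-open [x, x+w) x [y, y+h); positive vy is
// downward in image coordinates (row index increasing).
// [[Rcpp::export]]
NumericVector lk_flow_cpp(const NumericMatrix& prev, const NumericMatrix& curr,
                          int x, int y, int w, int h, int win = 2,
                          double min_eig = 1e-4) {
  const int nr = prev.nrow(), nc = prev.ncol();
  NumericMatrix Ix(nr, nc), Iy(nr, nc), It(nr, nc);
  const int i0 = std::max(1, y - win), i1 = std::min(nr - 2, y + h - 1 + win);
  const int j0 = std::max(1, x - win), j1 = std::min(nc - 2, x + w - 1 + win);
  for (int j = j0 - 1 < 0 ? 0 : j0 - 1; j <= std::min(nc - 1, j1 + 1); ++j)
    for (int i = i0 - 1 < 0 ? 0 : i0 - 1; i <= std::min(nr - 1, i1 + 1); ++i) {
      It(i, j) = curr(i, j) - prev(i, j);
    }
  for (int j = j0; j <= j1; ++j)
    for (int i = i0; i <= i1; ++i) {
      Iy(i, j) = 0.25 * ((prev(i + 1, j) + curr(i + 1, j)) -
                         (prev(i - 1, j) + curr(i - 1, j)));
      Ix(i, j) = 0.25 * ((prev(i, j + 1) + curr(i, j + 1)) -
                         (prev(i, j - 1) + curr(i, j - 1)));
    }
  double sum_vx = 0.0, sum_vy = 0.0;
  int n_valid = 0;
  const int pi0 = std::max(i0 + win, y), pi1 = std::min(i1 - win, y + h - 1);
  const int pj0 = std::max(j0 + win, x), pj1 = std::min(j1 - win, x + w - 1);
  for (int j = pj0; j <= pj1; ++j)
    for (int i = pi0; i <= pi1; ++i) {
      double axx = 0, axy = 0, ayy = 0, bx = 0, by = 0;
      for (int dj = -win; dj <= win; ++dj)
        for (int di = -win; di <= win; ++di) {
          const double gx = Ix(i + di, j + dj);
          const double gy = Iy(i + di, j + dj);
          const double gt = It(i + di, j + dj);
          axx += gx * gx; axy += gx * gy; ayy += gy * gy;
          bx -= gx * gt;  by -= gy * gt;
        }
      // smaller eigenvalue of [axx axy; axy ayy]
      const double tr = 0.5 * (axx + ayy);
      const double det = axx * ayy - axy * axy;
      const double disc = std::sqrt(std::max(0.0, tr * tr - det));
      const double lmin = tr - disc;
      const int area = (2 * win + 1) * (2 * win + 1);
      if (lmin < min_eig * area || det <= 0) continue;
      sum_vx += (ayy * bx - axy * by) / det;
      sum_vy += (axx * by - axy * bx) / det;
      ++n_valid;
    }
  NumericVector res(3);
  if (n_valid > 0) {
    res[0] = sum_vx / n_valid;
    res[1] = sum_vy / n_valid;
  }
  res[2] = n_valid;
  return res;
}
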