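#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Symmetric reflection (edge pixel included): for n = 4, indices
// -2,-1,0,1,2,3,4,5 map to 1,0,0,1,2,3,3,2.  Shared by all three
// spatial filters so borders never darken, which matters downstream:
// a dark border would register as spurious positive frame differences.
static inline int reflect(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// [[Rcpp::export]]
NumericMatrix median_filter_cpp(const NumericMatrix& img, int k) {
  const int nr = img.nrow(), nc = img.ncol(), r = k / 2;
  NumericMatrix out(nr, nc);
  std::vector<double> buf(k * k);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int m = 0;
      for (int dj = -r; dj <= r; ++dj) {
        const int jj = reflect(j + dj, nc);
        for (int di = -r; di <= r; ++di)
          buf[m++] = img(reflect(i + di, nr), jj);
      }
      std::nth_element(buf.begin(), buf.begin() + m / 2, buf.begin() + m);
      out(i, j) = buf[m / 2];
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix gaussian_filter_cpp(const NumericMatrix& img, int k, double sigma) {
  const int nr = img.nrow(), nc = img.ncol(), r = k / 2;
  // separable 1-D kernel, normalized
  std::vector<double> w(k);
  double s = 0.0;
  for (int d = -r; d <= r; ++d) {
    w[d + r] = std::exp(-(double)(d * d) / (2.0 * sigma * sigma));
    s += w[d + r];
  }
  for (int d = 0; d < k; ++d) w[d] /= s;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int j = 0; j < nc; ++j)         // vertical pass
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int d = -r; d <= r; ++d) acc += w[d + r] * img(reflect(i + d, nr), j);
      tmp(i, j) = acc;
    }
  for (int j = 0; j < nc; ++j)         // horizontal pass
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int d = -r; d <= r; ++d) acc += w[d + r] * tmp(i, reflect(j + d, nc));
      out(i, j) = acc;
    }
  return out;
}

// [[Rcpp::export]]
NumericMatrix bilateral_filter_cpp(const NumericMatrix& img, int k,
                                   double sigma_space, double sigma_range) {
  const int nr = img.nrow(), nc = img.ncol(), r = k / 2;
  NumericMatrix out(nr, nc);
  std::vector<double> gs(k * k);
  int m = 0;
  for (int dj = -r; dj <= r; ++dj)
    for (int di = -r; di <= r; ++di)
      gs[m++] = std::exp(-(double)(di * di + dj * dj) /
                         (2.0 * sigma_space * sigma_space));
  const double inv2sr2 = 1.0 / (2.0 * sigma_range * sigma_range);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      const double c = img(i, j);
      double num = 0.0, den = 0.0;
      m = 0;
      for (int dj = -r; dj <= r; ++dj) {
        const int jj = reflect(j + dj, nc);
        for (int di = -r; di <= r; ++di) {
          const double v = img(reflect(i + di, nr), jj);
          const double d = v - c;
          const double wgt = gs[m++] * std::exp(-d * d * inv2sr2);
          num += wgt * v;
          den += wgt;
        }
      }
      out(i, j) = num / den;
    }
  }
  return out;
}
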