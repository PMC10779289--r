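#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// 1-D lower envelope of parabolas (Felzenszwalb & Huttenlocher distance
// transform of a sampled function): out[i] = min_j f[j] + c * (i - j)^2.
// Exact, O(n), equivalent to grayscale erosion with an unbounded parabolic
// structuring element z(k) = -c k^2.
static void erode_parabola_line(const double *f, double *out, int n, double c,
                                std::vector<int> &v, std::vector<double> &z) {
  if (n == 1) { out[0] = f[0]; return; }
  int k = 0;
  v[0] = 0;
  z[0] = -INFINITY;
  z[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + c * q * q) - (f[p] + c * p * p)) / (2.0 * c * (q - p));
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    int p = v[k];
    out[q] = c * (q - p) * (double)(q - p) + f[p];
  }
}

// Separable parabolic erosion of a matrix: the paraboloid
// z(dx,dy) = -c (dx^2 + dy^2) is additively separable, so a 1-D pass along
// columns followed by one along rows gives the exact 2-D erosion.
static NumericMatrix erode2d(const NumericMatrix &img, double c) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix tmp(nr, nc), out(nr, nc);
  int m = std::max(nr, nc);
  std::vector<int> v(m);
  std::vector<double> z(m + 1);
  std::vector<double> line(m), res(m);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) line[i] = img(i, j);
    erode_parabola_line(line.data(), res.data(), nr, c, v, z);
    for (int i = 0; i < nr; ++i) tmp(i, j) = res[i];
  }
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) line[j] = tmp(i, j);
    erode_parabola_line(line.data(), res.data(), nc, c, v, z);
    for (int j = 0; j < nc; ++j) out(i, j) = res[j];
  }
  return out;
}

// [[Rcpp::export(name = ".parabola_erode")]]
NumericMatrix parabola_erode(NumericMatrix img, double curvature) {
  return erode2d(img, curvature);
}

// Grayscale opening with the paraboloid element: erosion then dilation.
// Dilation is erosion of the negated image, negated back.
// [[Rcpp::export(name = ".parabola_open")]]
NumericMatrix parabola_open(NumericMatrix img, double curvature) {
  NumericMatrix er = erode2d(img, curvature);
  int nr = er.nrow(), nc = er.ncol();
  NumericMatrix neg(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) neg(i, j) = -er(i, j);
  NumericMatrix di = erode2d(neg, curvature);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) di(i, j) = -di(i, j);
  return di;
}
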