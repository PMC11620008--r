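#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Large finite sentinel for "no feature"; grids are << 1e6 um across, so
// squared distances stay below 1e12 and never collide with it.
static const double BIG = 1e30;

// 1D squared Euclidean distance transform (lower envelope of parabolas,
// Felzenszwalb & Huttenlocher) with a physical sample spacing.
static void dt1d(std::vector<double>& f, double step) {
  const int n = (int)f.size();
  std::vector<double> d(n);
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -BIG;
  z[1] = BIG;
  for (int q = 1; q < n; ++q) {
    double xq = step * q;
    double s;
    while (true) {
      double xv = step * v[k];
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (s <= z[k] && k > 0) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = BIG;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = step * q;
    while (z[k + 1] < xq) ++k;
    double xv = step * v[k];
    d[q] = (xq - xv) * (xq - xv) + f[v[k]];
  }
  f.swap(d);
}

//' Anisotropic squared Euclidean distance transform
//'
//' For every pixel of a 2D grid, the squared physical distance (um^2) to the
//' nearest feature pixel, with independent row/column sample spacings.
//' Pixels of a grid with no feature pixels at all get \code{Inf}.
//'
//' @param feature logical matrix; \code{TRUE} marks feature pixels.
//' @param spacing_row physical spacing between rows (um).
//' @param spacing_col physical spacing between columns (um).
//' @return numeric matrix of squared distances in um^2.
//' @keywords internal
// [[Rcpp::export]]
NumericMatrix edt_sq(LogicalMatrix feature, double spacing_row, double spacing_col) {
  const int nr = feature.nrow(), nc = feature.ncol();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = feature(i, j) ? 0.0 : BIG;
  std::vector<double> buf(nr);
  // transform along rows (within each column), spacing_row
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) buf[i] = out(i, j);
    dt1d(buf, spacing_row);
    for (int i = 0; i < nr; ++i) out(i, j) = buf[i];
  }
  // then along columns (within each row), spacing_col
  buf.resize(nc);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) buf[j] = out(i, j);
    dt1d(buf, spacing_col);
    for (int j = 0; j < nc; ++j) out(i, j) = buf[j];
  }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (out(i, j) >= 1e29) out(i, j) = R_PosInf;
  return out;
}
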