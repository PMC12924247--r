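#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Brute-force Delaunay adjacency by the empty-circumsphere property.
// For the embryo frames this package handles (tens of nuclei) exhaustive
// enumeration of 4-point subsets is fast and, unlike incremental builders,
// has no incremental-insertion degeneracies to repair. For co-spherical
// inputs (e.g. lattices) every tetrahedron whose circumsphere contains no
// point strictly inside is accepted, so the edge set is the union over all
// valid triangulations.

static bool circumsphere3(const double *p0, const double *p1, const double *p2,
                          const double *p3, double *centre, double &r2,
                          double scale2) {
  double A[3][3], b[3];
  const double *pts[3] = {p1, p2, p3};
  for (int i = 0; i < 3; ++i) {
    b[i] = 0.0;
    for (int j = 0; j < 3; ++j) {
      A[i][j] = 2.0 * (pts[i][j] - p0[j]);
      b[i] += pts[i][j] * pts[i][j] - p0[j] * p0[j];
    }
  }
  // 3x3 solve with partial pivoting
  int piv[3] = {0, 1, 2};
  for (int col = 0; col < 3; ++col) {
    int best = col;
    for (int row = col + 1; row < 3; ++row)
      if (std::fabs(A[row][col]) > std::fabs(A[best][col])) best = row;
    if (best != col) {
      for (int j = 0; j < 3; ++j) std::swap(A[col][j], A[best][j]);
      std::swap(b[col], b[best]);
      std::swap(piv[col], piv[best]);
    }
    if (std::fabs(A[col][col]) < 1e-12 * scale2) return false; // degenerate
    for (int row = col + 1; row < 3; ++row) {
      double f = A[row][col] / A[col][col];
      for (int j = col; j < 3; ++j) A[row][j] -= f * A[col][j];
      b[row] -= f * b[col];
    }
  }
  for (int col = 2; col >= 0; --col) {
    double s = b[col];
    for (int j = col + 1; j < 3; ++j) s -= A[col][j] * centre[j];
    centre[col] = s / A[col][col];
  }
  r2 = 0.0;
  for (int j = 0; j < 3; ++j) {
    double d = p0[j] - centre[j];
    r2 += d * d;
  }
  return true;
}

// [[Rcpp::export(name = ".delaunay_edges_3d")]]
IntegerMatrix delaunay_edges_3d(NumericMatrix pts) {
  int n = pts.nrow();
  if (pts.ncol() != 3) stop("points must be an n x 3 matrix");
  if (n < 4) stop("need at least 4 points for a 3-D tessellation");

  std::vector<double> P(3 * n);
  double scale2 = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 3; ++j) {
      P[3 * i + j] = pts(i, j);
      scale2 = std::max(scale2, pts(i, j) * pts(i, j));
    }
  if (scale2 <= 0) scale2 = 1.0;
  double tol = 1e-9 * scale2;

  std::vector<char> adj((size_t)n * n, 0);
  double centre[3], r2;
  bool any_tet = false;
  for (int a = 0; a < n - 3; ++a)
    for (int b = a + 1; b < n - 2; ++b)
      for (int c = b + 1; c < n - 1; ++c)
        for (int d = c + 1; d < n; ++d) {
          if (!circumsphere3(&P[3 * a], &P[3 * b], &P[3 * c], &P[3 * d],
                             centre, r2, scale2))
            continue;
          bool empty = true;
          for (int q = 0; q < n && empty; ++q) {
            if (q == a || q == b || q == c || q == d) continue;
            double d2 = 0.0;
            for (int j = 0; j < 3; ++j) {
              double dd = P[3 * q + j] - centre[j];
              d2 += dd * dd;
            }
            if (d2 < r2 - tol) empty = false;
          }
          if (!empty) continue;
          any_tet = true;
          int v[4] = {a, b, c, d};
          for (int i = 0; i < 4; ++i)
            for (int j = i + 1; j < 4; ++j) {
              adj[(size_t)v[i] * n + v[j]] = 1;
              adj[(size_t)v[j] * n + v[i]] = 1;
            }
        }

  if (!any_tet) {
    // fully degenerate (coplanar/collinear): signal to the R fallback
    IntegerMatrix out(0, 2);
    out.attr("degenerate") = true;
    return out;
  }
  int m = 0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (adj[(size_t)i * n + j]) ++m;
  IntegerMatrix out(m, 2);
  int k = 0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (adj[(size_t)i * n + j]) {
        out(k, 0) = i + 1;
        out(k, 1) = j + 1;
        ++k;
      }
  return out;
}

// 2-D analogue (empty circumcircle) used as the coplanar fallback.
// [[Rcpp::export(name = ".delaunay_edges_2d")]]
IntegerMatrix delaunay_edges_2d(NumericMatrix pts) {
  int n = pts.nrow();
  if (pts.ncol() != 2) stop("points must be an n x 2 matrix");
  if (n < 3) stop("need at least 3 points for a 2-D tessellation");
  double scale2 = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 2; ++j)
      scale2 = std::max(scale2, pts(i, j) * pts(i, j));
  if (scale2 <= 0) scale2 = 1.0;
  double tol = 1e-9 * scale2;

  std::vector<char> adj((size_t)n * n, 0);
  bool any_tri = false;
  for (int a = 0; a < n - 2; ++a)
    for (int b = a + 1; b < n - 1; ++b)
      for (int c = b + 1; c < n; ++c) {
        double ax = pts(a, 0), ay = pts(a, 1);
        double bx = pts(b, 0), by = pts(b, 1);
        double cx = pts(c, 0), cy = pts(c, 1);
        double det = 2.0 * ((bx - ax) * (cy - ay) - (by - ay) * (cx - ax));
        if (std::fabs(det) < 1e-12 * scale2) continue; // collinear
        double b1 = bx * bx + by * by - ax * ax - ay * ay;
        double b2 = cx * cx + cy * cy - ax * ax - ay * ay;
        double ux = ((cy - ay) * b1 - (by - ay) * b2) / det;
        double uy = ((bx - ax) * b2 - (cx - ax) * b1) / det;
        double r2 = (ax - ux) * (ax - ux) + (ay - uy) * (ay - uy);
        bool empty = true;
        for (int q = 0; q < n && empty; ++q) {
          if (q == a || q == b || q == c) continue;
          double d2 = (pts(q, 0) - ux) * (pts(q, 0) - ux) +
                      (pts(q, 1) - uy) * (pts(q, 1) - uy);
          if (d2 < r2 - tol) empty = false;
        }
        if (!empty) continue;
        any_tri = true;
        int v[3] = {a, b, c};
        for (int i = 0; i < 3; ++i)
          for (int j = i + 1; j < 3; ++j) {
            adj[(size_t)v[i] * n + v[j]] = 1;
            adj[(size_t)v[j] * n + v[i]] = 1;
          }
      }
  if (!any_tri) {
    IntegerMatrix out(0, 2);
    out.attr("degenerate") = true;
    return out;
  }
  int m = 0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (adj[(size_t)i * n + j]) ++m;
  IntegerMatrix out(m, 2);
  int k = 0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (adj[(size_t)i * n + j]) {
        out(k, 0) = i + 1;
        out(k, 1) = j + 1;
        ++k;
      }
  return out;
}
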