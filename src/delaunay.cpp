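#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Brute-force Delaunay triangulation by the empty-circumsphere criterion.
// Intended for the moderate point counts produced by site/neighborhood atom
// selection; complexity is O(n^(d+2)) but every accepted cell is certified
// directly, which makes the construction easy to audit and to cross-check
// against an independent oracle.  Near-degenerate (cospherical/cocircular)
// configurations are reported to the caller, which resolves them by a
// deterministic symbolic perturbation and retries.

static bool circumsphere3(const double *a, const double *b, const double *c,
                          const double *d, double detTol, double *cx,
                          double *r2) {
  // Solve 2 * (p_i - a) . (x - a) = |p_i - a|^2 for x (Cramer's rule).
  double m[3][3], rhs[3];
  const double *pts[3] = {b, c, d};
  for (int i = 0; i < 3; ++i) {
    double n2 = 0.0;
    for (int j = 0; j < 3; ++j) {
      double e = pts[i][j] - a[j];
      m[i][j] = 2.0 * e;
      n2 += e * e;
    }
    rhs[i] = n2;
  }
  double det = m[0][0] * (m[1][1] * m[2][2] - m[1][2] * m[2][1]) -
               m[0][1] * (m[1][0] * m[2][2] - m[1][2] * m[2][0]) +
               m[0][2] * (m[1][0] * m[2][1] - m[1][1] * m[2][0]);
  if (std::fabs(det) < detTol) return false; // flat tetrahedron: not a cell
  double x[3];
  x[0] = (rhs[0] * (m[1][1] * m[2][2] - m[1][2] * m[2][1]) -
          m[0][1] * (rhs[1] * m[2][2] - m[1][2] * rhs[2]) +
          m[0][2] * (rhs[1] * m[2][1] - m[1][1] * rhs[2])) /
         det;
  x[1] = (m[0][0] * (rhs[1] * m[2][2] - m[1][2] * rhs[2]) -
          rhs[0] * (m[1][0] * m[2][2] - m[1][2] * m[2][0]) +
          m[0][2] * (m[1][0] * rhs[2] - rhs[1] * m[2][0])) /
         det;
  x[2] = (m[0][0] * (m[1][1] * rhs[2] - rhs[1] * m[2][1]) -
          m[0][1] * (m[1][0] * rhs[2] - rhs[1] * m[2][0]) +
          rhs[0] * (m[1][0] * m[2][1] - m[1][1] * m[2][0])) /
         det;
  *r2 = x[0] * x[0] + x[1] * x[1] + x[2] * x[2];
  for (int j = 0; j < 3; ++j) cx[j] = a[j] + x[j];
  return true;
}

static bool circumcircle2(const double *a, const double *b, const double *c,
                          double detTol, double *cx, double *r2) {
  double m[2][2], rhs[2];
  const double *pts[2] = {b, c};
  for (int i = 0; i < 2; ++i) {
    double n2 = 0.0;
    for (int j = 0; j < 2; ++j) {
      double e = pts[i][j] - a[j];
      m[i][j] = 2.0 * e;
      n2 += e * e;
    }
    rhs[i] = n2;
  }
  double det = m[0][0] * m[1][1] - m[0][1] * m[1][0];
  if (std::fabs(det) < detTol) return false;
  double x0 = (rhs[0] * m[1][1] - m[0][1] * rhs[1]) / det;
  double x1 = (m[0][0] * rhs[1] - rhs[0] * m[1][0]) / det;
  *r2 = x0 * x0 + x1 * x1;
  cx[0] = a[0] + x0;
  cx[1] = a[1] + x1;
  return true;
}

static double cloud_scale(const NumericMatrix &pts) {
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  int d = pts.ncol();
  for (int i = 0; i < pts.nrow(); ++i)
    for (int j = 0; j < d; ++j) {
      double v = pts(i, j);
      if (v < lo[j]) lo[j] = v;
      if (v > hi[j]) hi[j] = v;
    }
  double s2 = 0.0;
  for (int j = 0; j < d; ++j) s2 += (hi[j] - lo[j]) * (hi[j] - lo[j]);
  double s = std::sqrt(s2);
  return s > 0 ? s : 1.0;
}

// [[Rcpp::export(name = ".delaunay3_bf")]]
List delaunay3_bf(NumericMatrix pts) {
  int n = pts.nrow();
  double L = cloud_scale(pts);
  double detTol = 1e-12 * L * L * L;
  double band = 1e-9 * L * L;
  std::vector<int> cells;
  bool degenerate = false;
  std::vector<double> P(3 * n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 3; ++j) P[3 * i + j] = pts(i, j);
  double cx[3], r2;
  for (int a = 0; a < n - 3 && !degenerate; ++a)
    for (int b = a + 1; b < n - 2 && !degenerate; ++b)
      for (int c = b + 1; c < n - 1 && !degenerate; ++c)
        for (int d = c + 1; d < n && !degenerate; ++d) {
          if (!circumsphere3(&P[3 * a], &P[3 * b], &P[3 * c], &P[3 * d],
                             detTol, cx, &r2))
            continue;
          bool empty = true;
          for (int e = 0; e < n; ++e) {
            if (e == a || e == b || e == c || e == d) continue;
            double d2 = 0.0;
            for (int j = 0; j < 3; ++j) {
              double t = P[3 * e + j] - cx[j];
              d2 += t * t;
            }
            if (std::fabs(d2 - r2) < band) {
              degenerate = true;
              break;
            }
            if (d2 < r2) {
              empty = false;
              break;
            }
          }
          if (degenerate) break;
          if (empty) {
            cells.push_back(a + 1);
            cells.push_back(b + 1);
            cells.push_back(c + 1);
            cells.push_back(d + 1);
          }
        }
  IntegerMatrix out(cells.size() / 4, 4);
  for (int i = 0; i < out.nrow(); ++i)
    for (int j = 0; j < 4; ++j) out(i, j) = cells[4 * i + j];
  return List::create(_["cells"] = out, _["degenerate"] = degenerate);
}

// [[Rcpp::export(name = ".delaunay2_bf")]]
List delaunay2_bf(NumericMatrix pts) {
  int n = pts.nrow();
  double L = cloud_scale(pts);
  double detTol = 1e-12 * L * L;
  double band = 1e-9 * L * L;
  std::vector<int> cells;
  bool degenerate = false;
  std::vector<double> P(2 * n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 2; ++j) P[2 * i + j] = pts(i, j);
  double cx[2], r2;
  for (int a = 0; a < n - 2 && !degenerate; ++a)
    for (int b = a + 1; b < n - 1 && !degenerate; ++b)
      for (int c = b + 1; c < n && !degenerate; ++c) {
        if (!circumcircle2(&P[2 * a], &P[2 * b], &P[2 * c], detTol, cx, &r2))
          continue;
        bool empty = true;
        for (int e = 0; e < n; ++e) {
          if (e == a || e == b || e == c) continue;
          double dx = P[2 * e] - cx[0];
          double dy = P[2 * e + 1] - cx[1];
          double d2 = dx * dx + dy * dy;
          if (std::fabs(d2 - r2) < band) {
            degenerate = true;
            break;
          }
          if (d2 < r2) {
            empty = false;
            break;
          }
        }
        if (degenerate) break;
        if (empty) {
          cells.push_back(a + 1);
          cells.push_back(b + 1);
          cells.push_back(c + 1);
        }
      }
  IntegerMatrix out(cells.size() / 3, 3);
  for (int i = 0; i < out.nrow(); ++i)
    for (int j = 0; j < 3; ++j) out(i, j) = cells[3 * i + j];
  return List::create(_["cells"] = out, _["degenerate"] = degenerate);
}
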