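#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Banded linear solve, kl = ku = 2 (pentadiagonal), Gaussian elimination with
// partial pivoting confined to the band. Row-major band storage built by the
// caller. Used by the asPLS iteration below.
// ---------------------------------------------------------------------------
static void solve_penta(std::vector<double> &band, std::vector<double> &rhs, int n) {
  // band[i*5 + (j - i + 2)] holds A(i, j) for |i - j| <= 2
  const int kl = 2, ku = 2, w = kl + ku + 1;
  // forward elimination without pivoting: the asPLS system W + lam*a*D'D is
  // strictly diagonally dominant for w > 0, so this is stable
  for (int k = 0; k < n - 1; ++k) {
    double piv = band[(size_t)k * w + ku];
    for (int i = k + 1; i <= std::min(k + kl, n - 1); ++i) {
      int off = i - k; // 1 or 2
      double m = band[(size_t)i * w + ku - off] / piv;
      if (m == 0.0) continue;
      band[(size_t)i * w + ku - off] = 0.0;
      for (int j = k + 1; j <= std::min(k + ku, n - 1); ++j) {
        band[(size_t)i * w + ku + j - i] -= m * band[(size_t)k * w + ku + j - k];
      }
      rhs[i] -= m * rhs[k];
    }
  }
  // back substitution
  for (int i = n - 1; i >= 0; --i) {
    double s = rhs[i];
    for (int j = i + 1; j <= std::min(i + ku, n - 1); ++j)
      s -= band[(size_t)i * w + ku + j - i] * rhs[j];
    rhs[i] = s / band[(size_t)i * w + ku];
  }
}

// Build the banded matrix W + lam * diag(alpha) * D2'D2 where D2 is the
// (n-2) x n second-difference operator. D2'D2 row i has entries
// [1, -4, 6, -4, 1] in the interior with boundary corrections.
static inline double dtd_entry(int i, int j, int n) {
  int d = j - i;
  if (d < 0) { int t = i; i = j; j = t; d = -d; }
  if (d == 2) return 1.0;
  if (d == 1) {
    if (i == 0 || i == n - 2) return -2.0;
    return -4.0;
  }
  // diagonal
  if (i == 0 || i == n - 1) return 1.0;
  if (i == 1 || i == n - 2) return 5.0;
  return 6.0;
}

// [[Rcpp::export]]
List cpp_aspls(NumericVector y, double lambda, int max_iter, double tol) {
  int n = y.size();
  const int w = 5, ku = 2;
  std::vector<double> z(n, 0.0), wt(n, 1.0), wt_old(n, 1.0), alpha(n, 1.0);
  std::vector<double> band((size_t)n * w), rhs(n);
  bool converged = false;
  int iter = 0;
  for (iter = 1; iter <= max_iter; ++iter) {
    // assemble and solve (W + lam * A * D'D) z = W y
    for (int i = 0; i < n; ++i) {
      for (int j = std::max(0, i - 2); j <= std::min(n - 1, i + 2); ++j) {
        double v = lambda * alpha[i] * dtd_entry(i, j, n);
        if (i == j) v += wt[i];
        band[(size_t)i * w + ku + j - i] = v;
      }
      if (i < 2) for (int j = i - 2; j < 0; ++j) band[(size_t)i * w + ku + j - i] = 0.0;
      if (i > n - 3) for (int j = n; j <= i + 2; ++j) band[(size_t)i * w + ku + j - i] = 0.0;
      rhs[i] = wt[i] * y[i];
    }
    solve_penta(band, rhs, n);
    for (int i = 0; i < n; ++i) z[i] = rhs[i];
    // residuals, sigma from negative residuals, logistic weights
    double ssq = 0.0; int nneg = 0; double maxad = 0.0;
    for (int i = 0; i < n; ++i) {
      double d = y[i] - z[i];
      if (d < 0) { ssq += d * d; ++nneg; }
      double ad = std::fabs(d);
      if (ad > maxad) maxad = ad;
    }
    double sigma = (nneg > 1) ? std::sqrt(ssq / nneg) : 1e-12;
    if (sigma <= 0) sigma = 1e-12;
    double num = 0.0, den = 0.0;
    for (int i = 0; i < n; ++i) {
      double d = y[i] - z[i];
      double wi = 1.0 / (1.0 + std::exp(2.0 * d / sigma));
      num += (wi - wt_old[i]) * (wi - wt_old[i]);
      den += wt_old[i] * wt_old[i];
      wt[i] = wi;
      alpha[i] = (maxad > 0) ? std::fabs(d) / maxad : 1.0;
    }
    if (den > 0 && std::sqrt(num / den) < tol) { converged = true; break; }
    wt_old = wt;
  }
  return List::create(_["baseline"] = NumericVector(z.begin(), z.end()),
                      _["iterations"] = std::min(iter, max_iter),
                      _["converged"] = converged);
}

// ---------------------------------------------------------------------------
// Isosurface area by marching tetrahedra: each voxel cell is split into six
// tetrahedra; the level crossing inside a tetrahedron is a triangle or a
// quad found by linear interpolation along edges. No case table required.
// ---------------------------------------------------------------------------
static inline void edge_point(const double p1[3], const double p2[3], double v1,
                              double v2, double level, double out[3]) {
  double t = (level - v1) / (v2 - v1);
  for (int i = 0; i < 3; ++i) out[i] = p1[i] + t * (p2[i] - p1[i]);
}

static inline double tri_area(const double a[3], const double b[3], const double c[3]) {
  double u[3], v[3];
  for (int i = 0; i < 3; ++i) { u[i] = b[i] - a[i]; v[i] = c[i] - a[i]; }
  double cx = u[1] * v[2] - u[2] * v[1];
  double cy = u[2] * v[0] - u[0] * v[2];
  double cz = u[0] * v[1] - u[1] * v[0];
  return 0.5 * std::sqrt(cx * cx + cy * cy + cz * cz);
}

// [[Rcpp::export]]
double cpp_mt_area(NumericVector field, IntegerVector dims, NumericVector voxel,
                   double level) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  double dx = voxel[0], dy = voxel[1], dz = voxel[2];
  const double *f = REAL(field);
  static const int off[8][3] = {{0,0,0},{1,0,0},{1,1,0},{0,1,0},
                                {0,0,1},{1,0,1},{1,1,1},{0,1,1}};
  static const int tets[6][4] = {{0,5,1,6},{0,1,2,6},{0,2,3,6},
                                 {0,3,7,6},{0,7,4,6},{0,4,5,6}};
  double total = 0.0;
  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        double vv[8]; double pp[8][3];
        bool any_hi = false, any_lo = false;
        for (int v = 0; v < 8; ++v) {
          int ii = i + off[v][0], jj = j + off[v][1], kk = k + off[v][2];
          vv[v] = f[ii + (size_t)nx * (jj + (size_t)ny * kk)];
          pp[v][0] = ii * dx; pp[v][1] = jj * dy; pp[v][2] = kk * dz;
          if (vv[v] > level) any_hi = true; else any_lo = true;
        }
        if (!any_hi || !any_lo) continue;
        for (int t = 0; t < 6; ++t) {
          const int *tv = tets[t];
          int hi[4], lo[4], nh = 0, nl = 0;
          for (int v = 0; v < 4; ++v) {
            if (vv[tv[v]] > level) hi[nh++] = tv[v]; else lo[nl++] = tv[v];
          }
          if (nh == 0 || nh == 4) continue;
          double p[4][3];
          if (nh == 1 || nh == 3) {
            int apex = (nh == 1) ? hi[0] : lo[0];
            const int *base = (nh == 1) ? lo : hi;
            for (int v = 0; v < 3; ++v)
              edge_point(pp[apex], pp[base[v]], vv[apex], vv[base[v]], level, p[v]);
            total += tri_area(p[0], p[1], p[2]);
          } else {
            edge_point(pp[hi[0]], pp[lo[0]], vv[hi[0]], vv[lo[0]], level, p[0]);
            edge_point(pp[hi[0]], pp[lo[1]], vv[hi[0]], vv[lo[1]], level, p[1]);
            edge_point(pp[hi[1]], pp[lo[1]], vv[hi[1]], vv[lo[1]], level, p[2]);
            edge_point(pp[hi[1]], pp[lo[0]], vv[hi[1]], vv[lo[0]], level, p[3]);
            total += tri_area(p[0], p[1], p[2]) + tri_area(p[0], p[2], p[3]);
          }
        }
      }
  return total;
}

// ---------------------------------------------------------------------------
// Connected-component labelling on a 2D (8-connectivity) or 3D
// (26-connectivity) logical array by iterative flood fill.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims) {
  int nd = dims.size();
  int nx = dims[0], ny = dims[1], nz = (nd == 3) ? dims[2] : 1;
  size_t n = (size_t)nx * ny * nz;
  IntegerVector labels(n, 0);
  const int *m = LOGICAL(mask);
  int next_label = 0;
  std::vector<size_t> stack;
  for (size_t s = 0; s < n; ++s) {
    if (!m[s] || labels[s] != 0) continue;
    ++next_label;
    stack.push_back(s);
    labels[s] = next_label;
    while (!stack.empty()) {
      size_t cur = stack.back(); stack.pop_back();
      int i = cur % nx, j = (cur / nx) % ny, k = cur / ((size_t)nx * ny);
      for (int dk = -1; dk <= 1; ++dk) {
        int kk = k + dk;
        if (kk < 0 || kk >= nz) continue;
        for (int dj = -1; dj <= 1; ++dj) {
          int jj = j + dj;
          if (jj < 0 || jj >= ny) continue;
          for (int di = -1; di <= 1; ++di) {
            int ii = i + di;
            if (ii < 0 || ii >= nx) continue;
            if (di == 0 && dj == 0 && dk == 0) continue;
            size_t idx = ii + (size_t)nx * (jj + (size_t)ny * kk);
            if (m[idx] && labels[idx] == 0) {
              labels[idx] = next_label;
              stack.push_back(idx);
            }
          }
        }
      }
    }
  }
  labels.attr("dim") = dims;
  return labels;
}
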