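#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

static inline size_t IDX(int i, int j, int k, int nx, int ny) {
  return (size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * (size_t)k);
}

// Trilinear sample at continuous 0-based voxel coordinates; NaN when outside.
static inline double trisample(const double* v, int nx, int ny, int nz,
                               double x, double y, double z) {
  if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1)
    return std::numeric_limits<double>::quiet_NaN();
  int i0 = (int)std::floor(x); if (i0 > nx - 2) i0 = nx > 1 ? nx - 2 : 0;
  int j0 = (int)std::floor(y); if (j0 > ny - 2) j0 = ny > 1 ? ny - 2 : 0;
  int k0 = (int)std::floor(z); if (k0 > nz - 2) k0 = nz > 1 ? nz - 2 : 0;
  double fx = nx > 1 ? x - i0 : 0.0;
  double fy = ny > 1 ? y - j0 : 0.0;
  double fz = nz > 1 ? z - k0 : 0.0;
  int i1 = nx > 1 ? i0 + 1 : i0;
  int j1 = ny > 1 ? j0 + 1 : j0;
  int k1 = nz > 1 ? k0 + 1 : k0;
  double c000 = v[IDX(i0, j0, k0, nx, ny)], c100 = v[IDX(i1, j0, k0, nx, ny)];
  double c010 = v[IDX(i0, j1, k0, nx, ny)], c110 = v[IDX(i1, j1, k0, nx, ny)];
  double c001 = v[IDX(i0, j0, k1, nx, ny)], c101 = v[IDX(i1, j0, k1, nx, ny)];
  double c011 = v[IDX(i0, j1, k1, nx, ny)], c111 = v[IDX(i1, j1, k1, nx, ny)];
  double c00 = c000 * (1 - fx) + c100 * fx;
  double c10 = c010 * (1 - fx) + c110 * fx;
  double c01 = c001 * (1 - fx) + c101 * fx;
  double c11 = c011 * (1 - fx) + c111 * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// order: 0 = nearest, 1 = trilinear. pts are 0-based continuous voxel indices.
// [[Rcpp::export]]
NumericVector interp3_cpp(NumericVector vals, IntegerVector dim, NumericMatrix pts,
                          int order, double fill) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  const double* v = REAL(vals);
  R_xlen_t n = pts.nrow();
  NumericVector out(n);
  for (R_xlen_t p = 0; p < n; p++) {
    double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    if (ISNAN(x) || ISNAN(y) || ISNAN(z)) { out[p] = fill; continue; }
    if (order == 0) {
      long i = std::lround(x), j = std::lround(y), k = std::lround(z);
      if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) { out[p] = fill; continue; }
      out[p] = v[IDX((int)i, (int)j, (int)k, nx, ny)];
    } else {
      double s = trisample(v, nx, ny, nz, x, y, z);
      out[p] = ISNAN(s) ? fill : s;
    }
  }
  return out;
}

// Exact Siddon-style radiological path length from one source to many targets.
// Coordinates are continuous 0-based voxel indices (voxel i spans [i-.5, i+.5)),
// spacing gives mm per index step along each axis (orthonormal direction
// assumed: handled by the caller).  Density is piecewise constant per voxel.
// Returns g/cm^2 given density in g/cm^3.
// [[Rcpp::export]]
NumericVector ray_depth_cpp(NumericVector dens, IntegerVector dim, NumericVector spacing,
                            NumericVector src, NumericMatrix tgt) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int nn[3] = {nx, ny, nz};
  const double* dv = REAL(dens);
  double sp[3] = {spacing[0], spacing[1], spacing[2]};
  double s[3] = {src[0], src[1], src[2]};
  R_xlen_t n = tgt.nrow();
  NumericVector out(n);
  for (R_xlen_t p = 0; p < n; p++) {
    double d[3] = {tgt(p, 0) - s[0], tgt(p, 1) - s[1], tgt(p, 2) - s[2]};
    double L = std::sqrt(d[0] * sp[0] * d[0] * sp[0] + d[1] * sp[1] * d[1] * sp[1] +
                         d[2] * sp[2] * d[2] * sp[2]);
    if (L <= 0) { out[p] = 0.0; continue; }
    // clip t in [0,1] to the grid box [-0.5, n-0.5] per axis
    double t0 = 0.0, t1 = 1.0;
    bool empty = false;
    for (int a = 0; a < 3; a++) {
      double lo = -0.5, hi = nn[a] - 0.5;
      if (d[a] == 0.0) {
        if (s[a] < lo || s[a] > hi) { empty = true; break; }
      } else {
        double ta = (lo - s[a]) / d[a], tb = (hi - s[a]) / d[a];
        if (ta > tb) { double tmp = ta; ta = tb; tb = tmp; }
        if (ta > t0) t0 = ta;
        if (tb < t1) t1 = tb;
      }
    }
    if (empty || t1 <= t0) { out[p] = 0.0; continue; }
    double acc = 0.0;
    double t = t0;
    int guard = 2 * (nx + ny + nz) + 8;
    while (t < t1 && guard-- > 0) {
      // next boundary crossing after t
      double tn = t1;
      for (int a = 0; a < 3; a++) {
        if (d[a] == 0.0) continue;
        double pos = s[a] + t * d[a];
        double face;
        if (d[a] > 0) {
          face = std::floor(pos + 0.5) + 0.5;
          double ta = (face - s[a]) / d[a];
          if (ta <= t + 1e-12) ta += 1.0 / d[a];
          if (ta < tn) tn = ta;
        } else {
          face = std::ceil(pos - 0.5) - 0.5;
          double ta = (face - s[a]) / d[a];
          if (ta <= t + 1e-12) ta += 1.0 / (-d[a]);
          if (ta < tn) tn = ta;
        }
      }
      if (tn > t1) tn = t1;
      double tm = 0.5 * (t + tn);
      long i = std::lround(s[0] + tm * d[0]);
      long j = std::lround(s[1] + tm * d[1]);
      long k = std::lround(s[2] + tm * d[2]);
      if (i >= 0 && j >= 0 && k >= 0 && i < nx && j < ny && k < nz)
        acc += dv[IDX((int)i, (int)j, (int)k, nx, ny)] * (tn - t) * L;
      t = tn;
    }
    out[p] = acc / 10.0; // mm -> cm
  }
  return out;
}

// Trilinear value plus exact in-cell gradient (per index unit) at continuous
// coordinates; outside the grid: value = fill, gradient = 0.
// [[Rcpp::export]]
NumericMatrix interp3_vg_cpp(NumericVector vals, IntegerVector dim, NumericMatrix pts,
                             double fill) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  const double* v = REAL(vals);
  R_xlen_t n = pts.nrow();
  NumericMatrix out(n, 4);
  for (R_xlen_t p = 0; p < n; p++) {
    double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    if (ISNAN(x) || ISNAN(y) || ISNAN(z) ||
        x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) {
      out(p, 0) = fill; out(p, 1) = 0; out(p, 2) = 0; out(p, 3) = 0;
      continue;
    }
    int i0 = (int)std::floor(x); if (i0 > nx - 2) i0 = nx > 1 ? nx - 2 : 0;
    int j0 = (int)std::floor(y); if (j0 > ny - 2) j0 = ny > 1 ? ny - 2 : 0;
    int k0 = (int)std::floor(z); if (k0 > nz - 2) k0 = nz > 1 ? nz - 2 : 0;
    double fx = nx > 1 ? x - i0 : 0.0;
    double fy = ny > 1 ? y - j0 : 0.0;
    double fz = nz > 1 ? z - k0 : 0.0;
    int i1 = nx > 1 ? i0 + 1 : i0;
    int j1 = ny > 1 ? j0 + 1 : j0;
    int k1 = nz > 1 ? k0 + 1 : k0;
    double c000 = v[IDX(i0, j0, k0, nx, ny)], c100 = v[IDX(i1, j0, k0, nx, ny)];
    double c010 = v[IDX(i0, j1, k0, nx, ny)], c110 = v[IDX(i1, j1, k0, nx, ny)];
    double c001 = v[IDX(i0, j0, k1, nx, ny)], c101 = v[IDX(i1, j0, k1, nx, ny)];
    double c011 = v[IDX(i0, j1, k1, nx, ny)], c111 = v[IDX(i1, j1, k1, nx, ny)];
    double c00 = c000 * (1 - fx) + c100 * fx;
    double c10 = c010 * (1 - fx) + c110 * fx;
    double c01 = c001 * (1 - fx) + c101 * fx;
    double c11 = c011 * (1 - fx) + c111 * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    out(p, 0) = c0 * (1 - fz) + c1 * fz;
    // d/dx
    double d00 = c100 - c000, d10 = c110 - c010, d01 = c101 - c001, d11 = c111 - c011;
    out(p, 1) = ((d00 * (1 - fy) + d10 * fy) * (1 - fz) +
                 (d01 * (1 - fy) + d11 * fy) * fz);
    // d/dy
    out(p, 2) = (c10 - c00) * (1 - fz) + (c11 - c01) * fz;
    // d/dz
    out(p, 3) = c1 - c0;
  }
  return out;
}

// Cubic B-spline weights for control offsets {-1,0,1,2} at local fraction t.
static inline void bsw(double t, double* w) {
  double t2 = t * t, t3 = t2 * t;
  w[0] = (1 - 3 * t + 3 * t2 - t3) / 6.0;
  w[1] = (4 - 6 * t2 + 3 * t3) / 6.0;
  w[2] = (1 + 3 * t + 3 * t2 - 3 * t3) / 6.0;
  w[3] = t3 / 6.0;
}

// coef: array (n1,n2,n3,3); pts: N x 3 continuous control-lattice coordinates.
// Controls outside the lattice contribute zero displacement.
// [[Rcpp::export]]
NumericMatrix bspline_eval_cpp(NumericVector coef, IntegerVector cdim, NumericMatrix pts) {
  int n1 = cdim[0], n2 = cdim[1], n3 = cdim[2];
  size_t plane = (size_t)n1 * n2 * n3;
  const double* c = REAL(coef);
  R_xlen_t n = pts.nrow();
  NumericMatrix out(n, 3);
  double wx[4], wy[4], wz[4];
  for (R_xlen_t p = 0; p < n; p++) {
    double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
    bsw(x - i0, wx); bsw(y - j0, wy); bsw(z - k0, wz);
    double acc0 = 0, acc1 = 0, acc2 = 0;
    for (int ck = 0; ck < 4; ck++) {
      int kk = k0 - 1 + ck;
      if (kk < 0 || kk >= n3) continue;
      for (int cj = 0; cj < 4; cj++) {
        int jj = j0 - 1 + cj;
        if (jj < 0 || jj >= n2) continue;
        double wyz = wy[cj] * wz[ck];
        for (int ci = 0; ci < 4; ci++) {
          int ii = i0 - 1 + ci;
          if (ii < 0 || ii >= n1) continue;
          double w = wx[ci] * wyz;
          size_t b = IDX(ii, jj, kk, n1, n2);
          acc0 += w * c[b];
          acc1 += w * c[b + plane];
          acc2 += w * c[b + 2 * plane];
        }
      }
    }
    out(p, 0) = acc0; out(p, 1) = acc1; out(p, 2) = acc2;
  }
  return out;
}

// Adjoint of bspline_eval: scatter per-point weights (N x 3) onto the control
// lattice; returns array (n1,n2,n3,3) of objective gradients.
// [[Rcpp::export]]
NumericVector bspline_adjoint_cpp(IntegerVector cdim, NumericMatrix pts, NumericMatrix wts) {
  int n1 = cdim[0], n2 = cdim[1], n3 = cdim[2];
  size_t plane = (size_t)n1 * n2 * n3;
  NumericVector out(plane * 3);
  double* o = REAL(out);
  R_xlen_t n = pts.nrow();
  double wx[4], wy[4], wz[4];
  for (R_xlen_t p = 0; p < n; p++) {
    double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    double g0 = wts(p, 0), g1 = wts(p, 1), g2 = wts(p, 2);
    if (g0 == 0 && g1 == 0 && g2 == 0) continue;
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
    bsw(x - i0, wx); bsw(y - j0, wy); bsw(z - k0, wz);
    for (int ck = 0; ck < 4; ck++) {
      int kk = k0 - 1 + ck;
      if (kk < 0 || kk >= n3) continue;
      for (int cj = 0; cj < 4; cj++) {
        int jj = j0 - 1 + cj;
        if (jj < 0 || jj >= n2) continue;
        double wyz = wy[cj] * wz[ck];
        for (int ci = 0; ci < 4; ci++) {
          int ii = i0 - 1 + ci;
          if (ii < 0 || ii >= n1) continue;
          double w = wx[ci] * wyz;
          size_t b = IDX(ii, jj, kk, n1, n2);
          o[b] += w * g0;
          o[b + plane] += w * g1;
          o[b + 2 * plane] += w * g2;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(n1, n2, n3, 3);
  return out;
}

// 1D squared-distance transform (Felzenszwalb lower envelope), physical step.
static void dt1d(std::vector<double>& f, std::vector<double>& dout, int n, double step) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; q++) {
    double xq = q * step;
    double s;
    while (true) {
      double xv = v[k] * step;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
      if (s <= z[k]) k--; else break;
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    double xq = q * step;
    while (z[k + 1] < xq) k++;
    double dq = xq - v[k] * step;
    dout[q] = dq * dq + f[v[k]];
  }
}

// Squared Euclidean distance (mm^2) to the nearest TRUE voxel center.
// [[Rcpp::export]]
NumericVector edt_sq_cpp(LogicalVector mask, IntegerVector dim, NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t nt = (size_t)nx * ny * nz;
  // large finite sentinel: infinite parabolas break the lower envelope
  const double INF = 1e20;
  NumericVector out(nt);
  double* f = REAL(out);
  for (size_t i = 0; i < nt; i++) f[i] = mask[i] ? 0.0 : INF;
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> line(nmax), dl(nmax);
  // pass along x
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++) {
      size_t b = IDX(0, j, k, nx, ny);
      bool any = false;
      for (int i = 0; i < nx; i++) { line[i] = f[b + i]; if (line[i] < 1e19) any = true; }
      if (!any) continue;
      dt1d(line, dl, nx, spacing[0]);
      for (int i = 0; i < nx; i++) f[b + i] = dl[i];
    }
  // pass along y
  for (int k = 0; k < nz; k++)
    for (int i = 0; i < nx; i++) {
      bool any = false;
      for (int j = 0; j < ny; j++) { line[j] = f[IDX(i, j, k, nx, ny)]; if (line[j] < 1e19) any = true; }
      if (!any) continue;
      dt1d(line, dl, ny, spacing[1]);
      for (int j = 0; j < ny; j++) f[IDX(i, j, k, nx, ny)] = dl[j];
    }
  // pass along z
  for (int j = 0; j < ny; j++)
    for (int i = 0; i < nx; i++) {
      bool any = false;
      for (int k = 0; k < nz; k++) { line[k] = f[IDX(i, j, k, nx, ny)]; if (line[k] < 1e19) any = true; }
      if (!any) continue;
      dt1d(line, dl, nz, spacing[2]);
      for (int k = 0; k < nz; k++) f[IDX(i, j, k, nx, ny)] = dl[k];
    }
  return out;
}

// 3D gamma index (global normalization). ref/ev share one grid. Offsets are
// index-space displacements sorted by physical radius; off_rr = (r/dta)^2.
// The distance-sorted early break makes the search exact within the offset set.
// [[Rcpp::export]]
List gamma_cpp(NumericVector ref, NumericVector ev, IntegerVector dim,
               NumericMatrix off_idx, NumericVector off_rr,
               double tol_abs, double thresh_abs) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t nt = (size_t)nx * ny * nz;
  const double* rv = REAL(ref);
  const double* evv = REAL(ev);
  R_xlen_t noff = off_idx.nrow();
  NumericVector gam(nt, NA_REAL);
  size_t nev = 0, npass = 0;
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        size_t v = IDX(i, j, k, nx, ny);
        double r0 = rv[v];
        if (!(r0 >= thresh_abs)) continue;
        nev++;
        double best2 = std::numeric_limits<double>::infinity();
        for (R_xlen_t q = 0; q < noff; q++) {
          double rr = off_rr[q];
          if (rr >= best2) break;
          double e = trisample(evv, nx, ny, nz,
                               i + off_idx(q, 0), j + off_idx(q, 1), k + off_idx(q, 2));
          if (ISNAN(e)) continue;
          double dd = (e - r0) / tol_abs;
          double g2 = dd * dd + rr;
          if (g2 < best2) best2 = g2;
        }
        gam[v] = std::sqrt(best2);
        if (best2 <= 1.0) npass++;
      }
  gam.attr("dim") = dim;
  return List::create(_["gamma"] = gam,
                      _["n_evaluable"] = (double)nev,
                      _["n_pass"] = (double)npass);
}

// Block-mean downsampling by integer factor (partial edge blocks averaged).
// [[Rcpp::export]]
NumericVector block_mean_cpp(NumericVector vals, IntegerVector dim, int f) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int ox = (nx + f - 1) / f, oy = (ny + f - 1) / f, oz = (nz + f - 1) / f;
  NumericVector out((size_t)ox * oy * oz);
  const double* v = REAL(vals);
  double* o = REAL(out);
  std::vector<double> cnt((size_t)ox * oy * oz, 0.0);
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        size_t t = IDX(i / f, j / f, k / f, ox, oy);
        o[t] += v[IDX(i, j, k, nx, ny)];
        cnt[t] += 1.0;
      }
  for (size_t t = 0; t < (size_t)ox * oy * oz; t++) o[t] /= cnt[t];
  out.attr("dim") = IntegerVector::create(ox, oy, oz);
  return out;
}

// Separable box smoothing, window half-width hw (edge-truncated).
// [[Rcpp::export]]
NumericVector smooth3_cpp(NumericVector vals, IntegerVector dim, int hw) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t nt = (size_t)nx * ny * nz;
  NumericVector out(clone(vals));
  std::vector<double> buf(std::max(nx, std::max(ny, nz)));
  double* v = REAL(out);
  for (int pass = 0; pass < 3; pass++) {
    int n = pass == 0 ? nx : (pass == 1 ? ny : nz);
    size_t stride = pass == 0 ? 1 : (pass == 1 ? (size_t)nx : (size_t)nx * ny);
    size_t nlines = nt / n;
    for (size_t l = 0; l < nlines; l++) {
      // base index of line l for this axis
      size_t b;
      if (pass == 0) b = l * (size_t)nx;
      else if (pass == 1) { size_t i = l % nx, k = l / nx; b = i + (size_t)nx * ny * k; }
      else b = l;
      for (int q = 0; q < n; q++) buf[q] = v[b + stride * q];
      for (int q = 0; q < n; q++) {
        int lo = q - hw < 0 ? 0 : q - hw;
        int hi = q + hw >= n ? n - 1 : q + hw;
        double s = 0;
        for (int u = lo; u <= hi; u++) s += buf[u];
        v[b + stride * q] = s / (hi - lo + 1);
      }
    }
  }
  return out;
}
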