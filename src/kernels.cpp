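#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// Trilinear sampling of a 3D volume at continuous voxel coordinates
// (1-based, voxel-centre convention). Samples falling outside the volume
// return `fill` and are counted, so truncation is never silent.
// [[Rcpp::export]]
List cpp_trilinear(NumericVector vol, IntegerVector dim,
                   NumericVector xi, NumericVector yi, NumericVector zi,
                   double fill = 0.0, bool clamp = false) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = xi.size();
  NumericVector out(n);
  LogicalVector oob(n);
  R_xlen_t n_out = 0;
  const double *v = vol.begin();
  for (R_xlen_t p = 0; p < n; ++p) {
    double x = xi[p] - 1.0, y = yi[p] - 1.0, z = zi[p] - 1.0; // 0-based
    if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) {
      oob[p] = true; ++n_out;
      if (!clamp) { out[p] = fill; continue; }
      if (x < 0) x = 0; else if (x > nx - 1) x = nx - 1;
      if (y < 0) y = 0; else if (y > ny - 1) y = ny - 1;
      if (z < 0) z = 0; else if (z > nz - 1) z = nz - 1;
    }
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
    if (x0 == nx - 1) --x0;
    if (y0 == ny - 1) --y0;
    if (z0 == nz - 1) --z0;
    if (x0 < 0) x0 = 0;
    if (y0 < 0) y0 = 0;
    if (z0 < 0) z0 = 0;
    double fx = x - x0, fy = y - y0, fz = z - z0;
    const R_xlen_t sxy = (R_xlen_t)nx * ny;
    R_xlen_t i000 = x0 + (R_xlen_t)nx * y0 + sxy * z0;
    double c00 = v[i000] * (1 - fx) + v[i000 + 1] * fx;
    double c10 = v[i000 + nx] * (1 - fx) + v[i000 + nx + 1] * fx;
    double c01 = v[i000 + sxy] * (1 - fx) + v[i000 + sxy + 1] * fx;
    double c11 = v[i000 + sxy + nx] * (1 - fx) + v[i000 + sxy + nx + 1] * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    out[p] = c0 * (1 - fz) + c1 * fz;
  }
  return List::create(_["values"] = out, _["oob"] = oob,
                      _["n_out"] = (double)n_out);
}

static inline void bspline_w(double u, double w[4]) {
  const double u2 = u * u, u3 = u2 * u;
  w[0] = (1 - 3 * u + 3 * u2 - u3) / 6.0;
  w[1] = (4 - 6 * u2 + 3 * u3) / 6.0;
  w[2] = (1 + 3 * u + 3 * u2 - 3 * u3) / 6.0;
  w[3] = u3 / 6.0;
}

// Dense evaluation of a cubic B-spline free-form deformation.
// coef: (ncx*ncy*ncz) x 3 coefficient matrix (mm); control point j sits at
// corigin + j*cspacing (world mm, 0-based j). Points outside the well-
// supported lattice region are clamped to the nearest supported cell.
// [[Rcpp::export]]
NumericMatrix cpp_ffd_eval(NumericMatrix coef, IntegerVector cdim,
                           NumericVector corigin, NumericVector cspacing,
                           NumericMatrix pts) {
  const int ncx = cdim[0], ncy = cdim[1], ncz = cdim[2];
  const R_xlen_t n = pts.nrow();
  NumericMatrix out(n, 3);
  const double *cf = coef.begin();
  const R_xlen_t ncxy = (R_xlen_t)ncx * ncy, ntot = ncxy * ncz;
  double wx[4], wy[4], wz[4];
  for (R_xlen_t p = 0; p < n; ++p) {
    double tx = (pts(p, 0) - corigin[0]) / cspacing[0];
    double ty = (pts(p, 1) - corigin[1]) / cspacing[1];
    double tz = (pts(p, 2) - corigin[2]) / cspacing[2];
    int ix = (int)std::floor(tx), iy = (int)std::floor(ty), iz = (int)std::floor(tz);
    if (ix < 1) { ix = 1; tx = 1; } if (ix > ncx - 3) { ix = ncx - 3; tx = ix + 1; }
    if (iy < 1) { iy = 1; ty = 1; } if (iy > ncy - 3) { iy = ncy - 3; ty = iy + 1; }
    if (iz < 1) { iz = 1; tz = 1; } if (iz > ncz - 3) { iz = ncz - 3; tz = iz + 1; }
    bspline_w(tx - ix, wx); bspline_w(ty - iy, wy); bspline_w(tz - iz, wz);
    double acc0 = 0, acc1 = 0, acc2 = 0;
    for (int c = 0; c < 4; ++c) {
      for (int b = 0; b < 4; ++b) {
        const double wyz = wy[b] * wz[c];
        R_xlen_t base = (R_xlen_t)(ix - 1) + (R_xlen_t)ncx * (iy - 1 + b) +
          ncxy * (iz - 1 + c);
        for (int a = 0; a < 4; ++a) {
          const double w = wx[a] * wyz;
          R_xlen_t idx = base + a;
          acc0 += w * cf[idx];
          acc1 += w * cf[idx + ntot];
          acc2 += w * cf[idx + 2 * ntot];
        }
      }
    }
    out(p, 0) = acc0; out(p, 1) = acc1; out(p, 2) = acc2;
  }
  return out;
}

// Adjoint of cpp_ffd_eval: scatter per-point 3-vectors (e.g. residual times
// image gradient) back onto the control lattice.
// [[Rcpp::export]]
NumericMatrix cpp_ffd_backproject(NumericMatrix g, IntegerVector cdim,
                                  NumericVector corigin, NumericVector cspacing,
                                  NumericMatrix pts) {
  const int ncx = cdim[0], ncy = cdim[1], ncz = cdim[2];
  const R_xlen_t n = pts.nrow();
  const R_xlen_t ncxy = (R_xlen_t)ncx * ncy, ntot = ncxy * ncz;
  NumericMatrix out(ntot, 3);
  double *o = out.begin();
  double wx[4], wy[4], wz[4];
  for (R_xlen_t p = 0; p < n; ++p) {
    double tx = (pts(p, 0) - corigin[0]) / cspacing[0];
    double ty = (pts(p, 1) - corigin[1]) / cspacing[1];
    double tz = (pts(p, 2) - corigin[2]) / cspacing[2];
    int ix = (int)std::floor(tx), iy = (int)std::floor(ty), iz = (int)std::floor(tz);
    if (ix < 1) { ix = 1; tx = 1; } if (ix > ncx - 3) { ix = ncx - 3; tx = ix + 1; }
    if (iy < 1) { iy = 1; ty = 1; } if (iy > ncy - 3) { iy = ncy - 3; ty = iy + 1; }
    if (iz < 1) { iz = 1; tz = 1; } if (iz > ncz - 3) { iz = ncz - 3; tz = iz + 1; }
    bspline_w(tx - ix, wx); bspline_w(ty - iy, wy); bspline_w(tz - iz, wz);
    const double g0 = g(p, 0), g1 = g(p, 1), g2 = g(p, 2);
    for (int c = 0; c < 4; ++c) {
      for (int b = 0; b < 4; ++b) {
        const double wyz = wy[b] * wz[c];
        R_xlen_t base = (R_xlen_t)(ix - 1) + (R_xlen_t)ncx * (iy - 1 + b) +
          ncxy * (iz - 1 + c);
        for (int a = 0; a < 4; ++a) {
          const double w = wx[a] * wyz;
          R_xlen_t idx = base + a;
          o[idx] += w * g0;
          o[idx + ntot] += w * g1;
          o[idx + 2 * ntot] += w * g2;
        }
      }
    }
  }
  return out;
}

// 1D squared-distance transform (Felzenszwalb & Huttenlocher), anisotropic
// sample spacing s. f holds squared distances on input.
static void edt1d(std::vector<double> &f, std::vector<double> &d,
                  std::vector<int> &v, std::vector<double> &z,
                  int n, double s) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double xq = q * s;
    double sdist;
    while (true) {
      double xv = v[k] * s;
      sdist = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (sdist <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = sdist;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * s;
    while (z[k + 1] < xq) ++k;
    double dx = xq - v[k] * s;
    d[q] = dx * dx + f[v[k]];
  }
}

// Exact Euclidean distance (mm) from every voxel centre to the nearest
// foreground voxel centre, with per-axis spacing. Works for 2D by passing
// dim[2] = 1.
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dim,
                      NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  // large finite sentinel keeps the lower-envelope arithmetic NaN-free when a
  // scan line contains no foreground
  const double BIG = 1e20;
  std::vector<double> d(ntot);
  for (R_xlen_t i = 0; i < ntot; ++i) d[i] = mask[i] ? 0.0 : BIG;
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), dd(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  const R_xlen_t sxy = (R_xlen_t)nx * ny;
  // x pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t off = (R_xlen_t)nx * j + sxy * k;
      for (int i = 0; i < nx; ++i) f[i] = d[off + i];
      edt1d(f, dd, v, z, nx, spacing[0]);
      for (int i = 0; i < nx; ++i) d[off + i] = dd[i];
    }
  // y pass
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t off = (R_xlen_t)i + sxy * k;
      for (int j = 0; j < ny; ++j) f[j] = d[off + (R_xlen_t)nx * j];
      edt1d(f, dd, v, z, ny, spacing[1]);
      for (int j = 0; j < ny; ++j) d[off + (R_xlen_t)nx * j] = dd[j];
    }
  // z pass
  if (nz > 1)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t off = (R_xlen_t)i + (R_xlen_t)nx * j;
        for (int k = 0; k < nz; ++k) f[k] = d[off + sxy * k];
        edt1d(f, dd, v, z, nz, spacing[2]);
        for (int k = 0; k < nz; ++k) d[off + sxy * k] = dd[k];
      }
  NumericVector out(ntot);
  for (R_xlen_t i = 0; i < ntot; ++i)
    out[i] = (d[i] >= 1e19) ? R_PosInf : std::sqrt(d[i]);
  return out;
}
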