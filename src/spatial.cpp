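#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

// Numerics kernels shared by the deformation and metrics code: squared
// Euclidean distance transform (Felzenszwalb & Huttenlocher, separable,
// anisotropic spacing), trilinear / nearest-neighbour sampling of a 3D grid
// at continuous voxel coordinates, and separable Gaussian blur with
// replicate-edge padding. All grids are column-major (R array layout),
// coordinates are 1-based voxel indices as used from R.

static const double INF = std::numeric_limits<double>::infinity();

// 1D squared distance transform of sampled function f at sample spacing s.
// Parabolas with f == INF are skipped (no source on that line position).
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 int n, double s) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int q0 = 0;
  while (q0 < n && f[q0] == INF) ++q0;
  if (q0 == n) { for (int q = 0; q < n; ++q) d[q] = INF; return; }
  int k = 0;
  v[0] = q0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = q0 + 1; q < n; ++q) {
    if (f[q] == INF) continue;
    double sq = (double)q * s;
    while (true) {
      double sv = (double)v[k] * s;
      double sep = ((f[q] + sq * sq) - (f[v[k]] + sv * sv)) / (2.0 * (sq - sv));
      if (k > 0 && sep <= z[k]) { --k; continue; }
      ++k;
      v[k] = q;
      z[k] = sep;
      z[k + 1] = INF;
      break;
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double sq = (double)q * s;
    while (z[k + 1] < sq) ++k;
    double sv = (double)v[k] * s;
    d[q] = (sq - sv) * (sq - sv) + f[v[k]];
  }
}

// [[Rcpp::export(name = ".edtSquared")]]
NumericVector edt_squared(LogicalVector mask, IntegerVector dim,
                          NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? 0.0 : INF;

  std::vector<double> f, d;
  // pass along x
  f.resize(nx); d.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
      bool any = false;
      for (int x = 0; x < nx; ++x) { f[x] = out[base + x]; if (f[x] < INF) any = true; }
      if (!any) continue;
      dt1d(f, d, nx, spacing[0]);
      for (int x = 0; x < nx; ++x) out[base + x] = d[x];
    }
  // pass along y
  f.resize(ny); d.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + x;
      bool any = false;
      for (int y = 0; y < ny; ++y) { f[y] = out[base + (R_xlen_t)y * nx]; if (f[y] < INF) any = true; }
      if (!any) continue;
      dt1d(f, d, ny, spacing[1]);
      for (int y = 0; y < ny; ++y) out[base + (R_xlen_t)y * nx] = d[y];
    }
  // pass along z
  f.resize(nz); d.resize(nz);
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)y * nx + x;
      bool any = false;
      for (int z = 0; z < nz; ++z) { f[z] = out[base + (R_xlen_t)z * nxy]; if (f[z] < INF) any = true; }
      if (!any) continue;
      dt1d(f, d, nz, spacing[2]);
      for (int z = 0; z < nz; ++z) out[base + (R_xlen_t)z * nxy] = d[z];
    }
  out.attr("dim") = dim;
  return out;
}

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// pts: m x 3 matrix of 1-based continuous voxel coordinates; out-of-domain
// coordinates are clamped to the grid edge (nearest-edge sampling).
// [[Rcpp::export(name = ".sampleTrilinear")]]
NumericVector sample_trilinear(NumericVector vol, IntegerVector dim,
                               NumericMatrix pts) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  const R_xlen_t m = pts.nrow();
  NumericVector out(m);
  for (R_xlen_t i = 0; i < m; ++i) {
    double x = clampd(pts(i, 0), 1.0, (double)nx);
    double y = clampd(pts(i, 1), 1.0, (double)ny);
    double z = clampd(pts(i, 2), 1.0, (double)nz);
    int x0 = (int)std::floor(x); if (x0 >= nx) x0 = nx - 1;
    int y0 = (int)std::floor(y); if (y0 >= ny) y0 = ny - 1;
    int z0 = (int)std::floor(z); if (z0 >= nz) z0 = nz - 1;
    double fx = x - x0, fy = y - y0, fz = z - z0;
    R_xlen_t i000 = (R_xlen_t)(z0 - 1) * nxy + (R_xlen_t)(y0 - 1) * nx + (x0 - 1);
    R_xlen_t dx = 1, dy = nx, dz = nxy;
    double c00 = vol[i000] * (1 - fx) + vol[i000 + dx] * fx;
    double c10 = vol[i000 + dy] * (1 - fx) + vol[i000 + dy + dx] * fx;
    double c01 = vol[i000 + dz] * (1 - fx) + vol[i000 + dz + dx] * fx;
    double c11 = vol[i000 + dz + dy] * (1 - fx) + vol[i000 + dz + dy + dx] * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    out[i] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}

// [[Rcpp::export(name = ".sampleNearest")]]
NumericVector sample_nearest(NumericVector vol, IntegerVector dim,
                             NumericMatrix pts) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  const R_xlen_t m = pts.nrow();
  NumericVector out(m);
  for (R_xlen_t i = 0; i < m; ++i) {
    int x = (int)std::lround(clampd(pts(i, 0), 1.0, (double)nx));
    int y = (int)std::lround(clampd(pts(i, 1), 1.0, (double)ny));
    int z = (int)std::lround(clampd(pts(i, 2), 1.0, (double)nz));
    out[i] = vol[(R_xlen_t)(z - 1) * nxy + (R_xlen_t)(y - 1) * nx + (x - 1)];
  }
  return out;
}

static void blur_axis(std::vector<double>& buf, NumericVector& vol,
                      int nx, int ny, int nz, int axis, double sigma_vox) {
  if (sigma_vox <= 0) return;
  int radius = (int)std::ceil(3.0 * sigma_vox);
  std::vector<double> kern(2 * radius + 1);
  double s = 0;
  for (int i = -radius; i <= radius; ++i) {
    kern[i + radius] = std::exp(-0.5 * i * i / (sigma_vox * sigma_vox));
    s += kern[i + radius];
  }
  for (double& k : kern) k /= s;
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  int len = axis == 0 ? nx : (axis == 1 ? ny : nz);
  R_xlen_t stride = axis == 0 ? 1 : (axis == 1 ? nx : nxy);
  std::vector<double> line(len);
  int d1 = axis == 0 ? ny : nx;
  int d2 = axis == 2 ? ny : nz;
  for (int b = 0; b < d2; ++b)
    for (int a = 0; a < d1; ++a) {
      R_xlen_t base;
      if (axis == 0)      base = (R_xlen_t)b * nxy + (R_xlen_t)a * nx;
      else if (axis == 1) base = (R_xlen_t)b * nxy + a;
      else                base = (R_xlen_t)b * nx + a;
      for (int i = 0; i < len; ++i) line[i] = vol[base + (R_xlen_t)i * stride];
      for (int i = 0; i < len; ++i) {
        double acc = 0;
        for (int j = -radius; j <= radius; ++j) {
          int p = i + j;
          if (p < 0) p = 0; else if (p >= len) p = len - 1;  // replicate edge
          acc += kern[j + radius] * line[p];
        }
        vol[base + (R_xlen_t)i * stride] = acc;
      }
    }
  (void)buf;
}

// [[Rcpp::export(name = ".gaussBlur3d")]]
NumericVector gauss_blur3d(NumericVector vol, IntegerVector dim,
                           NumericVector sigma_vox) {
  NumericVector out = clone(vol);
  std::vector<double> buf;
  blur_axis(buf, out, dim[0], dim[1], dim[2], 0, sigma_vox[0]);
  blur_axis(buf, out, dim[0], dim[1], dim[2], 1, sigma_vox[1]);
  blur_axis(buf, out, dim[0], dim[1], dim[2], 2, sigma_vox[2]);
  out.attr("dim") = dim;
  return out;
}
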