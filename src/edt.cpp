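#include <Rcpp.h>
#include <vector>
#include <limits>

// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher,
// lower-envelope of parabolas), separable over the three grid dimensions.
// Distances are measured between voxel centers in voxel index units.

static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  static thread_local std::vector<int> v;
  static thread_local std::vector<double> z;
  v.assign(n, 0);
  z.assign(n + 1, 0.0);
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + q * (double)q) - (f[p] + p * (double)p)) / (2.0 * q - 2.0 * p);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export(name = ".edt3d_cpp")]]
Rcpp::NumericVector edt3d_cpp(Rcpp::LogicalVector occ, Rcpp::IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double INF = 1e30;
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  Rcpp::NumericVector out(n);
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = (occ[i] == TRUE) ? 0.0 : INF;

  std::vector<double> f, d;
  // pass along x (fastest index)
  f.resize(nx); d.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
      for (int x = 0; x < nx; ++x) f[x] = g[base + x];
      dt1d(f, d, nx);
      for (int x = 0; x < nx; ++x) g[base + x] = d[x];
    }
  // pass along y
  f.resize(ny); d.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + x;
      for (int y = 0; y < ny; ++y) f[y] = g[base + (R_xlen_t)y * nx];
      dt1d(f, d, ny);
      for (int y = 0; y < ny; ++y) g[base + (R_xlen_t)y * nx] = d[y];
    }
  // pass along z
  f.resize(nz); d.resize(nz);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)y * nx + x;
      for (int z = 0; z < nz; ++z) f[z] = g[base + (R_xlen_t)z * nx * ny];
      dt1d(f, d, nz);
      for (int z = 0; z < nz; ++z) g[base + (R_xlen_t)z * nx * ny] = d[z];
    }
  for (R_xlen_t i = 0; i < n; ++i) out[i] = g[i];
  return out;
}
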