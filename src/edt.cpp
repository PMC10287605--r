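#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

// 1D squared-distance transform (Felzenszwalb & Huttenlocher), lower
// envelope of parabolas rooted at f.
static void dt1d(const std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z, int n) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
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
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// Exact 3D squared Euclidean distance (in voxels) from each voxel to the
// nearest background (FALSE) voxel. Foreground-only masks return Inf.
// [[Rcpp::export]]
NumericVector edt_sq_cpp(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  // large finite sentinel instead of Inf: Inf-Inf in the envelope
  // intersection would poison the transform with NaN
  const double LARGE = 1e20;
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? LARGE : 0.0;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // x pass
  for (int zz = 0; zz < nz; ++zz)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = ((R_xlen_t)zz * ny + y) * nx;
      for (int x = 0; x < nx; ++x) f[x] = out[base + x];
      dt1d(f, d, v, z, nx);
      for (int x = 0; x < nx; ++x) out[base + x] = d[x];
    }
  // y pass
  for (int zz = 0; zz < nz; ++zz)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)zz * ny * nx + x;
      for (int y = 0; y < ny; ++y) f[y] = out[base + (R_xlen_t)y * nx];
      dt1d(f, d, v, z, ny);
      for (int y = 0; y < ny; ++y) out[base + (R_xlen_t)y * nx] = d[y];
    }
  // z pass
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)y * nx + x;
      for (int zz = 0; zz < nz; ++zz)
        f[zz] = out[base + (R_xlen_t)zz * ny * nx];
      dt1d(f, d, v, z, nz);
      for (int zz = 0; zz < nz; ++zz)
        out[base + (R_xlen_t)zz * ny * nx] = d[zz];
    }
  return out;
}
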