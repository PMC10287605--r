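#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Sliding-window Shannon entropy (nats) over a 3D integer-symbol array.
//
// `sym` is the quantized volume already padded by r = (k-1)/2 on every side
// when pad == true (reflect padding done by the caller); when pad == false
// the window is evaluated only where it fits and the border shell is NA.
// Each output voxel holds -sum p ln p = ln n - (1/n) sum c_j ln c_j over the
// symbol counts c_j of its k^3 neighborhood.
// [[Rcpp::export]]
NumericVector local_entropy_cpp(IntegerVector sym, IntegerVector dims_out,
                                int k, bool pad) {
  const int r = (k - 1) / 2;
  const int nx = dims_out[0], ny = dims_out[1], nz = dims_out[2];
  const int px = pad ? nx + 2 * r : nx;
  const int py = pad ? ny + 2 * r : ny;
  const int pz = pad ? nz + 2 * r : nz;
  if ((R_xlen_t)px * py * pz != sym.size())
    stop("padded array size does not match dimensions");

  NumericVector out((R_xlen_t)nx * ny * nz, NA_REAL);
  const int nwin = k * k * k;
  std::vector<int> buf(nwin);

  // p*log(p) table for counts 1..nwin; entropy accumulates these terms in
  // ascending symbol order with extended precision, matching how R's sum()
  // reduces -p*log(p) so the map is bit-identical to a per-voxel
  // kernel_entropy() loop
  std::vector<double> plogp(nwin + 1, 0.0);
  for (int c = 1; c <= nwin; ++c) {
    const double p = (double)c / (double)nwin;
    plogp[c] = p * std::log(p);
  }

  const int x0 = pad ? 0 : r, x1 = pad ? nx : nx - r;
  const int y0 = pad ? 0 : r, y1 = pad ? ny : ny - r;
  const int z0 = pad ? 0 : r, z1 = pad ? nz : nz - r;
  const int *s = INTEGER(sym);

  for (int z = z0; z < z1; ++z) {
    for (int y = y0; y < y1; ++y) {
      for (int x = x0; x < x1; ++x) {
        // center (x,y,z) in output space; window start in padded space
        const int wx = pad ? x : x - r;
        const int wy = pad ? y : y - r;
        const int wz = pad ? z : z - r;
        int m = 0;
        for (int dz = 0; dz < k; ++dz) {
          const R_xlen_t zoff = (R_xlen_t)(wz + dz) * py;
          for (int dy = 0; dy < k; ++dy) {
            const R_xlen_t row = ((zoff + wy + dy) * px) + wx;
            for (int dx = 0; dx < k; ++dx) buf[m++] = s[row + dx];
          }
        }
        std::sort(buf.begin(), buf.end());
        long double acc = 0.0L;
        int run = 1;
        for (int i = 1; i < nwin; ++i) {
          if (buf[i] == buf[i - 1]) ++run;
          else { acc += plogp[run]; run = 1; }
        }
        acc += plogp[run];
        out[(R_xlen_t)z * ny * nx + (R_xlen_t)y * nx + x] =
          -(double)acc;
      }
    }
  }
  return out;
}
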