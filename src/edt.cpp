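#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Exact Euclidean distance transform on a rectilinear grid with per-axis
// spacing, by three passes of the 1-D squared-distance lower-envelope
// transform (Felzenszwalb & Huttenlocher).  Input: logical mask.
// Output: for each TRUE voxel the Euclidean distance (mm) to the nearest
// FALSE voxel (0 for FALSE voxels).  Distances are measured between voxel
// centres.

static const double INF = std::numeric_limits<double>::infinity();

// 1-D squared distance transform with sample spacing h.  Unseeded samples
// carry a large finite sentinel rather than +Inf so the parabola
// intersections stay well defined.
static void dt1d(const double* f, double* d, int n, double h,
                 std::vector<int>& v, std::vector<double>& z) {
  v.resize(n); z.resize(n + 1);
  int k = 0;
  v[0] = 0; z[0] = -INF; z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double fq = f[q];
    int p = v[k];
    double s = ((fq + (double)q * q * h * h) - (f[p] + (double)p * p * h * h)) /
               (2.0 * h * h * (q - p));
    while (s <= z[k]) {
      --k;
      p = v[k];
      s = ((fq + (double)q * q * h * h) - (f[p] + (double)p * p * h * h)) /
          (2.0 * h * h * (q - p));
    }
    ++k; v[k] = q; z[k] = s; z[k + 1] = INF;
  }
  // z holds intersection abscissae in index units
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < (double)q) ++k;
    int p = v[k];
    double dq = (q - p) * h;
    d[q] = dq * dq + f[p];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dims,
                      NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double BIG = 1e20; // exceeds any realisable squared distance
  std::vector<double> d(n);
  for (R_xlen_t i = 0; i < n; ++i) d[i] = mask[i] ? BIG : 0.0;

  std::vector<int> v; std::vector<double> z;
  std::vector<double> f, g;

  // pass along x
  f.resize(nx); g.resize(nx);
  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy) {
      R_xlen_t base = (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
      for (int ix = 0; ix < nx; ++ix) f[ix] = d[base + ix];
      dt1d(f.data(), g.data(), nx, spacing[0], v, z);
      for (int ix = 0; ix < nx; ++ix) d[base + ix] = g[ix];
    }
  // pass along y
  f.resize(ny); g.resize(ny);
  for (int iz = 0; iz < nz; ++iz)
    for (int ix = 0; ix < nx; ++ix) {
      for (int iy = 0; iy < ny; ++iy)
        f[iy] = d[(R_xlen_t)ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz)];
      dt1d(f.data(), g.data(), ny, spacing[1], v, z);
      for (int iy = 0; iy < ny; ++iy)
        d[(R_xlen_t)ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz)] = g[iy];
    }
  // pass along z
  f.resize(nz); g.resize(nz);
  for (int iy = 0; iy < ny; ++iy)
    for (int ix = 0; ix < nx; ++ix) {
      for (int iz = 0; iz < nz; ++iz)
        f[iz] = d[(R_xlen_t)ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz)];
      dt1d(f.data(), g.data(), nz, spacing[2], v, z);
      for (int iz = 0; iz < nz; ++iz)
        d[(R_xlen_t)ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz)] = g[iz];
    }

  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = std::sqrt(d[i]);
  out.attr("dim") = dims;
  return out;
}
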