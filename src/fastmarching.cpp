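#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <limits>

using namespace Rcpp;

// First-order upwind fast marching solver for |grad T| * F = 1 on a
// rectilinear voxel grid with per-axis spacing (mm).  F is the per-voxel
// speed; voxels with F <= 0 are never entered.  Returns first-arrival
// times with +Inf for unreached voxels, plus a flag recording that the
// freezing order was monotone non-decreasing (a property of the upwind
// scheme that is asserted during the sweep rather than assumed).

static const double INF = std::numeric_limits<double>::infinity();

struct HeapEntry {
  double t;
  int idx;
  bool operator<(const HeapEntry& other) const { return t > other.t; } // min-heap
};

// Solve the upwind quadratic at a voxel given the minimal frozen
// neighbour arrival along each axis (a[k], may be INF) and spacing h[k].
static double upwind_solve(const double a[3], const double h[3], double invF) {
  // incremental solve over axes sorted by arrival value
  int ord[3] = {0, 1, 2};
  for (int i = 0; i < 2; ++i)
    for (int j = i + 1; j < 3; ++j)
      if (a[ord[j]] < a[ord[i]]) std::swap(ord[i], ord[j]);
  double T = INF;
  double A = 0.0, B = 0.0, C = -invF * invF;
  for (int m = 0; m < 3; ++m) {
    int k = ord[m];
    if (!std::isfinite(a[k])) break;
    double w = 1.0 / (h[k] * h[k]);
    A += w;
    B -= 2.0 * a[k] * w;
    C += a[k] * a[k] * w;
    double disc = B * B - 4.0 * A * C;
    if (disc < 0) break;
    double cand = (-B + std::sqrt(disc)) / (2.0 * A);
    if (cand >= a[k]) T = cand; // causal: solution must exceed all used arrivals
  }
  if (!std::isfinite(T) && std::isfinite(a[ord[0]])) {
    // fall back to one-sided update along the fastest axis
    int k = ord[0];
    T = a[k] + h[k] * invF;
  }
  return T;
}

// [[Rcpp::export]]
List cpp_fast_marching(NumericVector speed, IntegerVector dims,
                       NumericVector spacing, IntegerMatrix seeds) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double h[3] = {spacing[0], spacing[1], spacing[2]};

  std::vector<double> T(n, INF);
  std::vector<unsigned char> state(n, 0); // 0 far, 1 trial, 2 frozen
  std::priority_queue<HeapEntry> heap;

  for (int s = 0; s < seeds.nrow(); ++s) {
    int ix = seeds(s, 0), iy = seeds(s, 1), iz = seeds(s, 2);
    if (ix < 0 || ix >= nx || iy < 0 || iy >= ny || iz < 0 || iz >= nz)
      stop("seed %d outside the volume", s + 1);
    R_xlen_t idx = (R_xlen_t)ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
    T[idx] = 0.0;
    heap.push({0.0, (int)idx});
    state[idx] = 1;
    // exact initialization in a small ball around the seed: first-order
    // upwind differences are O(1) inaccurate at the point-source
    // singularity, so arrival there is seeded analytically (only within
    // the locally homogeneous-speed region)
    double Fs = speed[idx];
    if (Fs > 0.0) {
      for (int dzo = -2; dzo <= 2; ++dzo)
        for (int dyo = -2; dyo <= 2; ++dyo)
          for (int dxo = -2; dxo <= 2; ++dxo) {
            if (dxo == 0 && dyo == 0 && dzo == 0) continue;
            int jx = ix + dxo, jy = iy + dyo, jz = iz + dzo;
            if (jx < 0 || jx >= nx || jy < 0 || jy >= ny || jz < 0 || jz >= nz)
              continue;
            R_xlen_t j = (R_xlen_t)jx + (R_xlen_t)nx * (jy + (R_xlen_t)ny * jz);
            double Fj = speed[j];
            if (!(Fj > 0.0) || std::fabs(Fj - Fs) > 0.2 * Fs) continue;
            double dist = std::sqrt(dxo * dxo * h[0] * h[0] +
                                    dyo * dyo * h[1] * h[1] +
                                    dzo * dzo * h[2] * h[2]);
            double t0 = dist * 2.0 / (Fs + Fj);
            if (t0 < T[j]) {
              T[j] = t0;
              heap.push({t0, (int)j});
              state[j] = 1;
            }
          }
    }
  }

  bool monotone = true;
  double last_frozen = 0.0;
  const int offs[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};

  while (!heap.empty()) {
    HeapEntry e = heap.top(); heap.pop();
    R_xlen_t idx = e.idx;
    if (state[idx] == 2) continue;        // stale heap entry
    if (e.t > T[idx]) continue;
    state[idx] = 2;
    if (T[idx] < last_frozen - 1e-12) monotone = false;
    last_frozen = T[idx];

    int iz = (int)(idx / ((R_xlen_t)nx * ny));
    int rem = (int)(idx - (R_xlen_t)iz * nx * ny);
    int iy = rem / nx, ix = rem % nx;

    for (int d = 0; d < 6; ++d) {
      int jx = ix + offs[d][0], jy = iy + offs[d][1], jz = iz + offs[d][2];
      if (jx < 0 || jx >= nx || jy < 0 || jy >= ny || jz < 0 || jz >= nz) continue;
      R_xlen_t j = (R_xlen_t)jx + (R_xlen_t)nx * (jy + (R_xlen_t)ny * jz);
      if (state[j] == 2) continue;
      double F = speed[j];
      if (!(F > 0.0)) continue;
      // minimal frozen neighbour along each axis
      double a[3] = {INF, INF, INF};
      const int jc[3] = {jx, jy, jz};
      for (int k = 0; k < 3; ++k) {
        for (int pm = -1; pm <= 1; pm += 2) {
          int c[3] = {jx, jy, jz};
          c[k] = jc[k] + pm;
          if (c[k] < 0 || c[k] >= dims[k]) continue;
          R_xlen_t q = (R_xlen_t)c[0] + (R_xlen_t)nx * (c[1] + (R_xlen_t)ny * c[2]);
          if (state[q] == 2 && T[q] < a[k]) a[k] = T[q];
        }
      }
      double cand = upwind_solve(a, h, 1.0 / F);
      if (cand < T[j]) {
        T[j] = cand;
        state[j] = 1;
        heap.push({cand, (int)j});
      }
    }
  }

  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = T[i];
  out.attr("dim") = dims;
  return List::create(_["arrival"] = out, _["monotone"] = monotone);
}

// Connected component (6-connectivity) of `mask` containing `seed`
// (0-based voxel index triple).  Returns a logical array.
// [[Rcpp::export]]
LogicalVector cpp_flood_fill(LogicalVector mask, IntegerVector dims,
                             IntegerVector seed) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n);
  out.attr("dim") = dims;
  R_xlen_t s = (R_xlen_t)seed[0] + (R_xlen_t)nx * (seed[1] + (R_xlen_t)ny * seed[2]);
  if (s < 0 || s >= n || !mask[s]) return out;
  std::vector<R_xlen_t> stack;
  stack.push_back(s);
  out[s] = TRUE;
  const int offs[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
  while (!stack.empty()) {
    R_xlen_t idx = stack.back(); stack.pop_back();
    int iz = (int)(idx / ((R_xlen_t)nx * ny));
    int rem = (int)(idx - (R_xlen_t)iz * nx * ny);
    int iy = rem / nx, ix = rem % nx;
    for (int d = 0; d < 6; ++d) {
      int jx = ix + offs[d][0], jy = iy + offs[d][1], jz = iz + offs[d][2];
      if (jx < 0 || jx >= nx || jy < 0 || jy >= ny || jz < 0 || jz >= nz) continue;
      R_xlen_t j = (R_xlen_t)jx + (R_xlen_t)nx * (jy + (R_xlen_t)ny * jz);
      if (mask[j] && !out[j]) { out[j] = TRUE; stack.push_back(j); }
    }
  }
  return out;
}
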