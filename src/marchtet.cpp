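#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cmath>

using namespace Rcpp;

// Iso-surface extraction by the marching-tetrahedra variant of marching
// cubes: each grid cube is split into the six Kuhn tetrahedra sharing the
// main diagonal, which keeps face diagonals consistent between adjacent
// cubes, so the union of the per-tetrahedron triangles is watertight.
// Surface vertices are placed by linear interpolation along tetrahedron
// edges and deduplicated by the (sorted) global indices of the edge's two
// grid endpoints, so shared vertices are bit-identical.

struct KeyHash {
  std::size_t operator()(const uint64_t& k) const { return std::hash<uint64_t>()(k); }
};

// Kuhn decomposition: six paths 0 -> e_a -> e_a+e_b -> (1,1,1)
static const int KUHN[6][4][3] = {
  {{0,0,0},{1,0,0},{1,1,0},{1,1,1}},
  {{0,0,0},{1,0,0},{1,0,1},{1,1,1}},
  {{0,0,0},{0,1,0},{1,1,0},{1,1,1}},
  {{0,0,0},{0,1,0},{0,1,1},{1,1,1}},
  {{0,0,0},{0,0,1},{1,0,1},{1,1,1}},
  {{0,0,0},{0,0,1},{0,1,1},{1,1,1}}
};

// [[Rcpp::export]]
List cpp_march_tet(NumericVector field, IntegerVector dims,
                   NumericVector spacing, NumericVector origin, double iso) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  auto lin = [&](int x, int y, int z) -> int64_t {
    return (int64_t)x + (int64_t)nx * (y + (int64_t)ny * z);
  };

  std::vector<double> vx, vy, vz;
  std::vector<int> tri; // 0-based vertex indices, 3 per triangle
  std::unordered_map<uint64_t, int, KeyHash> edge_vertex;

  // emit a triangle oriented so its normal points from the inside
  // (field < iso) toward the outside half-space
  auto emit = [&](int a, int b, int c, const double in[3], const double out[3]) {
    if (a == b || b == c || a == c) return;
    double e1[3] = {vx[b] - vx[a], vy[b] - vy[a], vz[b] - vz[a]};
    double e2[3] = {vx[c] - vx[a], vy[c] - vy[a], vz[c] - vz[a]};
    double nvec[3] = {e1[1] * e2[2] - e1[2] * e2[1],
                      e1[2] * e2[0] - e1[0] * e2[2],
                      e1[0] * e2[1] - e1[1] * e2[0]};
    double d[3] = {out[0] - in[0], out[1] - in[1], out[2] - in[2]};
    double dot = nvec[0] * d[0] + nvec[1] * d[1] + nvec[2] * d[2];
    if (dot < 0) std::swap(b, c);
    tri.push_back(a); tri.push_back(b); tri.push_back(c);
  };

  auto edge_point = [&](int64_t ia, int64_t ib, double fa, double fb) -> int {
    int64_t lo = ia < ib ? ia : ib, hi = ia < ib ? ib : ia;
    uint64_t key = ((uint64_t)lo << 32) | (uint64_t)hi;
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    // interpolate consistently from the lower-index endpoint
    double flo = ia < ib ? fa : fb, fhi = ia < ib ? fb : fa;
    double t = (iso - flo) / (fhi - flo);
    if (t < 0) t = 0;
    if (t > 1) t = 1;
    int zlo = (int)(lo / ((int64_t)nx * ny));
    int rlo = (int)(lo - (int64_t)zlo * nx * ny);
    int ylo = rlo / nx, xlo = rlo % nx;
    int zhi = (int)(hi / ((int64_t)nx * ny));
    int rhi = (int)(hi - (int64_t)zhi * nx * ny);
    int yhi = rhi / nx, xhi = rhi % nx;
    vx.push_back(origin[0] + spacing[0] * (xlo + t * (xhi - xlo)));
    vy.push_back(origin[1] + spacing[1] * (ylo + t * (yhi - ylo)));
    vz.push_back(origin[2] + spacing[2] * (zlo + t * (zhi - zlo)));
    int id = (int)vx.size() - 1;
    edge_vertex[key] = id;
    return id;
  };

  for (int z = 0; z < nz - 1; ++z)
    for (int y = 0; y < ny - 1; ++y)
      for (int x = 0; x < nx - 1; ++x) {
        for (int t = 0; t < 6; ++t) {
          int64_t gi[4];
          double fv[4];
          double cw[4][3]; // world coordinates of the tet corners
          int inside[4], nin = 0;
          for (int c = 0; c < 4; ++c) {
            int cx = x + KUHN[t][c][0], cy = y + KUHN[t][c][1], cz = z + KUHN[t][c][2];
            gi[c] = lin(cx, cy, cz);
            cw[c][0] = origin[0] + spacing[0] * cx;
            cw[c][1] = origin[1] + spacing[1] * cy;
            cw[c][2] = origin[2] + spacing[2] * cz;
            fv[c] = field[gi[c]];
            if (fv[c] < iso) inside[nin++] = c;
          }
          if (nin == 0 || nin == 4) continue;
          // centroids of the inside/outside corner sets: a robust
          // outward reference direction for orientation
          double cin[3] = {0, 0, 0}, cout[3] = {0, 0, 0};
          int nout = 4 - nin;
          {
            bool isin[4] = {false, false, false, false};
            for (int mm = 0; mm < nin; ++mm) isin[inside[mm]] = true;
            for (int c = 0; c < 4; ++c)
              for (int k = 0; k < 3; ++k) {
                if (isin[c]) cin[k] += cw[c][k] / nin;
                else cout[k] += cw[c][k] / nout;
              }
          }
          if (nin == 1 || nin == 3) {
            // one triangle separating the lone corner
            int lone, other;
            if (nin == 1) lone = inside[0];
            else { // lone outside corner
              bool in[4] = {false, false, false, false};
              for (int mm = 0; mm < nin; ++mm) in[inside[mm]] = true;
              lone = 0; while (in[lone]) ++lone;
            }
            other = (lone == 0) ? 1 : 0;
            int v[3], mm = 0;
            for (int c = 0; c < 4; ++c)
              if (c != lone)
                v[mm++] = edge_point(gi[lone], gi[c], fv[lone], fv[c]);
            (void)other;
            emit(v[0], v[1], v[2], cin, cout);
          } else { // nin == 2: quad between the two in/out corner pairs
            int a = inside[0], b = inside[1];
            int o[2], mm = 0;
            for (int c = 0; c < 4; ++c) if (c != a && c != b) o[mm++] = c;
            int p0 = edge_point(gi[a], gi[o[0]], fv[a], fv[o[0]]);
            int p1 = edge_point(gi[a], gi[o[1]], fv[a], fv[o[1]]);
            int p2 = edge_point(gi[b], gi[o[1]], fv[b], fv[o[1]]);
            int p3 = edge_point(gi[b], gi[o[0]], fv[b], fv[o[0]]);
            emit(p0, p1, p2, cin, cout);
            emit(p0, p2, p3, cin, cout);
          }
        }
      }

  int nv = (int)vx.size(), nt = (int)tri.size() / 3;
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i) { V(i, 0) = vx[i]; V(i, 1) = vy[i]; V(i, 2) = vz[i]; }
  IntegerMatrix F(nt, 3);
  for (int i = 0; i < nt; ++i) {
    F(i, 0) = tri[3 * i] + 1; F(i, 1) = tri[3 * i + 1] + 1; F(i, 2) = tri[3 * i + 2] + 1;
  }
  return List::create(_["vertices"] = V, _["triangles"] = F);
}
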