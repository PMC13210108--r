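#include <Rcpp.h>
#include <unordered_map>
using namespace Rcpp;

// Marching tetrahedra on a scalar grid: each cell is split into six tetrahedra
// sharing the main diagonal, interface vertices are placed by linear
// interpolation along crossed edges and welded through an edge hash, and every
// emitted triangle is oriented so that its normal points away from the
// super-level ("inside") region. On a field whose super-level set is strictly
// interior to the grid the result is a closed, consistently oriented manifold.

struct Key {
  uint64_t k;
  bool operator==(const Key& o) const { return k == o.k; }
};
struct KeyHash {
  size_t operator()(const Key& o) const { return std::hash<uint64_t>()(o.k); }
};

// [[Rcpp::export(name = ".march_tetra")]]
List march_tetra(NumericVector field, IntegerVector dim, double level,
                 NumericVector spacing, NumericVector origin) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t nxy = (size_t)nx * ny;
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;
  std::unordered_map<Key, int, KeyHash> edge_vertex;

  static const int corner[8][3] = {{0,0,0},{1,0,0},{1,1,0},{0,1,0},
                                   {0,0,1},{1,0,1},{1,1,1},{0,1,1}};
  static const int tets[6][4] = {{0,1,2,6},{0,2,3,6},{0,3,7,6},
                                 {0,7,4,6},{0,4,5,6},{0,5,1,6}};

  auto edge_point = [&](size_t ga, size_t gb, double fa, double fb,
                        const double pa[3], const double pb[3]) -> int {
    Key key{ (std::min(ga, gb) << 32) | (uint64_t)std::max(ga, gb) };
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    double t = (level - fa) / (fb - fa);
    int id = (int)vx.size();
    vx.push_back(pa[0] + t * (pb[0] - pa[0]));
    vy.push_back(pa[1] + t * (pb[1] - pa[1]));
    vz.push_back(pa[2] + t * (pb[2] - pa[2]));
    edge_vertex[key] = id;
    return id;
  };

  auto emit = [&](int a, int b, int c, const double inside_pt[3]) {
    // orient away from an interior corner
    double ux = vx[b] - vx[a], uy = vy[b] - vy[a], uz = vz[b] - vz[a];
    double wx = vx[c] - vx[a], wy = vy[c] - vy[a], wz = vz[c] - vz[a];
    double nxv = uy * wz - uz * wy, nyv = uz * wx - ux * wz, nzv = ux * wy - uy * wx;
    double cx = (vx[a] + vx[b] + vx[c]) / 3 - inside_pt[0];
    double cy = (vy[a] + vy[b] + vy[c]) / 3 - inside_pt[1];
    double cz = (vz[a] + vz[b] + vz[c]) / 3 - inside_pt[2];
    if (nxv * cx + nyv * cy + nzv * cz < 0) std::swap(b, c);
    tri.push_back(a); tri.push_back(b); tri.push_back(c);
  };

  double f[8], pos[8][3];
  size_t gidx[8];
  for (int z = 0; z < nz - 1; ++z)
    for (int y = 0; y < ny - 1; ++y)
      for (int x = 0; x < nx - 1; ++x) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int cx = x + corner[c][0], cy = y + corner[c][1], cz = z + corner[c][2];
          gidx[c] = cx + nx * (cy + (size_t)ny * cz);
          f[c] = field[gidx[c]];
          pos[c][0] = origin[0] + cx * spacing[0];
          pos[c][1] = origin[1] + cy * spacing[1];
          pos[c][2] = origin[2] + cz * spacing[2];
          (f[c] > level ? any_in : any_out) = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          const int* T = tets[t];
          int in[4], nin = 0, out[4], nout = 0;
          for (int c = 0; c < 4; ++c)
            if (f[T[c]] > level) in[nin++] = T[c]; else out[nout++] = T[c];
          if (nin == 0 || nin == 4) continue;
          if (nin == 1) {
            int a = edge_point(gidx[in[0]], gidx[out[0]], f[in[0]], f[out[0]], pos[in[0]], pos[out[0]]);
            int b = edge_point(gidx[in[0]], gidx[out[1]], f[in[0]], f[out[1]], pos[in[0]], pos[out[1]]);
            int c = edge_point(gidx[in[0]], gidx[out[2]], f[in[0]], f[out[2]], pos[in[0]], pos[out[2]]);
            emit(a, b, c, pos[in[0]]);
          } else if (nin == 3) {
            int a = edge_point(gidx[in[0]], gidx[out[0]], f[in[0]], f[out[0]], pos[in[0]], pos[out[0]]);
            int b = edge_point(gidx[in[1]], gidx[out[0]], f[in[1]], f[out[0]], pos[in[1]], pos[out[0]]);
            int c = edge_point(gidx[in[2]], gidx[out[0]], f[in[2]], f[out[0]], pos[in[2]], pos[out[0]]);
            emit(a, b, c, pos[in[0]]);
          } else {  // 2 in, 2 out -> quad
            int a = edge_point(gidx[in[0]], gidx[out[0]], f[in[0]], f[out[0]], pos[in[0]], pos[out[0]]);
            int b = edge_point(gidx[in[0]], gidx[out[1]], f[in[0]], f[out[1]], pos[in[0]], pos[out[1]]);
            int c = edge_point(gidx[in[1]], gidx[out[1]], f[in[1]], f[out[1]], pos[in[1]], pos[out[1]]);
            int d = edge_point(gidx[in[1]], gidx[out[0]], f[in[1]], f[out[0]], pos[in[1]], pos[out[0]]);
            emit(a, b, c, pos[in[0]]);
            emit(a, c, d, pos[in[0]]);
          }
        }
      }

  int nv = (int)vx.size(), nt = (int)tri.size() / 3;
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i) { V(i,0) = vx[i]; V(i,1) = vy[i]; V(i,2) = vz[i]; }
  IntegerMatrix F(nt, 3);
  for (int i = 0; i < nt; ++i)
    for (int j = 0; j < 3; ++j) F(i, j) = tri[3 * i + j] + 1;
  return List::create(_["vertices"] = V, _["faces"] = F);
}
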