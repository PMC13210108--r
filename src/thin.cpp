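#include <Rcpp.h>
using namespace Rcpp;

// Topology-preserving 3D thinning by sequential simple-point deletion with
// six directional sub-iterations (up/down/north/south/east/west borders).
// A voxel is simple iff (Malandain-Bertrand characterisation)
//   * its foreground 26-neighbours form exactly one 26-connected component, and
//   * the background 6-neighbours lie in exactly one 6-connected component of
//     the background restricted to the 18-neighbourhood.
// Endpoints (<= 1 foreground 26-neighbour) are preserved so that centerline
// terminations survive. The caller must supply a volume with an empty
// one-voxel border shell.

static const int NB26[26][3] = {
  {-1,-1,-1},{0,-1,-1},{1,-1,-1},{-1,0,-1},{0,0,-1},{1,0,-1},{-1,1,-1},{0,1,-1},{1,1,-1},
  {-1,-1,0},{0,-1,0},{1,-1,0},{-1,0,0},{1,0,0},{-1,1,0},{0,1,0},{1,1,0},
  {-1,-1,1},{0,-1,1},{1,-1,1},{-1,0,1},{0,0,1},{1,0,1},{-1,1,1},{0,1,1},{1,1,1}};

static inline int lidx(int dx, int dy, int dz) {  // 0..26 within 3x3x3, center = 13
  return (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1);
}

static bool adj26(int a, int b) {
  int ax = a % 3, ay = (a / 3) % 3, az = a / 9;
  int bx = b % 3, by = (b / 3) % 3, bz = b / 9;
  int dx = std::abs(ax - bx), dy = std::abs(ay - by), dz = std::abs(az - bz);
  return (dx <= 1 && dy <= 1 && dz <= 1) && (dx + dy + dz > 0);
}

static bool adj6(int a, int b) {
  int ax = a % 3, ay = (a / 3) % 3, az = a / 9;
  int bx = b % 3, by = (b / 3) % 3, bz = b / 9;
  return std::abs(ax - bx) + std::abs(ay - by) + std::abs(az - bz) == 1;
}

static bool in18(int a) {  // edge+face neighbours of the center (not corners/center)
  int ax = a % 3 - 1, ay = (a / 3) % 3 - 1, az = a / 9 - 1;
  int m = std::abs(ax) + std::abs(ay) + std::abs(az);
  return m == 1 || m == 2;
}

static bool is_simple(const std::vector<uint8_t>& vol, int nx, int ny,
                      size_t nxy, size_t idx) {
  uint8_t nb[27];
  // neighbourhood occupancy
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx)
        nb[lidx(dx, dy, dz)] = vol[idx + dx + (size_t)nx * dy + nxy * dz];
  nb[13] = 0;

  // one 26-component of foreground neighbours
  int labels[27]; for (int i = 0; i < 27; ++i) labels[i] = -1;
  int ncomp_fg = 0;
  for (int i = 0; i < 27; ++i) {
    if (i == 13 || !nb[i] || labels[i] >= 0) continue;
    // BFS
    std::vector<int> stack = {i};
    labels[i] = ncomp_fg;
    while (!stack.empty()) {
      int c = stack.back(); stack.pop_back();
      for (int j = 0; j < 27; ++j)
        if (j != 13 && nb[j] && labels[j] < 0 && adj26(c, j)) {
          labels[j] = ncomp_fg; stack.push_back(j);
        }
    }
    ++ncomp_fg;
  }
  if (ncomp_fg != 1) return false;

  // one 6-component of background within the 18-neighbourhood containing a
  // face neighbour
  int blabels[27]; for (int i = 0; i < 27; ++i) blabels[i] = -1;
  int ncomp_bg = 0;
  static const int faces[6] = {4, 10, 12, 14, 16, 22};
  for (int fi = 0; fi < 6; ++fi) {
    int i = faces[fi];
    if (nb[i] || blabels[i] >= 0) continue;
    std::vector<int> stack = {i};
    blabels[i] = ncomp_bg;
    while (!stack.empty()) {
      int c = stack.back(); stack.pop_back();
      for (int j = 0; j < 27; ++j)
        if (in18(j) && !nb[j] && blabels[j] < 0 && adj6(c, j)) {
          blabels[j] = ncomp_bg; stack.push_back(j);
        }
    }
    ++ncomp_bg;
  }
  return ncomp_bg == 1;
}

// [[Rcpp::export(name = ".thin3d")]]
LogicalVector thin3d(LogicalVector vol, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t nxy = (size_t)nx * ny, n = nxy * nz;
  std::vector<uint8_t> v(n);
  for (size_t i = 0; i < n; ++i) v[i] = vol[i] ? 1 : 0;

  const int dirs[6][3] = {{0,0,1},{0,0,-1},{0,1,0},{0,-1,0},{1,0,0},{-1,0,0}};
  bool changed = true;
  std::vector<size_t> cand;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      long off = dirs[d][0] + (long)nx * dirs[d][1] + (long)nxy * dirs[d][2];
      cand.clear();
      for (int z = 1; z < nz - 1; ++z)
        for (int y = 1; y < ny - 1; ++y)
          for (int x = 1; x < nx - 1; ++x) {
            size_t idx = x + nx * (y + (size_t)ny * z);
            if (!v[idx] || v[idx + off]) continue;  // border in direction d
            cand.push_back(idx);
          }
      for (size_t k = 0; k < cand.size(); ++k) {
        size_t idx = cand[k];
        if (!v[idx]) continue;
        // endpoint?
        int nn = 0;
        for (int q = 0; q < 26; ++q)
          nn += v[idx + NB26[q][0] + (size_t)nx * NB26[q][1] + nxy * NB26[q][2]];
        if (nn <= 1) continue;
        if (is_simple(v, nx, ny, nxy, idx)) { v[idx] = 0; changed = true; }
      }
    }
  }

  LogicalVector out(n);
  for (size_t i = 0; i < n; ++i) out[i] = v[i] != 0;
  out.attr("dim") = dim;
  return out;
}
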