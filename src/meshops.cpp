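#include <Rcpp.h>
#include <unordered_map>
using namespace Rcpp;

// Nearest-neighbour matching on a uniform grid hash with expanding ring
// search. Exact: rings are expanded until the best candidate distance is
// provably smaller than anything a further ring could contain.

// [[Rcpp::export(name = ".nn_match")]]
IntegerVector nn_match(NumericMatrix query, NumericMatrix ref, double cell) {
  int nq = query.nrow(), nr = ref.nrow();
  if (nr == 0) stop("empty reference point set");
  std::vector<double> rx(nr), ry(nr), rz(nr);
  for (int i = 0; i < nr; ++i) { rx[i] = ref(i,0); ry[i] = ref(i,1); rz[i] = ref(i,2); }
  double lo[3] = {rx[0], ry[0], rz[0]};
  for (int i = 1; i < nr; ++i) {
    lo[0] = std::min(lo[0], rx[i]);
    lo[1] = std::min(lo[1], ry[i]);
    lo[2] = std::min(lo[2], rz[i]);
  }
  auto cell_of = [&](double x, double y, double z, int* c) {
    c[0] = (int)std::floor((x - lo[0]) / cell);
    c[1] = (int)std::floor((y - lo[1]) / cell);
    c[2] = (int)std::floor((z - lo[2]) / cell);
  };
  auto key_of = [](const int* c) -> int64_t {
    return ((int64_t)(c[0] + 1048576) << 42) | ((int64_t)(c[1] + 1048576) << 21) |
           (int64_t)(c[2] + 1048576);
  };
  std::unordered_map<int64_t, std::vector<int>> grid;
  for (int i = 0; i < nr; ++i) {
    int c[3]; cell_of(rx[i], ry[i], rz[i], c);
    grid[key_of(c)].push_back(i);
  }

  IntegerVector out(nq);
  for (int q = 0; q < nq; ++q) {
    double px = query(q,0), py = query(q,1), pz = query(q,2);
    int c0[3]; cell_of(px, py, pz, c0);
    int best = -1; double bestd2 = R_PosInf;
    for (int ring = 0; ; ++ring) {
      // once a match is found, stop when the ring cannot hold anything closer
      if (best >= 0 && (double)(ring - 1) * cell > std::sqrt(bestd2)) break;
      bool any_cell = false;
      for (int dz = -ring; dz <= ring; ++dz)
        for (int dy = -ring; dy <= ring; ++dy)
          for (int dx = -ring; dx <= ring; ++dx) {
            if (std::max({std::abs(dx), std::abs(dy), std::abs(dz)}) != ring) continue;
            int c[3] = {c0[0] + dx, c0[1] + dy, c0[2] + dz};
            auto it = grid.find(key_of(c));
            if (it == grid.end()) continue;
            any_cell = true;
            for (int i : it->second) {
              double ddx = rx[i] - px, ddy = ry[i] - py, ddz = rz[i] - pz;
              double d2 = ddx*ddx + ddy*ddy + ddz*ddz;
              if (d2 < bestd2) { bestd2 = d2; best = i; }
            }
          }
      if (best < 0 && !any_cell && ring > 2097152) break;  // safety valve
      (void)any_cell;
    }
    out[q] = best + 1;
  }
  return out;
}

// First intersection of each ray with a triangle mesh (Moller-Trumbore),
// returning the hit point and ray parameter t (NA when the ray misses).

// [[Rcpp::export(name = ".ray_mesh_hits")]]
List ray_mesh_hits(NumericMatrix orig, NumericMatrix dir,
                   NumericMatrix V, IntegerMatrix F) {
  int nrays = orig.nrow(), nf = F.nrow();
  NumericMatrix hit(nrays, 3);
  NumericVector tval(nrays);
  const double eps = 1e-9;
  for (int r = 0; r < nrays; ++r) {
    double ox = orig(r,0), oy = orig(r,1), oz = orig(r,2);
    double dx = dir(r,0), dy = dir(r,1), dz = dir(r,2);
    double tbest = R_PosInf;
    for (int f = 0; f < nf; ++f) {
      int a = F(f,0) - 1, b = F(f,1) - 1, c = F(f,2) - 1;
      double e1x = V(b,0)-V(a,0), e1y = V(b,1)-V(a,1), e1z = V(b,2)-V(a,2);
      double e2x = V(c,0)-V(a,0), e2y = V(c,1)-V(a,1), e2z = V(c,2)-V(a,2);
      double px = dy*e2z - dz*e2y, py = dz*e2x - dx*e2z, pz = dx*e2y - dy*e2x;
      double det = e1x*px + e1y*py + e1z*pz;
      if (std::fabs(det) < eps) continue;
      double inv = 1.0 / det;
      double tx = ox - V(a,0), ty = oy - V(a,1), tz = oz - V(a,2);
      double u = (tx*px + ty*py + tz*pz) * inv;
      if (u < -1e-9 || u > 1 + 1e-9) continue;
      double qx = ty*e1z - tz*e1y, qy = tz*e1x - tx*e1z, qz = tx*e1y - ty*e1x;
      double v = (dx*qx + dy*qy + dz*qz) * inv;
      if (v < -1e-9 || u + v > 1 + 1e-9) continue;
      double t = (e2x*qx + e2y*qy + e2z*qz) * inv;
      if (t > eps && t < tbest) tbest = t;
    }
    if (std::isfinite(tbest)) {
      hit(r,0) = ox + tbest*dx; hit(r,1) = oy + tbest*dy; hit(r,2) = oz + tbest*dz;
      tval[r] = tbest;
    } else {
      hit(r,0) = hit(r,1) = hit(r,2) = NA_REAL;
      tval[r] = NA_REAL;
    }
  }
  return List::create(_["hit"] = hit, _["t"] = tval);
}

// Exact two-sided permutation p-value for the Spearman statistic: enumerates
// all distinct arrangements of the (possibly tied) y ranks. With ties every
// distinct arrangement carries equal multiplicity, so uniform enumeration of
// distinct arrangements is an exact permutation test.

// [[Rcpp::export(name = ".spearman_perm_p")]]
double spearman_perm_p(NumericVector xr, NumericVector yr) {
  int n = xr.size();
  double sx = 0, sy = 0;
  std::vector<double> xc(n), yc(n);
  double mx = mean(xr), my = mean(yr);
  for (int i = 0; i < n; ++i) { xc[i] = xr[i] - mx; yc[i] = yr[i] - my; }
  for (int i = 0; i < n; ++i) { sx += xc[i]*xc[i]; sy += yc[i]*yc[i]; }
  double denom = std::sqrt(sx * sy);
  if (denom <= 0) return NA_REAL;
  double obs = 0;
  for (int i = 0; i < n; ++i) obs += xc[i] * yc[i];
  obs = std::fabs(obs / denom);

  std::vector<double> perm(yc);
  std::sort(perm.begin(), perm.end());
  uint64_t total = 0, extreme = 0;
  do {
    double s = 0;
    for (int i = 0; i < n; ++i) s += xc[i] * perm[i];
    double rho = std::fabs(s / denom);
    ++total;
    if (rho >= obs - 1e-12) ++extreme;
  } while (std::next_permutation(perm.begin(), perm.end()));
  return (double)extreme / (double)total;
}
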