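#include <Rcpp.h>
using namespace Rcpp;

// Incremental 3D convex hull (visible-face deletion / horizon re-triangulation).
// O(n * f) without conflict lists, which is ample for isosurface meshes of a
// few tens of thousands of vertices. Faces are kept outward-oriented against
// the centroid of the initial tetrahedron.

struct Face { int a, b, c; double nx, ny, nz, off; bool alive; };

// [[Rcpp::export(name = ".convex_hull3")]]
List convex_hull3(NumericMatrix pts) {
  int n = pts.nrow();
  if (n < 4) stop("convex hull needs at least 4 points");
  std::vector<double> X(n), Y(n), Z(n);
  for (int i = 0; i < n; ++i) { X[i] = pts(i,0); Y[i] = pts(i,1); Z[i] = pts(i,2); }

  double span = 0;
  for (int d = 0; d < 3; ++d) {
    double lo = pts(0,d), hi = pts(0,d);
    for (int i = 1; i < n; ++i) { lo = std::min(lo, pts(i,d)); hi = std::max(hi, pts(i,d)); }
    span = std::max(span, hi - lo);
  }
  const double eps = 1e-9 * std::max(span, 1.0);

  // initial simplex: two extreme points, farthest from line, farthest from plane
  int i0 = 0, i1 = 0;
  for (int i = 1; i < n; ++i) {
    if (X[i] < X[i0] || (X[i] == X[i0] && (Y[i] < Y[i0] || (Y[i] == Y[i0] && Z[i] < Z[i0])))) i0 = i;
    if (X[i] > X[i1] || (X[i] == X[i1] && (Y[i] > Y[i1] || (Y[i] == Y[i1] && Z[i] > Z[i1])))) i1 = i;
  }
  if (i0 == i1) stop("degenerate point set (all points identical)");
  auto sub = [&](int p, int q, double* v) { v[0]=X[p]-X[q]; v[1]=Y[p]-Y[q]; v[2]=Z[p]-Z[q]; };
  double d01[3]; sub(i1, i0, d01);
  int i2 = -1; double best = eps;
  for (int i = 0; i < n; ++i) {
    double v[3]; sub(i, i0, v);
    double cx = d01[1]*v[2]-d01[2]*v[1], cy = d01[2]*v[0]-d01[0]*v[2], cz = d01[0]*v[1]-d01[1]*v[0];
    double d2 = std::sqrt(cx*cx + cy*cy + cz*cz);
    if (d2 > best) { best = d2; i2 = i; }
  }
  if (i2 < 0) stop("degenerate point set (collinear)");
  double d02[3]; sub(i2, i0, d02);
  double nx0 = d01[1]*d02[2]-d01[2]*d02[1], ny0 = d01[2]*d02[0]-d01[0]*d02[2],
         nz0 = d01[0]*d02[1]-d01[1]*d02[0];
  int i3 = -1; best = eps;
  for (int i = 0; i < n; ++i) {
    double v[3]; sub(i, i0, v);
    double d3 = std::fabs(nx0*v[0] + ny0*v[1] + nz0*v[2]) /
                std::sqrt(nx0*nx0 + ny0*ny0 + nz0*nz0);
    if (d3 > best) { best = d3; i3 = i; }
  }
  if (i3 < 0) stop("degenerate point set (coplanar)");

  double ctr[3] = {(X[i0]+X[i1]+X[i2]+X[i3])/4, (Y[i0]+Y[i1]+Y[i2]+Y[i3])/4,
                   (Z[i0]+Z[i1]+Z[i2]+Z[i3])/4};

  std::vector<Face> faces;
  auto add_face = [&](int a, int b, int c) {
    double u[3], w[3]; sub(b, a, u); sub(c, a, w);
    double fx = u[1]*w[2]-u[2]*w[1], fy = u[2]*w[0]-u[0]*w[2], fz = u[0]*w[1]-u[1]*w[0];
    double cx = (X[a]+X[b]+X[c])/3 - ctr[0], cy = (Y[a]+Y[b]+Y[c])/3 - ctr[1],
           cz = (Z[a]+Z[b]+Z[c])/3 - ctr[2];
    if (fx*cx + fy*cy + fz*cz < 0) { std::swap(b, c); fx = -fx; fy = -fy; fz = -fz; }
    double norm = std::sqrt(fx*fx + fy*fy + fz*fz);
    Face f{a, b, c, fx/norm, fy/norm, fz/norm, 0, true};
    f.off = f.nx * X[a] + f.ny * Y[a] + f.nz * Z[a];
    faces.push_back(f);
  };
  add_face(i0, i1, i2); add_face(i0, i1, i3); add_face(i0, i2, i3); add_face(i1, i2, i3);

  for (int p = 0; p < n; ++p) {
    if (p == i0 || p == i1 || p == i2 || p == i3) continue;
    std::vector<int> visible;
    for (size_t f = 0; f < faces.size(); ++f) {
      if (!faces[f].alive) continue;
      if (faces[f].nx * X[p] + faces[f].ny * Y[p] + faces[f].nz * Z[p] - faces[f].off > eps)
        visible.push_back((int)f);
    }
    if (visible.empty()) continue;
    // horizon = undirected edges of visible faces not shared by two visible faces
    std::map<std::pair<int,int>, int> edge_count;
    for (int fi : visible) {
      const Face& f = faces[fi];
      int e[3][2] = {{f.a, f.b}, {f.b, f.c}, {f.c, f.a}};
      for (int k = 0; k < 3; ++k) {
        auto key = std::minmax(e[k][0], e[k][1]);
        edge_count[{key.first, key.second}]++;
      }
      faces[fi].alive = false;
    }
    for (auto& kv : edge_count)
      if (kv.second == 1) add_face(kv.first.first, kv.first.second, p);
  }

  int nf = 0;
  for (auto& f : faces) if (f.alive) ++nf;
  IntegerMatrix F(nf, 3);
  double vol = 0, area = 0;
  int r = 0;
  for (auto& f : faces) {
    if (!f.alive) continue;
    F(r,0) = f.a + 1; F(r,1) = f.b + 1; F(r,2) = f.c + 1; ++r;
    double u[3], w[3], q[3];
    sub(f.b, f.a, u); sub(f.c, f.a, w);
    q[0] = u[1]*w[2]-u[2]*w[1]; q[1] = u[2]*w[0]-u[0]*w[2]; q[2] = u[0]*w[1]-u[1]*w[0];
    area += 0.5 * std::sqrt(q[0]*q[0] + q[1]*q[1] + q[2]*q[2]);
    // signed tet against centroid (outward faces -> positive)
    double a0[3] = {X[f.a]-ctr[0], Y[f.a]-ctr[1], Z[f.a]-ctr[2]};
    double b0[3] = {X[f.b]-ctr[0], Y[f.b]-ctr[1], Z[f.b]-ctr[2]};
    double c0[3] = {X[f.c]-ctr[0], Y[f.c]-ctr[1], Z[f.c]-ctr[2]};
    vol += (a0[0]*(b0[1]*c0[2]-b0[2]*c0[1]) - a0[1]*(b0[0]*c0[2]-b0[2]*c0[0]) +
            a0[2]*(b0[0]*c0[1]-b0[1]*c0[0])) / 6.0;
  }
  return List::create(_["faces"] = F, _["volume"] = vol, _["area"] = area);
}
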