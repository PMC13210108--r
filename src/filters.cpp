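#include <Rcpp.h>
using namespace Rcpp;

// Separable [3,3,3] box average. Border taps are renormalised by the number of
// in-bounds samples, so a constant field is a fixed point and total mass is
// conserved for any object at least one voxel away from the grid border.
static void box_pass(const std::vector<double>& in, std::vector<double>& out,
                     int nx, int ny, int nz, int axis) {
  int str[3] = {1, nx, nx * ny};
  int dim[3] = {nx, ny, nz};
  int s = str[axis], n = dim[axis];
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int idx = x + nx * (y + (size_t)ny * z);
        int pos = (axis == 0) ? x : (axis == 1 ? y : z);
        double acc = in[idx];
        int cnt = 1;
        if (pos > 0)     { acc += in[idx - s]; ++cnt; }
        if (pos < n - 1) { acc += in[idx + s]; ++cnt; }
        out[idx] = acc / cnt;
      }
}

// [[Rcpp::export(name = ".box_smooth3")]]
NumericVector box_smooth3(NumericVector vol, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<double> a(vol.begin(), vol.end()), b(n);
  box_pass(a, b, nx, ny, nz, 0);
  box_pass(b, a, nx, ny, nz, 1);
  box_pass(a, b, nx, ny, nz, 2);
  NumericVector out(b.begin(), b.end());
  out.attr("dim") = dim;
  return out;
}

// Trilinear refinement by an integer factor per axis: output grid keeps the
// corner samples and inserts (factor - 1) interpolated planes per cell.
// [[Rcpp::export(name = ".trilinear_refine")]]
NumericVector trilinear_refine(NumericVector vol, IntegerVector dim, int factor) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int ox = (nx - 1) * factor + 1, oy = (ny - 1) * factor + 1, oz = (nz - 1) * factor + 1;
  NumericVector out((size_t)ox * oy * oz);
  const double f = factor;
  for (int z = 0; z < oz; ++z) {
    double zi = z / f; int z0 = std::min((int)zi, nz - 2); double tz = zi - z0;
    if (nz == 1) { z0 = 0; tz = 0; }
    for (int y = 0; y < oy; ++y) {
      double yi = y / f; int y0 = std::min((int)yi, ny - 2); double ty = yi - y0;
      if (ny == 1) { y0 = 0; ty = 0; }
      for (int x = 0; x < ox; ++x) {
        double xi = x / f; int x0 = std::min((int)xi, nx - 2); double tx = xi - x0;
        if (nx == 1) { x0 = 0; tx = 0; }
        size_t c000 = x0 + nx * (y0 + (size_t)ny * z0);
        size_t dx = (nx > 1), dy = (ny > 1) ? nx : 0, dz = (nz > 1) ? (size_t)nx * ny : 0;
        double v =
          (1 - tz) * ((1 - ty) * ((1 - tx) * vol[c000] + tx * vol[c000 + dx]) +
                      ty * ((1 - tx) * vol[c000 + dy] + tx * vol[c000 + dy + dx])) +
          tz * ((1 - ty) * ((1 - tx) * vol[c000 + dz] + tx * vol[c000 + dz + dx]) +
                ty * ((1 - tx) * vol[c000 + dz + dy] + tx * vol[c000 + dz + dy + dx]));
        out[x + ox * (y + (size_t)oy * z)] = v;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(ox, oy, oz);
  return out;
}
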