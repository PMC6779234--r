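// Exact-intersection-length (Siddon-style) 2D parallel-beam projector,
// applied independently per axial slice. Column-major (nx, ny, nz) volumes;
// sinograms are (n_angles, n_radial, nz). All lengths in mm.
#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Traverse one ray through an nx x ny slice. The ray passes through the
// point (r*cos(th), r*sin(th)) with direction (-sin(th), cos(th)); grid is
// centred on the origin with voxel sizes (sx, sy). Calls visit(voxel, len).
template <typename F>
static void trace_ray(double th, double r, int nx, int ny, double sx,
                      double sy, F visit) {
  const double eps = 1e-12;
  double dx = -std::sin(th), dy = std::cos(th);
  double px = r * std::cos(th), py = r * std::sin(th);
  double xmin = -0.5 * nx * sx, ymin = -0.5 * ny * sy;
  double xmax = -xmin, ymax = -ymin;
  // parametric entry/exit of the bounding box
  double t0 = -std::numeric_limits<double>::infinity();
  double t1 = std::numeric_limits<double>::infinity();
  if (std::fabs(dx) < eps) {
    if (px <= xmin || px >= xmax) return;
  } else {
    double a = (xmin - px) / dx, b = (xmax - px) / dx;
    t0 = std::max(t0, std::min(a, b));
    t1 = std::min(t1, std::max(a, b));
  }
  if (std::fabs(dy) < eps) {
    if (py <= ymin || py >= ymax) return;
  } else {
    double a = (ymin - py) / dy, b = (ymax - py) / dy;
    t0 = std::max(t0, std::min(a, b));
    t1 = std::min(t1, std::max(a, b));
  }
  if (t1 <= t0) return;
  double t = t0;
  // current voxel at midpoint just after entry
  double mx = px + (t0 + eps) * dx, my = py + (t0 + eps) * dy;
  int i = (int)std::floor((mx - xmin) / sx);
  int j = (int)std::floor((my - ymin) / sy);
  if (i < 0) i = 0; if (i >= nx) i = nx - 1;
  if (j < 0) j = 0; if (j >= ny) j = ny - 1;
  int stepi = dx > eps ? 1 : (dx < -eps ? -1 : 0);
  int stepj = dy > eps ? 1 : (dy < -eps ? -1 : 0);
  // parametric distance to next x/y plane crossing
  double tx = std::numeric_limits<double>::infinity();
  double ty = std::numeric_limits<double>::infinity();
  double dtx = stepi ? sx / std::fabs(dx) : 0;
  double dty = stepj ? sy / std::fabs(dy) : 0;
  if (stepi)
    tx = ((xmin + (i + (stepi > 0 ? 1 : 0)) * sx) - px) / dx;
  if (stepj)
    ty = ((ymin + (j + (stepj > 0 ? 1 : 0)) * sy) - py) / dy;
  while (t < t1 - eps) {
    double tn = std::min(std::min(tx, ty), t1);
    double len = tn - t;
    if (len > 0) visit(i, j, len);
    if (tn >= t1 - eps) break;
    if (tx <= ty) { i += stepi; tx += dtx; } else { j += stepj; ty += dty; }
    if (i < 0 || i >= nx || j < 0 || j >= ny) break;
    t = tn;
  }
}

// [[Rcpp::export(name = ".proj_forward")]]
NumericVector proj_forward(NumericVector vol, IntegerVector dim,
                           NumericVector spacing, NumericVector angles,
                           NumericVector offsets) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int na = angles.size(), nr = offsets.size();
  double sx = spacing[0], sy = spacing[1];
  NumericVector sino(na * nr * nz);
  for (int k = 0; k < nz; ++k) {
    const double* sl = vol.begin() + (R_xlen_t)k * nx * ny;
    for (int a = 0; a < na; ++a)
      for (int b = 0; b < nr; ++b) {
        double acc = 0;
        trace_ray(angles[a], offsets[b], nx, ny, sx, sy,
                  [&](int i, int j, double len) { acc += len * sl[i + nx * j]; });
        sino[a + na * (b + (R_xlen_t)nr * k)] = acc;
      }
  }
  sino.attr("dim") = IntegerVector::create(na, nr, nz);
  return sino;
}

// [[Rcpp::export(name = ".proj_back")]]
NumericVector proj_back(NumericVector sino, IntegerVector dim,
                        NumericVector spacing, NumericVector angles,
                        NumericVector offsets) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int na = angles.size(), nr = offsets.size();
  double sx = spacing[0], sy = spacing[1];
  NumericVector vol(nx * ny * (R_xlen_t)nz);
  for (int k = 0; k < nz; ++k) {
    double* sl = vol.begin() + (R_xlen_t)k * nx * ny;
    for (int a = 0; a < na; ++a)
      for (int b = 0; b < nr; ++b) {
        double w = sino[a + na * (b + (R_xlen_t)nr * k)];
        if (w == 0) continue;
        trace_ray(angles[a], offsets[b], nx, ny, sx, sy,
                  [&](int i, int j, double len) { sl[i + nx * j] += len * w; });
      }
  }
  vol.attr("dim") = dim;
  return vol;
}
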