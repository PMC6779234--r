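// 3D binary morphology, connected components and separable Gaussian
// smoothing on column-major (nx, ny, nz) arrays.
#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

static inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// one 6-neighbourhood (face-connected) erosion or dilation pass
static LogicalVector morph_pass(const LogicalVector& m, IntegerVector dim,
                                bool dilate) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector out(m.size());
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int c = idx3(i, j, k, nx, ny);
        bool v = m[c];
        bool hit = v;
        if (dilate) {
          if (!hit && i > 0)      hit = m[idx3(i - 1, j, k, nx, ny)];
          if (!hit && i < nx - 1) hit = m[idx3(i + 1, j, k, nx, ny)];
          if (!hit && j > 0)      hit = m[idx3(i, j - 1, k, nx, ny)];
          if (!hit && j < ny - 1) hit = m[idx3(i, j + 1, k, nx, ny)];
          if (!hit && k > 0)      hit = m[idx3(i, j, k - 1, nx, ny)];
          if (!hit && k < nz - 1) hit = m[idx3(i, j, k + 1, nx, ny)];
          out[c] = hit;
        } else {
          // erosion: voxels outside the grid count as background
          bool all = v;
          if (all) all = (i > 0)      && m[idx3(i - 1, j, k, nx, ny)];
          if (all) all = (i < nx - 1) && m[idx3(i + 1, j, k, nx, ny)];
          if (all) all = (j > 0)      && m[idx3(i, j - 1, k, nx, ny)];
          if (all) all = (j < ny - 1) && m[idx3(i, j + 1, k, nx, ny)];
          if (all) all = (k > 0)      && m[idx3(i, j, k - 1, nx, ny)];
          if (all) all = (k < nz - 1) && m[idx3(i, j, k + 1, nx, ny)];
          out[c] = all;
        }
      }
  return out;
}

// [[Rcpp::export(name = ".morph3d")]]
LogicalVector morph3d(LogicalVector mask, IntegerVector dim, int radius,
                      std::string op) {
  LogicalVector m = clone(mask);
  bool first_dilate = (op == "dilate" || op == "close");
  bool two_stage = (op == "close" || op == "open");
  for (int r = 0; r < radius; ++r) m = morph_pass(m, dim, first_dilate);
  if (two_stage)
    for (int r = 0; r < radius; ++r) m = morph_pass(m, dim, !first_dilate);
  m.attr("dim") = dim;
  return m;
}

// 6-connected component labelling; labels 1..n in scan order, 0 background
// [[Rcpp::export(name = ".label3d")]]
IntegerVector label3d(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = mask.size();
  IntegerVector lab(n, 0);
  int next = 0;
  std::queue<int> q;
  const int dx[6] = {-1, 1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, -1, 1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, -1, 1};
  for (int s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    lab[s] = ++next;
    q.push(s);
    while (!q.empty()) {
      int c = q.front(); q.pop();
      int i = c % nx, j = (c / nx) % ny, k = c / (nx * ny);
      for (int t = 0; t < 6; ++t) {
        int ii = i + dx[t], jj = j + dy[t], kk = k + dz[t];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        int nb = idx3(ii, jj, kk, nx, ny);
        if (mask[nb] && !lab[nb]) { lab[nb] = next; q.push(nb); }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// separable Gaussian along one axis with reflective boundaries
static void gauss_axis(std::vector<double>& v, int nx, int ny, int nz,
                       int axis, double sigma) {
  if (sigma <= 0) return;
  int rad = (int)std::ceil(4.0 * sigma);
  std::vector<double> ker(2 * rad + 1);
  double s = 0;
  for (int t = -rad; t <= rad; ++t) {
    ker[t + rad] = std::exp(-0.5 * t * t / (sigma * sigma));
    s += ker[t + rad];
  }
  for (double& w : ker) w /= s;
  int len = axis == 0 ? nx : (axis == 1 ? ny : nz);
  int stride = axis == 0 ? 1 : (axis == 1 ? nx : nx * ny);
  std::vector<double> line(len);
  // iterate over all lines along 'axis'
  int n1 = axis == 0 ? ny : nx;
  int n2 = axis == 2 ? ny : nz;
  for (int b = 0; b < n2; ++b)
    for (int a = 0; a < n1; ++a) {
      int base;
      if (axis == 0)      base = idx3(0, a, b, nx, ny);
      else if (axis == 1) base = idx3(a, 0, b, nx, ny);
      else                base = idx3(a, b, 0, nx, ny);
      for (int t = 0; t < len; ++t) line[t] = v[base + t * stride];
      for (int t = 0; t < len; ++t) {
        double acc = 0;
        for (int u = -rad; u <= rad; ++u) {
          int p = t + u;
          if (p < 0) p = -p - 1;            // reflect
          if (p >= len) p = 2 * len - 1 - p;
          if (p < 0) p = 0;                 // guard for very wide kernels
          if (p >= len) p = len - 1;
          acc += ker[u + rad] * line[p];
        }
        v[base + t * stride] = acc;
      }
    }
}

// [[Rcpp::export(name = ".gauss3d")]]
NumericVector gauss3d(NumericVector vol, IntegerVector dim,
                      NumericVector sigma_vox) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> v(vol.begin(), vol.end());
  gauss_axis(v, nx, ny, nz, 0, sigma_vox[0]);
  gauss_axis(v, nx, ny, nz, 1, sigma_vox[1]);
  gauss_axis(v, nx, ny, nz, 2, sigma_vox[2]);
  NumericVector out(v.begin(), v.end());
  out.attr("dim") = dim;
  return out;
}
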