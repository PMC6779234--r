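// Channel-first 3D convolution (3x3x3, zero padded), max pooling and
// nearest-neighbour upsampling with backward passes. Tensors are R arrays
// with dim (C, nx, ny, nz, B); convolution weights are (Cout, Cin*27)
// matrices with rows of the input patch ordered channel-fastest, offset
// index o = (ox+1) + 3*(oy+1) + 9*(oz+1). im2col is blocked over voxel
// columns to bound memory.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static const int BLOCK = 4096;

struct Dim5 {
  int C, nx, ny, nz, B;
  R_xlen_t vox() const { return (R_xlen_t)nx * ny * nz; }
};

static Dim5 getdim(SEXP a) {
  IntegerVector d = as<IntegerVector>(Rf_getAttrib(a, R_DimSymbol));
  if (d.size() != 5) stop("expected a 5D (C, x, y, z, batch) array");
  return Dim5{d[0], d[1], d[2], d[3], d[4]};
}

// fill im2col block for columns [n0, n1) of one sample
static void im2col_block(const double* x, const Dim5& d, R_xlen_t n0,
                         R_xlen_t n1, arma::mat& K) {
  int C = d.C, nx = d.nx, ny = d.ny, nz = d.nz;
  K.zeros();
  for (int oz = -1; oz <= 1; ++oz)
    for (int oy = -1; oy <= 1; ++oy)
      for (int ox = -1; ox <= 1; ++ox) {
        int o = (ox + 1) + 3 * (oy + 1) + 9 * (oz + 1);
        for (R_xlen_t n = n0; n < n1; ++n) {
          int i = (int)(n % nx), j = (int)((n / nx) % ny), k = (int)(n / ((R_xlen_t)nx * ny));
          int ii = i + ox, jj = j + oy, kk = k + oz;
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
            continue;
          R_xlen_t nsrc = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
          std::memcpy(K.colptr(n - n0) + (R_xlen_t)o * C, x + (R_xlen_t)C * nsrc,
                      C * sizeof(double));
        }
      }
}

// [[Rcpp::export(name = ".conv3_fw")]]
NumericVector conv3_fw(NumericVector x, NumericMatrix W, NumericVector bias) {
  Dim5 d = getdim(x);
  int Cout = W.nrow();
  if (W.ncol() != d.C * 27) stop("weight/input channel mismatch");
  R_xlen_t N = d.vox();
  NumericVector y((R_xlen_t)Cout * N * d.B);
  arma::mat Wm(W.begin(), Cout, d.C * 27, false);
  arma::vec bv(bias.begin(), Cout, false);
  arma::mat K(d.C * 27, std::min((R_xlen_t)BLOCK, N));
  for (int b = 0; b < d.B; ++b) {
    const double* xs = x.begin() + (R_xlen_t)d.C * N * b;
    double* ys = y.begin() + (R_xlen_t)Cout * N * b;
    for (R_xlen_t n0 = 0; n0 < N; n0 += BLOCK) {
      R_xlen_t n1 = std::min(n0 + (R_xlen_t)BLOCK, N);
      arma::mat Kb = K.cols(0, n1 - n0 - 1);
      im2col_block(xs, d, n0, n1, Kb);
      arma::mat Y = Wm * Kb;
      Y.each_col() += bv;
      std::memcpy(ys + (R_xlen_t)Cout * n0, Y.memptr(),
                  Y.n_elem * sizeof(double));
    }
  }
  y.attr("dim") = IntegerVector::create(Cout, d.nx, d.ny, d.nz, d.B);
  return y;
}

// [[Rcpp::export(name = ".conv3_bw")]]
List conv3_bw(NumericVector x, NumericMatrix W, NumericVector dy) {
  Dim5 d = getdim(x);
  int Cout = W.nrow();
  R_xlen_t N = d.vox();
  arma::mat Wm(W.begin(), Cout, d.C * 27, false);
  NumericVector dx((R_xlen_t)d.C * N * d.B);
  arma::mat dW(Cout, d.C * 27, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  arma::mat K(d.C * 27, std::min((R_xlen_t)BLOCK, N));
  for (int b = 0; b < d.B; ++b) {
    const double* xs = x.begin() + (R_xlen_t)d.C * N * b;
    double* dxs = dx.begin() + (R_xlen_t)d.C * N * b;
    const double* dys = dy.begin() + (R_xlen_t)Cout * N * b;
    for (R_xlen_t n0 = 0; n0 < N; n0 += BLOCK) {
      R_xlen_t n1 = std::min(n0 + (R_xlen_t)BLOCK, N);
      arma::mat Kb = K.cols(0, n1 - n0 - 1);
      im2col_block(xs, d, n0, n1, Kb);
      arma::mat dY(const_cast<double*>(dys) + (R_xlen_t)Cout * n0, Cout,
                   n1 - n0, false);
      dW += dY * Kb.t();
      db += arma::sum(dY, 1);
      arma::mat dK = Wm.t() * dY;  // (C*27) x block
      // col2im scatter-add
      for (int oz = -1; oz <= 1; ++oz)
        for (int oy = -1; oy <= 1; ++oy)
          for (int ox = -1; ox <= 1; ++ox) {
            int o = (ox + 1) + 3 * (oy + 1) + 9 * (oz + 1);
            for (R_xlen_t n = n0; n < n1; ++n) {
              int i = (int)(n % d.nx), j = (int)((n / d.nx) % d.ny),
                  k = (int)(n / ((R_xlen_t)d.nx * d.ny));
              int ii = i + ox, jj = j + oy, kk = k + oz;
              if (ii < 0 || ii >= d.nx || jj < 0 || jj >= d.ny || kk < 0 ||
                  kk >= d.nz)
                continue;
              R_xlen_t nsrc = ii + (R_xlen_t)d.nx * (jj + (R_xlen_t)d.ny * kk);
              const double* src = dK.colptr(n - n0) + (R_xlen_t)o * d.C;
              double* dst = dxs + (R_xlen_t)d.C * nsrc;
              for (int c = 0; c < d.C; ++c) dst[c] += src[c];
            }
          }
    }
  }
  dx.attr("dim") = IntegerVector::create(d.C, d.nx, d.ny, d.nz, d.B);
  return List::create(_["dx"] = dx, _["dW"] = wrap(dW), _["db"] = wrap(db));
}

// [[Rcpp::export(name = ".maxpool3_fw")]]
List maxpool3_fw(NumericVector x, IntegerVector f) {
  Dim5 d = getdim(x);
  int fx = f[0], fy = f[1], fz = f[2];
  if (d.nx % fx || d.ny % fy || d.nz % fz) stop("non-divisible pooling");
  int mx = d.nx / fx, my = d.ny / fy, mz = d.nz / fz;
  R_xlen_t Ny = (R_xlen_t)d.C * mx * my * mz;
  NumericVector y(Ny * d.B);
  IntegerVector arg(Ny * d.B);
  for (int b = 0; b < d.B; ++b) {
    const double* xs = x.begin() + (R_xlen_t)d.C * d.vox() * b;
    double* ys = y.begin() + Ny * b;
    int* as = arg.begin() + Ny * b;
    for (int k = 0; k < mz; ++k)
      for (int j = 0; j < my; ++j)
        for (int i = 0; i < mx; ++i)
          for (int c = 0; c < d.C; ++c) {
            double best = -INFINITY; R_xlen_t besti = 0;
            for (int w = 0; w < fz; ++w)
              for (int v = 0; v < fy; ++v)
                for (int u = 0; u < fx; ++u) {
                  R_xlen_t src = c + (R_xlen_t)d.C *
                    ((i * fx + u) + (R_xlen_t)d.nx *
                      ((j * fy + v) + (R_xlen_t)d.ny * (k * fz + w)));
                  if (xs[src] > best) { best = xs[src]; besti = src; }
                }
            R_xlen_t dst = c + (R_xlen_t)d.C *
              (i + (R_xlen_t)mx * (j + (R_xlen_t)my * k));
            ys[dst] = best;
            as[dst] = (int)besti;
          }
  }
  y.attr("dim") = IntegerVector::create(d.C, mx, my, mz, d.B);
  arg.attr("dim") = y.attr("dim");
  return List::create(_["y"] = y, _["arg"] = arg);
}

// [[Rcpp::export(name = ".maxpool3_bw")]]
NumericVector maxpool3_bw(IntegerVector arg, NumericVector dy,
                          IntegerVector dimx) {
  R_xlen_t Nx = 1;
  for (int t = 0; t < 5; ++t) Nx *= dimx[t];
  R_xlen_t per_in = Nx / dimx[4];
  NumericVector dx(Nx);
  R_xlen_t Ny = dy.size() / dimx[4];
  for (int b = 0; b < dimx[4]; ++b) {
    const double* dys = dy.begin() + Ny * b;
    const int* as = arg.begin() + Ny * b;
    double* dxs = dx.begin() + per_in * b;
    for (R_xlen_t t = 0; t < Ny; ++t) dxs[as[t]] += dys[t];
  }
  dx.attr("dim") = dimx;
  return dx;
}

// [[Rcpp::export(name = ".upsample3_fw")]]
NumericVector upsample3_fw(NumericVector x, IntegerVector f) {
  Dim5 d = getdim(x);
  int fx = f[0], fy = f[1], fz = f[2];
  int ux = d.nx * fx, uy = d.ny * fy, uz = d.nz * fz;
  R_xlen_t Ny = (R_xlen_t)d.C * ux * uy * uz;
  NumericVector y(Ny * d.B);
  for (int b = 0; b < d.B; ++b) {
    const double* xs = x.begin() + (R_xlen_t)d.C * d.vox() * b;
    double* ys = y.begin() + Ny * b;
    for (int k = 0; k < uz; ++k)
      for (int j = 0; j < uy; ++j)
        for (int i = 0; i < ux; ++i) {
          R_xlen_t src = (R_xlen_t)d.C *
            ((i / fx) + (R_xlen_t)d.nx * ((j / fy) + (R_xlen_t)d.ny * (k / fz)));
          R_xlen_t dst = (R_xlen_t)d.C *
            (i + (R_xlen_t)ux * (j + (R_xlen_t)uy * k));
          std::memcpy(ys + dst, xs + src, d.C * sizeof(double));
        }
  }
  y.attr("dim") = IntegerVector::create(d.C, ux, uy, uz, d.B);
  return y;
}

// [[Rcpp::export(name = ".upsample3_bw")]]
NumericVector upsample3_bw(NumericVector dy, IntegerVector f) {
  Dim5 d = getdim(dy);
  int fx = f[0], fy = f[1], fz = f[2];
  int mx = d.nx / fx, my = d.ny / fy, mz = d.nz / fz;
  R_xlen_t Nx = (R_xlen_t)d.C * mx * my * mz;
  NumericVector dx(Nx * d.B);
  for (int b = 0; b < d.B; ++b) {
    const double* dys = dy.begin() + (R_xlen_t)d.C * d.vox() * b;
    double* dxs = dx.begin() + Nx * b;
    for (int k = 0; k < d.nz; ++k)
      for (int j = 0; j < d.ny; ++j)
        for (int i = 0; i < d.nx; ++i) {
          R_xlen_t src = (R_xlen_t)d.C *
            (i + (R_xlen_t)d.nx * (j + (R_xlen_t)d.ny * k));
          R_xlen_t dst = (R_xlen_t)d.C *
            ((i / fx) + (R_xlen_t)mx * ((j / fy) + (R_xlen_t)my * (k / fz)));
          for (int c = 0; c < d.C; ++c) dxs[dst + c] += dys[src + c];
        }
  }
  dx.attr("dim") = IntegerVector::create(d.C, mx, my, mz, d.B);
  return dx;
}
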