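// Low-level kernels for the 3D convolution engine.
//
// Memory layout follows R arrays: dim = c(X, Y, Z, C), column-major, so the
// x index runs fastest and channels are contiguous blocks of X*Y*Z voxels.
// Convolutions are computed as im2col + sgemm (BLAS), chunked over output
// z-slices to bound the size of the patch matrix. The convolution path runs
// in single precision (the usual choice for convolutional networks);
// normalization, activations and the optimizer stay in double precision.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

inline int out_size(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// Fill the single-precision im2col patch matrix for output slices
// [oz0, oz1). col has dims (rows, k^3 * cin), rows = OX * OY * (oz1 - oz0).
void fill_im2col(const double* x, int X, int Y, int Z, int cin,
                 int k, int stride, int pad,
                 int OX, int OY, int oz0, int oz1, arma::fmat& col) {
  const R_xlen_t XY = (R_xlen_t)X * Y;
  const R_xlen_t XYZ = XY * Z;
  col.zeros();
  for (int ci = 0; ci < cin; ++ci) {
    const double* xc = x + (R_xlen_t)ci * XYZ;
    for (int dz = 0; dz < k; ++dz) {
      for (int dy = 0; dy < k; ++dy) {
        for (int dx = 0; dx < k; ++dx) {
          const int q = dx + k * (dy + k * (dz + k * ci));
          float* cp = col.colptr(q);
          for (int oz = oz0; oz < oz1; ++oz) {
            const int iz = oz * stride - pad + dz;
            if (iz < 0 || iz >= Z) continue;
            for (int oy = 0; oy < OY; ++oy) {
              const int iy = oy * stride - pad + dy;
              if (iy < 0 || iy >= Y) continue;
              const R_xlen_t ibase = (R_xlen_t)iz * XY + (R_xlen_t)iy * X;
              const int rbase = OX * (oy + OY * (oz - oz0));
              for (int ox = 0; ox < OX; ++ox) {
                const int ix = ox * stride - pad + dx;
                if (ix < 0 || ix >= X) continue;
                cp[rbase + ox] = (float)xc[ibase + ix];
              }
            }
          }
        }
      }
    }
  }
}

int chunk_slices(int OX, int OY, int cols) {
  // target <= ~32 MB per patch matrix
  double per_slice = (double)OX * OY * cols * 4.0;
  int nz = (int)std::floor(32e6 / std::max(per_slice, 1.0));
  return std::max(nz, 1);
}

} // namespace

// [[Rcpp::export(rng = false)]]
NumericVector conv3d_fw_cpp(NumericVector x, IntegerVector xdim,
                            NumericMatrix w, NumericVector bias,
                            int k, int stride, int pad) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], cin = xdim[3];
  const int OX = out_size(X, k, stride, pad);
  const int OY = out_size(Y, k, stride, pad);
  const int OZ = out_size(Z, k, stride, pad);
  const int cout = w.ncol();
  const int cols = k * k * k * cin;
  if (w.nrow() != cols) stop("weight matrix rows do not match k^3 * cin");
  NumericVector y((R_xlen_t)OX * OY * OZ * cout);
  arma::fmat W(cols, cout);
  std::copy(w.begin(), w.end(), W.begin());
  const int zstep = chunk_slices(OX, OY, cols);
  const R_xlen_t OXYZ = (R_xlen_t)OX * OY * OZ;
  arma::fmat col;
  for (int oz0 = 0; oz0 < OZ; oz0 += zstep) {
    const int oz1 = std::min(oz0 + zstep, OZ);
    const int rows = OX * OY * (oz1 - oz0);
    col.set_size(rows, cols);
    fill_im2col(x.begin(), X, Y, Z, cin, k, stride, pad, OX, OY, oz0, oz1, col);
    arma::fmat out = col * W; // rows x cout
    for (int co = 0; co < cout; ++co) {
      double* yp = y.begin() + (R_xlen_t)co * OXYZ + (R_xlen_t)oz0 * OX * OY;
      const double b = bias.size() ? bias[co] : 0.0;
      const float* op = out.colptr(co);
      for (int r = 0; r < rows; ++r) yp[r] = (double)op[r] + b;
    }
  }
  y.attr("dim") = IntegerVector::create(OX, OY, OZ, cout);
  return y;
}

// [[Rcpp::export(rng = false)]]
List conv3d_bw_cpp(NumericVector x, IntegerVector xdim,
                   NumericMatrix w, NumericVector gy,
                   int k, int stride, int pad, bool need_gx) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], cin = xdim[3];
  const int OX = out_size(X, k, stride, pad);
  const int OY = out_size(Y, k, stride, pad);
  const int OZ = out_size(Z, k, stride, pad);
  const int cout = w.ncol();
  const int cols = k * k * k * cin;
  const R_xlen_t OXYZ = (R_xlen_t)OX * OY * OZ;
  arma::fmat W(cols, cout);
  std::copy(w.begin(), w.end(), W.begin());
  arma::fmat GW(cols, cout, arma::fill::zeros);
  NumericVector gb(cout);
  NumericVector gx;
  std::vector<float> gxf;
  if (need_gx) gxf.assign((size_t)X * Y * Z * cin, 0.0f);
  const int zstep = chunk_slices(OX, OY, cols);
  const R_xlen_t XY = (R_xlen_t)X * Y;
  const R_xlen_t XYZ = XY * Z;
  arma::fmat col;
  for (int oz0 = 0; oz0 < OZ; oz0 += zstep) {
    const int oz1 = std::min(oz0 + zstep, OZ);
    const int rows = OX * OY * (oz1 - oz0);
    arma::fmat gyc(rows, cout);
    for (int co = 0; co < cout; ++co) {
      const double* gp = gy.begin() + (R_xlen_t)co * OXYZ + (R_xlen_t)oz0 * OX * OY;
      float* cp = gyc.colptr(co);
      double s = 0.0;
      for (int r = 0; r < rows; ++r) { cp[r] = (float)gp[r]; s += gp[r]; }
      gb[co] += s;
    }
    col.set_size(rows, cols);
    fill_im2col(x.begin(), X, Y, Z, cin, k, stride, pad, OX, OY, oz0, oz1, col);
    GW += col.t() * gyc;
    if (need_gx) {
      arma::fmat gcol = gyc * W.t(); // rows x cols
      // scatter-add (col2im)
      for (int ci = 0; ci < cin; ++ci) {
        float* gxc = gxf.data() + (R_xlen_t)ci * XYZ;
        for (int dz = 0; dz < k; ++dz) {
          for (int dy = 0; dy < k; ++dy) {
            for (int dx = 0; dx < k; ++dx) {
              const int q = dx + k * (dy + k * (dz + k * ci));
              const float* cp = gcol.colptr(q);
              for (int oz = oz0; oz < oz1; ++oz) {
                const int iz = oz * stride - pad + dz;
                if (iz < 0 || iz >= Z) continue;
                for (int oy = 0; oy < OY; ++oy) {
                  const int iy = oy * stride - pad + dy;
                  if (iy < 0 || iy >= Y) continue;
                  const R_xlen_t ibase = (R_xlen_t)iz * XY + (R_xlen_t)iy * X;
                  const int rbase = OX * (oy + OY * (oz - oz0));
                  for (int ox = 0; ox < OX; ++ox) {
                    const int ix = ox * stride - pad + dx;
                    if (ix < 0 || ix >= X) continue;
                    gxc[ibase + ix] += cp[rbase + ox];
                  }
                }
              }
            }
          }
        }
      }
    }
  }
  NumericMatrix gwR(cols, cout);
  std::copy(GW.begin(), GW.end(), gwR.begin());
  if (need_gx) {
    gx = NumericVector((R_xlen_t)X * Y * Z * cin);
    for (R_xlen_t i = 0; i < (R_xlen_t)gxf.size(); ++i) gx[i] = gxf[i];
    gx.attr("dim") = xdim;
  }
  return List::create(_["gw"] = gwR, _["gb"] = gb, _["gx"] = gx);
}

// [[Rcpp::export(rng = false)]]
NumericVector leaky_fw_cpp(NumericVector x, double alpha) {
  NumericVector y(clone(x));
  double* p = y.begin();
  const R_xlen_t n = y.size();
  for (R_xlen_t i = 0; i < n; ++i) if (p[i] < 0) p[i] *= alpha;
  return y;
}

// [[Rcpp::export(rng = false)]]
NumericVector leaky_bw_cpp(NumericVector x, NumericVector gy, double alpha) {
  NumericVector gx(clone(gy));
  const double* xp = x.begin();
  double* g = gx.begin();
  const R_xlen_t n = gx.size();
  for (R_xlen_t i = 0; i < n; ++i) if (xp[i] < 0) g[i] *= alpha;
  return gx;
}

// Per-channel normalization over the spatial dimensions of one sample,
// with learnable affine parameters.
// [[Rcpp::export(rng = false)]]
List instnorm_fw_cpp(NumericVector x, IntegerVector xdim,
                     NumericVector gamma, NumericVector beta, double eps) {
  const R_xlen_t N = (R_xlen_t)xdim[0] * xdim[1] * xdim[2];
  const int C = xdim[3];
  NumericVector y(x.size());
  NumericVector mu(C), invstd(C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + c * N;
    double* yc = y.begin() + c * N;
    double m = 0.0;
    for (R_xlen_t i = 0; i < N; ++i) m += xc[i];
    m /= N;
    double v = 0.0;
    for (R_xlen_t i = 0; i < N; ++i) { const double d = xc[i] - m; v += d * d; }
    v /= N;
    const double is = 1.0 / std::sqrt(v + eps);
    mu[c] = m; invstd[c] = is;
    const double g = gamma[c], b = beta[c];
    for (R_xlen_t i = 0; i < N; ++i) yc[i] = g * (xc[i] - m) * is + b;
  }
  y.attr("dim") = xdim;
  return List::create(_["y"] = y, _["mu"] = mu, _["invstd"] = invstd);
}

// [[Rcpp::export(rng = false)]]
List instnorm_bw_cpp(NumericVector x, IntegerVector xdim,
                     NumericVector gamma, NumericVector mu, NumericVector invstd,
                     NumericVector gy) {
  const R_xlen_t N = (R_xlen_t)xdim[0] * xdim[1] * xdim[2];
  const int C = xdim[3];
  NumericVector gx(x.size()), dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + c * N;
    const double* gc = gy.begin() + c * N;
    double* gxc = gx.begin() + c * N;
    const double m = mu[c], is = invstd[c], g = gamma[c];
    double sg = 0.0, sgx = 0.0;
    for (R_xlen_t i = 0; i < N; ++i) {
      const double xh = (xc[i] - m) * is;
      sg += gc[i];
      sgx += gc[i] * xh;
    }
    dbeta[c] = sg; dgamma[c] = sgx;
    const double mg = sg / N, mgx = sgx / N;
    for (R_xlen_t i = 0; i < N; ++i) {
      const double xh = (xc[i] - m) * is;
      gxc[i] = g * is * (gc[i] - mg - xh * mgx);
    }
  }
  gx.attr("dim") = xdim;
  return List::create(_["gx"] = gx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// [[Rcpp::export(rng = false)]]
NumericVector upsample2_fw_cpp(NumericVector x, IntegerVector xdim) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], C = xdim[3];
  const int X2 = 2 * X, Y2 = 2 * Y, Z2 = 2 * Z;
  NumericVector y((R_xlen_t)X2 * Y2 * Z2 * C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + (R_xlen_t)c * X * Y * Z;
    double* yc = y.begin() + (R_xlen_t)c * X2 * Y2 * Z2;
    for (int z = 0; z < Z2; ++z) {
      const R_xlen_t zb = (R_xlen_t)(z / 2) * X * Y;
      for (int yy = 0; yy < Y2; ++yy) {
        const R_xlen_t yb = zb + (R_xlen_t)(yy / 2) * X;
        double* row = yc + (R_xlen_t)z * X2 * Y2 + (R_xlen_t)yy * X2;
        for (int xx = 0; xx < X2; ++xx) row[xx] = xc[yb + xx / 2];
      }
    }
  }
  y.attr("dim") = IntegerVector::create(X2, Y2, Z2, C);
  return y;
}

// [[Rcpp::export(rng = false)]]
NumericVector upsample2_bw_cpp(NumericVector gy, IntegerVector ydim) {
  const int X2 = ydim[0], Y2 = ydim[1], Z2 = ydim[2], C = ydim[3];
  const int X = X2 / 2, Y = Y2 / 2, Z = Z2 / 2;
  NumericVector gx((R_xlen_t)X * Y * Z * C);
  for (int c = 0; c < C; ++c) {
    const double* gc = gy.begin() + (R_xlen_t)c * X2 * Y2 * Z2;
    double* xc = gx.begin() + (R_xlen_t)c * X * Y * Z;
    for (int z = 0; z < Z2; ++z) {
      const R_xlen_t zb = (R_xlen_t)(z / 2) * X * Y;
      for (int yy = 0; yy < Y2; ++yy) {
        const R_xlen_t yb = zb + (R_xlen_t)(yy / 2) * X;
        const double* row = gc + (R_xlen_t)z * X2 * Y2 + (R_xlen_t)yy * X2;
        for (int xx = 0; xx < X2; ++xx) xc[yb + xx / 2] += row[xx];
      }
    }
  }
  gx.attr("dim") = IntegerVector::create(X, Y, Z, C);
  return gx;
}
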