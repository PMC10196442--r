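// Volume resampling kernels: affine resampling (rotation/scaling and
// whole-volume resizing), separable resizing with nearest/linear/cubic
// interpolation, and separable Gaussian blur.
//
// Continuous voxel coordinates are 0-based with voxel centers on integers.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Keys cubic convolution kernel, a = -0.5
inline double cubic_w(double t) {
  t = std::fabs(t);
  if (t < 1.0) return 1.5 * t * t * t - 2.5 * t * t + 1.0;
  if (t < 2.0) return -0.5 * t * t * t + 2.5 * t * t - 4.0 * t + 2.0;
  return 0.0;
}

} // namespace

// Sample the input volume at q = A %*% p + t for every output voxel p.
// method: 0 = nearest, 1 = trilinear. Out-of-field voxels get `fill`.
// [[Rcpp::export(rng = false)]]
NumericVector affine_resample3d_cpp(NumericVector vol, IntegerVector vdim,
                                    NumericMatrix A, NumericVector tvec,
                                    IntegerVector odim, int method, double fill) {
  const int X = vdim[0], Y = vdim[1], Z = vdim[2];
  const int OX = odim[0], OY = odim[1], OZ = odim[2];
  NumericVector out((R_xlen_t)OX * OY * OZ);
  const double* v = vol.begin();
  const R_xlen_t XY = (R_xlen_t)X * Y;
  double* o = out.begin();
  R_xlen_t idx = 0;
  for (int z = 0; z < OZ; ++z) {
    for (int y = 0; y < OY; ++y) {
      for (int x = 0; x < OX; ++x, ++idx) {
        const double qx = A(0,0)*x + A(0,1)*y + A(0,2)*z + tvec[0];
        const double qy = A(1,0)*x + A(1,1)*y + A(1,2)*z + tvec[1];
        const double qz = A(2,0)*x + A(2,1)*y + A(2,2)*z + tvec[2];
        if (method == 0) {
          const int ix = (int)std::lround(qx);
          const int iy = (int)std::lround(qy);
          const int iz = (int)std::lround(qz);
          if (ix < 0 || ix >= X || iy < 0 || iy >= Y || iz < 0 || iz >= Z) {
            o[idx] = fill;
          } else {
            o[idx] = v[ix + X * iy + XY * iz];
          }
        } else {
          if (qx < 0 || qx > X - 1 || qy < 0 || qy > Y - 1 || qz < 0 || qz > Z - 1) {
            o[idx] = fill;
            continue;
          }
          const int x0 = (int)std::floor(qx), y0 = (int)std::floor(qy), z0 = (int)std::floor(qz);
          const int x1 = std::min(x0 + 1, X - 1), y1 = std::min(y0 + 1, Y - 1), z1 = std::min(z0 + 1, Z - 1);
          const double fx = qx - x0, fy = qy - y0, fz = qz - z0;
          const double c00 = v[x0 + X*y0 + XY*z0] * (1-fx) + v[x1 + X*y0 + XY*z0] * fx;
          const double c10 = v[x0 + X*y1 + XY*z0] * (1-fx) + v[x1 + X*y1 + XY*z0] * fx;
          const double c01 = v[x0 + X*y0 + XY*z1] * (1-fx) + v[x1 + X*y0 + XY*z1] * fx;
          const double c11 = v[x0 + X*y1 + XY*z1] * (1-fx) + v[x1 + X*y1 + XY*z1] * fx;
          const double c0 = c00 * (1-fy) + c10 * fy;
          const double c1 = c01 * (1-fy) + c11 * fy;
          o[idx] = c0 * (1-fz) + c1 * fz;
        }
      }
    }
  }
  out.attr("dim") = odim;
  return out;
}

// Resize along one axis (0 = x, 1 = y, 2 = z).
// method: 0 nearest, 1 linear, 3 cubic (third-order spline).
// [[Rcpp::export(rng = false)]]
NumericVector resize_axis_cpp(NumericVector vol, IntegerVector vdim,
                              int axis, int nout, int method) {
  const int d[3] = {vdim[0], vdim[1], vdim[2]};
  int od[3] = {d[0], d[1], d[2]};
  od[axis] = nout;
  const int nin = d[axis];
  NumericVector out((R_xlen_t)od[0] * od[1] * od[2]);
  const double scale = (double)nin / nout;
  const R_xlen_t XYi = (R_xlen_t)d[0] * d[1];
  const R_xlen_t XYo = (R_xlen_t)od[0] * od[1];
  const double* v = vol.begin();
  double* o = out.begin();
  const R_xlen_t strides_in[3] = {1, (R_xlen_t)d[0], XYi};
  const R_xlen_t stride = strides_in[axis];
  for (int z = 0; z < od[2]; ++z) {
    for (int y = 0; y < od[1]; ++y) {
      for (int x = 0; x < od[0]; ++x) {
        int oc[3] = {x, y, z};
        const int j = oc[axis];
        const double q = (j + 0.5) * scale - 0.5;
        int ic[3] = {x, y, z};
        ic[axis] = 0;
        const R_xlen_t base = ic[0] + (R_xlen_t)d[0] * ic[1] + XYi * ic[2];
        double val;
        if (method == 0) {
          val = v[base + stride * clampi((int)std::lround(q), 0, nin - 1)];
        } else if (method == 1) {
          const double qc = clampd(q, 0, nin - 1);
          const int j0 = (int)std::floor(qc);
          const int j1 = std::min(j0 + 1, nin - 1);
          const double f = qc - j0;
          val = v[base + stride * j0] * (1 - f) + v[base + stride * j1] * f;
        } else {
          const int j0 = (int)std::floor(q);
          double acc = 0.0, wsum = 0.0;
          for (int m = j0 - 1; m <= j0 + 2; ++m) {
            const double w = cubic_w(q - m);
            if (w == 0.0) continue;
            acc += w * v[base + stride * clampi(m, 0, nin - 1)];
            wsum += w;
          }
          val = acc / wsum;
        }
        o[x + (R_xlen_t)od[0] * y + XYo * z] = val;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(od[0], od[1], od[2]);
  return out;
}

// [[Rcpp::export(rng = false)]]
NumericVector gauss_blur3d_cpp(NumericVector vol, IntegerVector vdim, double sigma) {
  const int d[3] = {vdim[0], vdim[1], vdim[2]};
  const int rad = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> ker(2 * rad + 1);
  double s = 0.0;
  for (int i = -rad; i <= rad; ++i) {
    ker[i + rad] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += ker[i + rad];
  }
  for (double& k : ker) k /= s;
  NumericVector cur(clone(vol));
  const R_xlen_t XY = (R_xlen_t)d[0] * d[1];
  const R_xlen_t strides[3] = {1, (R_xlen_t)d[0], XY};
  for (int axis = 0; axis < 3; ++axis) {
    NumericVector nxt((R_xlen_t)d[0] * d[1] * d[2]);
    const double* v = cur.begin();
    double* o = nxt.begin();
    const int n = d[axis];
    const R_xlen_t stride = strides[axis];
    for (int z = 0; z < d[2]; ++z) {
      for (int y = 0; y < d[1]; ++y) {
        for (int x = 0; x < d[0]; ++x) {
          const int c[3] = {x, y, z};
          const int j = c[axis];
          const R_xlen_t idx = x + (R_xlen_t)d[0] * y + XY * z;
          const R_xlen_t base = idx - stride * j;
          double acc = 0.0;
          for (int m = -rad; m <= rad; ++m) {
            const int jj = clampi(j + m, 0, n - 1); // replicate boundary
            acc += ker[m + rad] * v[base + stride * jj];
          }
          o[idx] = acc;
        }
      }
    }
    cur = nxt;
  }
  cur.attr("dim") = IntegerVector::create(d[0], d[1], d[2]);
  return cur;
}
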