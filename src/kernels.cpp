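// Low-level numerical kernels for 3D convolutional registration.
//
// Array conventions (all column-major, matching R):
//   feature tensors  : dim = c(nx, ny, nz, C)
//   conv weights     : dim = c(3, 3, 3, Cin, Cout)      (k = 3 throughout)
//   tconv weights    : dim = c(2, 2, 2, Cin, Cout)      (stride-2 upsampling)
//   displacement     : dim = c(nx, ny, nz, 3), voxel units, 0-based coords
//

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline int out_size(int n, int stride) {
  // k = 3, pad = 1: stride 1 -> n, stride 2 -> n/2 (n even)
  return (n + 2 - 3) / stride + 1;
}

// [[Rcpp::export]]
NumericVector tconv3d_fw(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector d = x.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2], Ci = (d.size() > 3) ? d[3] : 1;
  IntegerVector dw = w.attr("dim");
  const int Co = dw[4];
  const int mx = 2 * nx, my = 2 * ny, mz = 2 * nz;
  NumericVector y((R_xlen_t)mx * my * mz * Co);
  y.attr("dim") = IntegerVector::create(mx, my, mz, Co);
  double* py = y.begin();
  const double* px = x.begin();
  const double* pw = w.begin();
  for (int co = 0; co < Co; ++co) {
    double* yc = py + (R_xlen_t)co * mx * my * mz;
    const double bc = b[co];
    for (R_xlen_t i = 0; i < (R_xlen_t)mx * my * mz; ++i) yc[i] = bc;
    for (int ci = 0; ci < Ci; ++ci) {
      const double* xc = px + (R_xlen_t)ci * nx * ny * nz;
      const double* wc = pw + 8 * ((R_xlen_t)ci + (R_xlen_t)Ci * co);
      for (int iz = 0; iz < nz; ++iz)
      for (int iy = 0; iy < ny; ++iy)
      for (int ix = 0; ix < nx; ++ix) {
        const double v = xc[ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz)];
        if (v == 0.0) continue;
        for (int dz = 0; dz < 2; ++dz)
        for (int dy = 0; dy < 2; ++dy)
        for (int dx = 0; dx < 2; ++dx) {
          const R_xlen_t o = (2 * ix + dx) +
            (R_xlen_t)mx * ((2 * iy + dy) + (R_xlen_t)my * (2 * iz + dz));
          yc[o] += v * wc[dx + 2 * (dy + 2 * dz)];
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List tconv3d_bw(NumericVector x, NumericVector w, NumericVector gy) {
  IntegerVector d = x.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2], Ci = (d.size() > 3) ? d[3] : 1;
  IntegerVector dw = w.attr("dim");
  const int Co = dw[4];
  const int mx = 2 * nx, my = 2 * ny, mz = 2 * nz;
  NumericVector gx((R_xlen_t)nx * ny * nz * Ci);
  gx.attr("dim") = IntegerVector::create(nx, ny, nz, Ci);
  NumericVector gw((R_xlen_t)8 * Ci * Co);
  gw.attr("dim") = IntegerVector::create(2, 2, 2, Ci, Co);
  NumericVector gb(Co);
  const double* px = x.begin();
  const double* pw = w.begin();
  const double* pg = gy.begin();
  double* pgx = gx.begin();
  double* pgw = gw.begin();
  for (int co = 0; co < Co; ++co) {
    const double* gc = pg + (R_xlen_t)co * mx * my * mz;
    double acc = 0.0;
    for (R_xlen_t i = 0; i < (R_xlen_t)mx * my * mz; ++i) acc += gc[i];
    gb[co] = acc;
    for (int ci = 0; ci < Ci; ++ci) {
      const double* xc = px + (R_xlen_t)ci * nx * ny * nz;
      const double* wc = pw + 8 * ((R_xlen_t)ci + (R_xlen_t)Ci * co);
      double* gwc = pgw + 8 * ((R_xlen_t)ci + (R_xlen_t)Ci * co);
      double* gxc = pgx + (R_xlen_t)ci * nx * ny * nz;
      for (int iz = 0; iz < nz; ++iz)
      for (int iy = 0; iy < ny; ++iy)
      for (int ix = 0; ix < nx; ++ix) {
        const R_xlen_t xi = ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
        const double v = xc[xi];
        double gacc = 0.0;
        for (int dz = 0; dz < 2; ++dz)
        for (int dy = 0; dy < 2; ++dy)
        for (int dx = 0; dx < 2; ++dx) {
          const R_xlen_t o = (2 * ix + dx) +
            (R_xlen_t)mx * ((2 * iy + dy) + (R_xlen_t)my * (2 * iz + dz));
          const double g = gc[o];
          const int t = dx + 2 * (dy + 2 * dz);
          gacc += g * wc[t];
          gwc[t] += g * v;
        }
        gxc[xi] += gacc;
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Trilinear sampling of a single-channel volume at arbitrary voxel
// coordinates (0-based).  Samples outside the domain contribute 0.
// coords: dim c(m, 3) matrix of target coordinates.
// [[Rcpp::export]]
NumericVector sample3d_fw(NumericVector img, NumericMatrix coords) {
  IntegerVector d = img.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2];
  const R_xlen_t m = coords.nrow();
  NumericVector out(m);
  const double* p = img.begin();
  for (R_xlen_t i = 0; i < m; ++i) {
    const double fx = coords(i, 0), fy = coords(i, 1), fz = coords(i, 2);
    const int x0 = (int)std::floor(fx), y0 = (int)std::floor(fy), z0 = (int)std::floor(fz);
    const double wx = fx - x0, wy = fy - y0, wz = fz - z0;
    double acc = 0.0;
    for (int dz = 0; dz < 2; ++dz)
    for (int dy = 0; dy < 2; ++dy)
    for (int dx = 0; dx < 2; ++dx) {
      const int xx = x0 + dx, yy = y0 + dy, zz = z0 + dz;
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
      const double wgt = (dx ? wx : 1 - wx) * (dy ? wy : 1 - wy) * (dz ? wz : 1 - wz);
      acc += wgt * p[xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)];
    }
    out[i] = acc;
  }
  return out;
}

// Backward pass of sample3d_fw: gradients w.r.t. the image (scatter-add)
// and w.r.t. the coordinates (spatial derivative of the interpolant).
// [[Rcpp::export]]
List sample3d_bw(NumericVector img, NumericMatrix coords, NumericVector gout) {
  IntegerVector d = img.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2];
  const R_xlen_t m = coords.nrow();
  NumericVector gimg((R_xlen_t)nx * ny * nz);
  gimg.attr("dim") = IntegerVector::create(nx, ny, nz);
  NumericMatrix gcoords(m, 3);
  const double* p = img.begin();
  double* gp = gimg.begin();
  for (R_xlen_t i = 0; i < m; ++i) {
    const double g = gout[i];
    const double fx = coords(i, 0), fy = coords(i, 1), fz = coords(i, 2);
    const int x0 = (int)std::floor(fx), y0 = (int)std::floor(fy), z0 = (int)std::floor(fz);
    const double wx = fx - x0, wy = fy - y0, wz = fz - z0;
    double gx = 0.0, gy = 0.0, gz = 0.0;
    for (int dz = 0; dz < 2; ++dz)
    for (int dy = 0; dy < 2; ++dy)
    for (int dx = 0; dx < 2; ++dx) {
      const int xx = x0 + dx, yy = y0 + dy, zz = z0 + dz;
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
      const double ax = dx ? wx : 1 - wx, ay = dy ? wy : 1 - wy, az = dz ? wz : 1 - wz;
      const double sx = dx ? 1.0 : -1.0, sy = dy ? 1.0 : -1.0, sz = dz ? 1.0 : -1.0;
      const R_xlen_t idx = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
      const double v = p[idx];
      gp[idx] += g * ax * ay * az;
      gx += sx * ay * az * v;
      gy += ax * sy * az * v;
      gz += ax * ay * sz * v;
    }
    gcoords(i, 0) = g * gx;
    gcoords(i, 1) = g * gy;
    gcoords(i, 2) = g * gz;
  }
  return List::create(_["gimg"] = gimg, _["gcoords"] = gcoords);
}

static inline int sym_index(int i, int n) {
  // half-sample symmetric reflection: ... b a | a b c ... | c b ...
  while (i < 0 || i >= n) {
    if (i < 0) i = -1 - i;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// 1D kernel applied along one axis of a 3D array with symmetric padding.
// transpose = true applies the adjoint (scatter), used in backprop.
// [[Rcpp::export]]
NumericVector sepconv3d_axis(NumericVector x, NumericVector kernel, int axis, bool transpose) {
  IntegerVector d = x.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2];
  const int k = kernel.size();
  const int ofs = (k - 1) / 2;
  NumericVector out((R_xlen_t)nx * ny * nz);
  out.attr("dim") = IntegerVector::create(nx, ny, nz);
  const double* px = x.begin();
  double* po = out.begin();
  const int n[3] = {nx, ny, nz};
  const R_xlen_t strides[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  const int na = n[axis];
  const R_xlen_t sa = strides[axis];
  // iterate over all lines along `axis`
  const int b1 = (axis == 0) ? 1 : 0;
  const int b2 = (axis == 2) ? 1 : 2;
  for (int j2 = 0; j2 < n[b2]; ++j2)
  for (int j1 = 0; j1 < n[b1]; ++j1) {
    const R_xlen_t base = (R_xlen_t)j1 * strides[b1] + (R_xlen_t)j2 * strides[b2];
    for (int i = 0; i < na; ++i) {
      if (!transpose) {
        double acc = 0.0;
        for (int t = 0; t < k; ++t)
          acc += kernel[t] * px[base + (R_xlen_t)sym_index(i + t - ofs, na) * sa];
        po[base + (R_xlen_t)i * sa] = acc;
      } else {
        const double g = px[base + (R_xlen_t)i * sa];
        for (int t = 0; t < k; ++t)
          po[base + (R_xlen_t)sym_index(i + t - ofs, na) * sa] += kernel[t] * g;
      }
    }
  }
  return out;
}
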