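// Performance-critical fused kernels: direct 3x3x3 convolution (forward,
// input-gradient, weight-gradient), uniform box smoothing via running sums,
// and the displacement-field penalties with their gradients.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline int cout_size(int n, int stride) { return (n - 1) / stride + 1; }

// Direct 3D convolution, kernel 3, pad 1.  Loops are arranged so the
// innermost x-loop is unit-stride on both input and output for stride 1.
// [[Rcpp::export]]
NumericVector conv3d_direct_fw(NumericVector x, NumericVector w,
                               NumericVector b, int stride) {
  IntegerVector d = x.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2], Ci = (d.size() > 3) ? d[3] : 1;
  IntegerVector dw = w.attr("dim");
  const int Co = dw[4];
  const int ox = cout_size(nx, stride), oy = cout_size(ny, stride),
            oz = cout_size(nz, stride);
  const R_xlen_t nout = (R_xlen_t)ox * oy * oz;
  NumericVector y(nout * Co);
  y.attr("dim") = IntegerVector::create(ox, oy, oz, Co);
  const double* px = x.begin();
  const double* pw = w.begin();
  double* py = y.begin();
  for (int co = 0; co < Co; ++co) {
    double* yc = py + (R_xlen_t)co * nout;
    const double bc = b[co];
    for (R_xlen_t i = 0; i < nout; ++i) yc[i] = bc;
    for (int ci = 0; ci < Ci; ++ci) {
      const double* xc = px + (R_xlen_t)ci * nx * ny * nz;
      const double* wc = pw + 27 * ((R_xlen_t)ci + (R_xlen_t)Ci * co);
      for (int kz = 0; kz < 3; ++kz)
      for (int ky = 0; ky < 3; ++ky)
      for (int kx = 0; kx < 3; ++kx) {
        const double wv = wc[kx + 3 * (ky + 3 * kz)];
        if (wv == 0.0) continue;
        for (int izo = 0; izo < oz; ++izo) {
          const int iz = izo * stride + kz - 1;
          if (iz < 0 || iz >= nz) continue;
          for (int iyo = 0; iyo < oy; ++iyo) {
            const int iy = iyo * stride + ky - 1;
            if (iy < 0 || iy >= ny) continue;
            const double* src = xc + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
            double* dst = yc + (R_xlen_t)ox * (iyo + (R_xlen_t)oy * izo);
            int lo = 0, hi = ox;
            while (lo < ox && lo * stride + kx - 1 < 0) ++lo;
            while (hi > lo && (hi - 1) * stride + kx - 1 >= nx) --hi;
            if (stride == 1) {
              const double* s2 = src + kx - 1;
              for (int i = lo; i < hi; ++i) dst[i] += wv * s2[i];
            } else {
              for (int i = lo; i < hi; ++i)
                dst[i] += wv * src[i * stride + kx - 1];
            }
          }
        }
      }
    }
  }
  return y;
}

// gradient w.r.t. the input: scatter gy back through the taps
// [[Rcpp::export]]
NumericVector conv3d_direct_bwx(IntegerVector in_dim, NumericVector w,
                                NumericVector gy, int stride) {
  const int nx = in_dim[0], ny = in_dim[1], nz = in_dim[2], Ci = in_dim[3];
  IntegerVector dw = w.attr("dim");
  const int Co = dw[4];
  const int ox = cout_size(nx, stride), oy = cout_size(ny, stride),
            oz = cout_size(nz, stride);
  const R_xlen_t nout = (R_xlen_t)ox * oy * oz;
  NumericVector gx((R_xlen_t)nx * ny * nz * Ci);
  gx.attr("dim") = in_dim;
  const double* pg = gy.begin();
  const double* pw = w.begin();
  double* pgx = gx.begin();
  for (int co = 0; co < Co; ++co) {
    const double* gc = pg + (R_xlen_t)co * nout;
    for (int ci = 0; ci < Ci; ++ci) {
      double* xc = pgx + (R_xlen_t)ci * nx * ny * nz;
      const double* wc = pw + 27 * ((R_xlen_t)ci + (R_xlen_t)Ci * co);
      for (int kz = 0; kz < 3; ++kz)
      for (int ky = 0; ky < 3; ++ky)
      for (int kx = 0; kx < 3; ++kx) {
        const double wv = wc[kx + 3 * (ky + 3 * kz)];
        if (wv == 0.0) continue;
        for (int izo = 0; izo < oz; ++izo) {
          const int iz = izo * stride + kz - 1;
          if (iz < 0 || iz >= nz) continue;
          for (int iyo = 0; iyo < oy; ++iyo) {
            const int iy = iyo * stride + ky - 1;
            if (iy < 0 || iy >= ny) continue;
            const double* src = gc + (R_xlen_t)ox * (iyo + (R_xlen_t)oy * izo);
            double* dst = xc + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
            int lo = 0, hi = ox;
            while (lo < ox && lo * stride + kx - 1 < 0) ++lo;
            while (hi > lo && (hi - 1) * stride + kx - 1 >= nx) --hi;
            if (stride == 1) {
              double* d2 = dst + kx - 1;
              for (int i = lo; i < hi; ++i) d2[i] += wv * src[i];
            } else {
              for (int i = lo; i < hi; ++i)
                dst[i * stride + kx - 1] += wv * src[i];
            }
          }
        }
      }
    }
  }
  return gx;
}

// gradients w.r.t. weights and bias
// [[Rcpp::export]]
List conv3d_direct_bww(NumericVector x, NumericVector gy, int stride, int Co) {
  IntegerVector d = x.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2], Ci = (d.size() > 3) ? d[3] : 1;
  const int ox = cout_size(nx, stride), oy = cout_size(ny, stride),
            oz = cout_size(nz, stride);
  const R_xlen_t nout = (R_xlen_t)ox * oy * oz;
  NumericVector gw((R_xlen_t)27 * Ci * Co);
  gw.attr("dim") = IntegerVector::create(3, 3, 3, Ci, Co);
  NumericVector gb(Co);
  const double* px = x.begin();
  const double* pg = gy.begin();
  double* pgw = gw.begin();
  for (int co = 0; co < Co; ++co) {
    const double* gc = pg + (R_xlen_t)co * nout;
    double acc = 0.0;
    for (R_xlen_t i = 0; i < nout; ++i) acc += gc[i];
    gb[co] = acc;
    for (int ci = 0; ci < Ci; ++ci) {
      const double* xc = px + (R_xlen_t)ci * nx * ny * nz;
      double* wc = pgw + 27 * ((R_xlen_t)ci + (R_xlen_t)Ci * co);
      for (int kz = 0; kz < 3; ++kz)
      for (int ky = 0; ky < 3; ++ky)
      for (int kx = 0; kx < 3; ++kx) {
        double wacc = 0.0;
        for (int izo = 0; izo < oz; ++izo) {
          const int iz = izo * stride + kz - 1;
          if (iz < 0 || iz >= nz) continue;
          for (int iyo = 0; iyo < oy; ++iyo) {
            const int iy = iyo * stride + ky - 1;
            if (iy < 0 || iy >= ny) continue;
            const double* src = xc + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
            const double* g2 = gc + (R_xlen_t)ox * (iyo + (R_xlen_t)oy * izo);
            int lo = 0, hi = ox;
            while (lo < ox && lo * stride + kx - 1 < 0) ++lo;
            while (hi > lo && (hi - 1) * stride + kx - 1 >= nx) --hi;
            if (stride == 1) {
              const double* s2 = src + kx - 1;
              for (int i = lo; i < hi; ++i) wacc += g2[i] * s2[i];
            } else {
              for (int i = lo; i < hi; ++i)
                wacc += g2[i] * src[i * stride + kx - 1];
            }
          }
        }
        wc[kx + 3 * (ky + 3 * kz)] = wacc;
      }
    }
  }
  return List::create(_["gw"] = gw, _["gb"] = gb);
}

static inline int sym_ix(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -1 - i;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// Uniform box filter (kernel k, stride 1, symmetric padding) along one axis,
// running-sum interior with explicit borders; transpose = adjoint.
// [[Rcpp::export]]
NumericVector boxblur3d_axis(NumericVector x, int k, int axis, bool transpose) {
  IntegerVector d = x.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2];
  const int ofs = (k - 1) / 2;
  const double inv = 1.0 / k;
  NumericVector out((R_xlen_t)nx * ny * nz);
  out.attr("dim") = d;
  const double* px = x.begin();
  double* po = out.begin();
  const int n[3] = {nx, ny, nz};
  const R_xlen_t strides[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  const int na = n[axis];
  const R_xlen_t sa = strides[axis];
  const int b1 = (axis == 0) ? 1 : 0;
  const int b2 = (axis == 2) ? 1 : 2;
  // interior positions where the whole window is in-range
  const int ilo = ofs, ihi = na - (k - 1 - ofs);   // [ilo, ihi)
  std::vector<double> line(na), res(na);
  for (int j2 = 0; j2 < n[b2]; ++j2)
  for (int j1 = 0; j1 < n[b1]; ++j1) {
    const R_xlen_t base = (R_xlen_t)j1 * strides[b1] + (R_xlen_t)j2 * strides[b2];
    for (int i = 0; i < na; ++i) line[i] = px[base + (R_xlen_t)i * sa];
    if (!transpose) {
      if (ilo < ihi) {
        double s = 0.0;
        for (int t = 0; t < k; ++t) s += line[ilo - ofs + t];
        res[ilo] = s * inv;
        for (int i = ilo + 1; i < ihi; ++i) {
          s += line[i - ofs + k - 1] - line[i - ofs - 1];
          res[i] = s * inv;
        }
      }
      for (int i = 0; i < std::min(ilo, na); ++i) {
        double s = 0.0;
        for (int t = 0; t < k; ++t) s += line[sym_ix(i + t - ofs, na)];
        res[i] = s * inv;
      }
      for (int i = std::max(ihi, 0); i < na; ++i) {
        double s = 0.0;
        for (int t = 0; t < k; ++t) s += line[sym_ix(i + t - ofs, na)];
        res[i] = s * inv;
      }
    } else {
      std::fill(res.begin(), res.end(), 0.0);
      // adjoint of the interior part is a box filter with mirrored offset
      for (int i = std::max(ilo, 0); i < ihi; ++i) {
        const double g = line[i] * inv;
        // contributes to gin[i-ofs .. i-ofs+k-1]; accumulate via scatter
        for (int t = 0; t < k; ++t) res[i - ofs + t] += g;
      }
      for (int i = 0; i < std::min(ilo, na); ++i) {
        const double g = line[i] * inv;
        for (int t = 0; t < k; ++t) res[sym_ix(i + t - ofs, na)] += g;
      }
      for (int i = std::max(ihi, 0); i < na; ++i) {
        const double g = line[i] * inv;
        for (int t = 0; t < k; ++t) res[sym_ix(i + t - ofs, na)] += g;
      }
    }
    for (int i = 0; i < na; ++i) po[base + (R_xlen_t)i * sa] = res[i];
  }
  return out;
}

// Smoothness, folding and magnitude penalties of a displacement field with
// their combined weighted gradient, fused in one pass-friendly routine.
// [[Rcpp::export]]
List field_penalties(NumericVector field, double w_smooth, double w_fold,
                     double w_mag) {
  IntegerVector d = field.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector grad(nvox * 3);
  grad.attr("dim") = d;
  const double* u = field.begin();
  double* g = grad.begin();
  const R_xlen_t strides[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  const int n[3] = {nx, ny, nz};

  // ---- magnitude: mean ||u||^2
  double mag = 0.0;
  for (R_xlen_t i = 0; i < nvox * 3; ++i) mag += u[i] * u[i];
  mag /= nvox;
  if (w_mag != 0.0)
    for (R_xlen_t i = 0; i < nvox * 3; ++i) g[i] += w_mag * 2.0 * u[i] / nvox;

  // ---- smoothness: mean over (voxel site, axis) of ||forward diff||^2
  double nsites = 0.0;
  for (int ax = 0; ax < 3; ++ax) nsites += (double)nvox / n[ax] * (n[ax] - 1);
  double smooth = 0.0;
  for (int c = 0; c < 3; ++c) {
    const double* uc = u + c * nvox;
    double* gc = g + c * nvox;
    for (int ax = 0; ax < 3; ++ax) {
      const R_xlen_t sa = strides[ax];
      for (int iz = 0; iz < nz; ++iz)
      for (int iy = 0; iy < ny; ++iy)
      for (int ix = 0; ix < nx; ++ix) {
        const int ia = (ax == 0) ? ix : (ax == 1) ? iy : iz;
        if (ia >= n[ax] - 1) continue;
        const R_xlen_t idx = ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
        const double df = uc[idx + sa] - uc[idx];
        smooth += df * df;
        if (w_smooth != 0.0) {
          const double t = w_smooth * 2.0 * df / nsites;
          gc[idx + sa] += t;
          gc[idx] -= t;
        }
      }
    }
  }
  smooth /= nsites;

  // ---- folding: mean over interior voxels of max(0, -det(I + grad u))
  double fold = 0.0;
  const int mx = nx - 1, my = ny - 1, mz = nz - 1;
  if (mx > 0 && my > 0 && mz > 0) {
    const R_xlen_t mtot = (R_xlen_t)mx * my * mz;
    for (int iz = 0; iz < mz; ++iz)
    for (int iy = 0; iy < my; ++iy)
    for (int ix = 0; ix < mx; ++ix) {
      const R_xlen_t idx = ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
      double J[3][3];
      for (int c = 0; c < 3; ++c) {
        const double* uc = u + c * nvox;
        const double u0 = uc[idx];
        J[c][0] = uc[idx + 1] - u0 + (c == 0);
        J[c][1] = uc[idx + strides[1]] - u0 + (c == 1);
        J[c][2] = uc[idx + strides[2]] - u0 + (c == 2);
      }
      const double det =
        J[0][0] * (J[1][1] * J[2][2] - J[1][2] * J[2][1]) -
        J[0][1] * (J[1][0] * J[2][2] - J[1][2] * J[2][0]) +
        J[0][2] * (J[1][0] * J[2][1] - J[1][1] * J[2][0]);
      if (det < 0) {
        fold += -det;
        if (w_fold != 0.0) {
          double C[3][3];
          C[0][0] = J[1][1] * J[2][2] - J[1][2] * J[2][1];
          C[0][1] = -(J[1][0] * J[2][2] - J[1][2] * J[2][0]);
          C[0][2] = J[1][0] * J[2][1] - J[1][1] * J[2][0];
          C[1][0] = -(J[0][1] * J[2][2] - J[0][2] * J[2][1]);
          C[1][1] = J[0][0] * J[2][2] - J[0][2] * J[2][0];
          C[1][2] = -(J[0][0] * J[2][1] - J[0][1] * J[2][0]);
          C[2][0] = J[0][1] * J[1][2] - J[0][2] * J[1][1];
          C[2][1] = -(J[0][0] * J[1][2] - J[0][2] * J[1][0]);
          C[2][2] = J[0][0] * J[1][1] - J[0][1] * J[1][0];
          for (int c = 0; c < 3; ++c) {
            double* gc = g + c * nvox;
            for (int dd = 0; dd < 3; ++dd) {
              const double gj = -w_fold * C[c][dd] / mtot;
              gc[idx + strides[dd]] += gj;
              gc[idx] -= gj;
            }
          }
        }
      }
    }
    fold /= mtot;
  }
  return List::create(_["smoothness"] = smooth, _["folding"] = fold,
                      _["magnitude"] = mag, _["grad"] = grad);
}

// [[Rcpp::export]]
NumericVector lrelu_fw_cpp(NumericVector x, double slope) {
  NumericVector y = clone(x);
  double* p = y.begin();
  const R_xlen_t n = y.size();
  for (R_xlen_t i = 0; i < n; ++i) if (p[i] < 0) p[i] *= slope;
  return y;
}

// gradient through leaky ReLU, recovered from the cached output (slope > 0
// keeps the sign, so y < 0 iff x < 0)
// [[Rcpp::export]]
NumericVector lrelu_bw_cpp(NumericVector y, NumericVector gy, double slope) {
  NumericVector gx = clone(gy);
  double* p = gx.begin();
  const double* q = y.begin();
  const R_xlen_t n = gx.size();
  for (R_xlen_t i = 0; i < n; ++i) if (q[i] < 0) p[i] *= slope;
  return gx;
}
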