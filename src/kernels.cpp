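// Low-level numeric kernels for the 3D segmentation networks and image ops.
//
// Tensor layout: numeric 4D arrays dim = (D, H, W, C), column-major, so the
// z (slice) index varies fastest. Convolution weights: dim = (k, k, k, Cin,
// Cout). Convolutions are lowered to im2col + GEMM; the matrix products
// themselves happen in R through the BLAS.

#include <Rcpp.h>
#include <cmath>
#include <cstring>
using namespace Rcpp;

static inline R_xlen_t idx4(int z, int y, int x, int c, int D, int H, int W) {
  return z + (R_xlen_t)D * (y + (R_xlen_t)H * (x + (R_xlen_t)W * c));
}

// Unfold zero-padded k x k x k neighbourhoods ("same" padding, stride 1)
// into a (D*H*W) x (k^3 * cin) matrix. Column index = kz + k*(ky + k*(kx +
// k*ci)), matching the column-major flattening of the weight array.
// [[Rcpp::export(name = ".im2col3d")]]
NumericMatrix im2col3d(NumericVector x, IntegerVector xdim, int k, int cin) {
  const int D = xdim[0], H = xdim[1], W = xdim[2];
  const int p = k / 2;
  const R_xlen_t N = (R_xlen_t)D * H * W;
  NumericMatrix out(N, (R_xlen_t)k * k * k * cin);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int ci = 0; ci < cin; ++ci)
    for (int kx = 0; kx < k; ++kx)
      for (int ky = 0; ky < k; ++ky)
        for (int kz = 0; kz < k; ++kz) {
          const int col = kz + k * (ky + k * (kx + k * ci));
          double* dst_col = op + (R_xlen_t)col * N;
          const int dz = kz - p, dy = ky - p, dx = kx - p;
          const int x0 = std::max(0, -dx), x1 = std::min(W, W - dx);
          const int y0 = std::max(0, -dy), y1 = std::min(H, H - dy);
          const int z0 = std::max(0, -dz), z1 = std::min(D, D - dz);
          for (int xx = x0; xx < x1; ++xx)
            for (int yy = y0; yy < y1; ++yy) {
              const double* src = xp + idx4(z0 + dz, yy + dy, xx + dx, ci, D, H, W);
              double* dst = dst_col + idx4(z0, yy, xx, 0, D, H, W);
              std::memcpy(dst, src, sizeof(double) * (z1 - z0));
            }
        }
  return out;
}

// Fold a (D*H*W) x (k^3 * cin) matrix back onto the input grid by
// scatter-add; the adjoint of im2col3d. Returns a (D, H, W, cin) tensor.
// [[Rcpp::export(name = ".col2im3d")]]
NumericVector col2im3d(NumericMatrix cols, IntegerVector xdim, int k, int cin) {
  const int D = xdim[0], H = xdim[1], W = xdim[2];
  const int p = k / 2;
  const R_xlen_t N = (R_xlen_t)D * H * W;
  NumericVector out(N * cin);
  const double* cp = cols.begin();
  double* op = out.begin();
  for (int ci = 0; ci < cin; ++ci)
    for (int kx = 0; kx < k; ++kx)
      for (int ky = 0; ky < k; ++ky)
        for (int kz = 0; kz < k; ++kz) {
          const int col = kz + k * (ky + k * (kx + k * ci));
          const double* src_col = cp + (R_xlen_t)col * N;
          const int dz = kz - p, dy = ky - p, dx = kx - p;
          const int x0 = std::max(0, -dx), x1 = std::min(W, W - dx);
          const int y0 = std::max(0, -dy), y1 = std::min(H, H - dy);
          const int z0 = std::max(0, -dz), z1 = std::min(D, D - dz);
          for (int xx = x0; xx < x1; ++xx)
            for (int yy = y0; yy < y1; ++yy) {
              const double* src = src_col + idx4(z0, yy, xx, 0, D, H, W);
              double* dst = op + idx4(z0 + dz, yy + dy, xx + dx, ci, D, H, W);
              const int n = z1 - z0;
              for (int zz = 0; zz < n; ++zz) dst[zz] += src[zz];
            }
        }
  return out;
}

// 2x2x2 max pooling. Returns pooled values and 1-based argmax indices into
// the input (for the backward pass).
// [[Rcpp::export(name = ".maxpool3d_fw")]]
List maxpool3d_fw(NumericVector x, IntegerVector xdim, int ch) {
  const int D = xdim[0], H = xdim[1], W = xdim[2];
  const int Do = D / 2, Ho = H / 2, Wo = W / 2;
  NumericVector out((R_xlen_t)Do * Ho * Wo * ch);
  IntegerVector amax(out.size());
  const double* xp = x.begin();
  double* op = out.begin();
  int* ap = amax.begin();
  for (int c = 0; c < ch; ++c)
    for (int xo = 0; xo < Wo; ++xo)
      for (int yo = 0; yo < Ho; ++yo) {
        R_xlen_t obase = idx4(0, yo, xo, c, Do, Ho, Wo);
        for (int zo = 0; zo < Do; ++zo) {
          double best = -1e300; R_xlen_t bi = -1;
          for (int dx = 0; dx < 2; ++dx)
            for (int dy = 0; dy < 2; ++dy) {
              R_xlen_t base = idx4(2 * zo, 2 * yo + dy, 2 * xo + dx, c, D, H, W);
              for (int dz = 0; dz < 2; ++dz)
                if (xp[base + dz] > best) { best = xp[base + dz]; bi = base + dz; }
            }
          op[obase + zo] = best;
          ap[obase + zo] = (int)(bi + 1);
        }
      }
  return List::create(_["out"] = out, _["argmax"] = amax);
}

// [[Rcpp::export(name = ".maxpool3d_bw")]]
NumericVector maxpool3d_bw(NumericVector gout, IntegerVector amax, R_xlen_t n_in) {
  NumericVector gin(n_in);
  double* ip = gin.begin();
  const double* gp = gout.begin();
  const int* ap = amax.begin();
  for (R_xlen_t i = 0; i < gout.size(); ++i) ip[ap[i] - 1] += gp[i];
  return gin;
}

// Linear (trilinear when all factors are 2) upsampling by per-axis integer
// factors in {1, 2}, half-pixel convention with edge clamping. Per-axis
// source indices and weights are precomputed.
struct AxisMap {
  std::vector<int> i0, i1;
  std::vector<double> w1;
};

static AxisMap axis_map(int n_src, int f) {
  AxisMap m;
  const int n_dst = n_src * f;
  m.i0.resize(n_dst); m.i1.resize(n_dst); m.w1.resize(n_dst);
  for (int d = 0; d < n_dst; ++d) {
    if (f == 1) { m.i0[d] = d; m.i1[d] = d; m.w1[d] = 0.0; continue; }
    double s = (d + 0.5) / f - 0.5;
    if (s < 0) s = 0;
    if (s > n_src - 1) s = n_src - 1;
    int i0 = (int)std::floor(s);
    m.i0[d] = i0;
    m.i1[d] = std::min(i0 + 1, n_src - 1);
    m.w1[d] = s - i0;
  }
  return m;
}

// [[Rcpp::export(name = ".upsample3d_fw")]]
NumericVector upsample3d_fw(NumericVector x, IntegerVector xdim, int ch,
                            int fz, int fy, int fx) {
  const int D = xdim[0], H = xdim[1], W = xdim[2];
  const int Do = D * fz, Ho = H * fy, Wo = W * fx;
  NumericVector out((R_xlen_t)Do * Ho * Wo * ch);
  const double* xp = x.begin();
  double* op = out.begin();
  AxisMap mz = axis_map(D, fz), my = axis_map(H, fy), mx = axis_map(W, fx);
  for (int c = 0; c < ch; ++c)
    for (int xo = 0; xo < Wo; ++xo) {
      const double wx = mx.w1[xo];
      for (int yo = 0; yo < Ho; ++yo) {
        const double wy = my.w1[yo];
        const double* s00 = xp + idx4(0, my.i0[yo], mx.i0[xo], c, D, H, W);
        const double* s10 = xp + idx4(0, my.i1[yo], mx.i0[xo], c, D, H, W);
        const double* s01 = xp + idx4(0, my.i0[yo], mx.i1[xo], c, D, H, W);
        const double* s11 = xp + idx4(0, my.i1[yo], mx.i1[xo], c, D, H, W);
        const double c00 = (1 - wy) * (1 - wx), c10 = wy * (1 - wx);
        const double c01 = (1 - wy) * wx, c11 = wy * wx;
        double* dst = op + idx4(0, yo, xo, c, Do, Ho, Wo);
        for (int zo = 0; zo < Do; ++zo) {
          const int z0 = mz.i0[zo], z1 = mz.i1[zo];
          const double wz = mz.w1[zo];
          const double v0 = c00 * s00[z0] + c10 * s10[z0] + c01 * s01[z0] + c11 * s11[z0];
          const double v1 = c00 * s00[z1] + c10 * s10[z1] + c01 * s01[z1] + c11 * s11[z1];
          dst[zo] = (1 - wz) * v0 + wz * v1;
        }
      }
    }
  return out;
}

// [[Rcpp::export(name = ".upsample3d_bw")]]
NumericVector upsample3d_bw(NumericVector gout, IntegerVector xdim, int ch,
                            int fz, int fy, int fx) {
  const int D = xdim[0], H = xdim[1], W = xdim[2];
  const int Do = D * fz, Ho = H * fy, Wo = W * fx;
  NumericVector gin((R_xlen_t)D * H * W * ch);
  const double* gp = gout.begin();
  double* ip = gin.begin();
  AxisMap mz = axis_map(D, fz), my = axis_map(H, fy), mx = axis_map(W, fx);
  for (int c = 0; c < ch; ++c)
    for (int xo = 0; xo < Wo; ++xo) {
      const double wx = mx.w1[xo];
      for (int yo = 0; yo < Ho; ++yo) {
        const double wy = my.w1[yo];
        double* d00 = ip + idx4(0, my.i0[yo], mx.i0[xo], c, D, H, W);
        double* d10 = ip + idx4(0, my.i1[yo], mx.i0[xo], c, D, H, W);
        double* d01 = ip + idx4(0, my.i0[yo], mx.i1[xo], c, D, H, W);
        double* d11 = ip + idx4(0, my.i1[yo], mx.i1[xo], c, D, H, W);
        const double c00 = (1 - wy) * (1 - wx), c10 = wy * (1 - wx);
        const double c01 = (1 - wy) * wx, c11 = wy * wx;
        const double* src = gp + idx4(0, yo, xo, c, Do, Ho, Wo);
        for (int zo = 0; zo < Do; ++zo) {
          const int z0 = mz.i0[zo], z1 = mz.i1[zo];
          const double wz = mz.w1[zo];
          const double g0 = (1 - wz) * src[zo], g1 = wz * src[zo];
          d00[z0] += c00 * g0; d10[z0] += c10 * g0;
          d01[z0] += c01 * g0; d11[z0] += c11 * g0;
          if (g1 != 0.0) {
            d00[z1] += c00 * g1; d10[z1] += c10 * g1;
            d01[z1] += c01 * g1; d11[z1] += c11 * g1;
          }
        }
      }
    }
  return gin;
}

// In-plane block-mean downscaling of a (D, H, W) volume by integer factor.
// [[Rcpp::export(name = ".blockmean_xy")]]
NumericVector blockmean_xy(NumericVector x, IntegerVector xdim, int f) {
  const int D = xdim[0], H = xdim[1], W = xdim[2];
  const int Ho = H / f, Wo = W / f;
  NumericVector out((R_xlen_t)D * Ho * Wo);
  const double* xp = x.begin();
  double* op = out.begin();
  const double inv = 1.0 / (f * f);
  for (int xo = 0; xo < Wo; ++xo)
    for (int yo = 0; yo < Ho; ++yo) {
      double* dst = op + (R_xlen_t)D * (yo + (R_xlen_t)Ho * xo);
      std::memset(dst, 0, sizeof(double) * D);
      for (int dx = 0; dx < f; ++dx)
        for (int dy = 0; dy < f; ++dy) {
          const double* src = xp + (R_xlen_t)D * ((f * yo + dy) + (R_xlen_t)H * (f * xo + dx));
          for (int z = 0; z < D; ++z) dst[z] += src[z];
        }
      for (int z = 0; z < D; ++z) dst[z] *= inv;
    }
  return out;
}

// In-plane resize of a (D, H, W) volume to (D, Ho, Wo).
// method 0 = bilinear (half-pixel, clamped), 1 = nearest neighbour.
// [[Rcpp::export(name = ".resize_xy")]]
NumericVector resize_xy(NumericVector x, IntegerVector xdim, int Ho, int Wo, int method) {
  const int D = xdim[0], H = xdim[1], W = xdim[2];
  NumericVector out((R_xlen_t)D * Ho * Wo);
  const double* xp = x.begin();
  double* op = out.begin();
  const double sy = (double)H / Ho, sx = (double)W / Wo;
  for (int xo = 0; xo < Wo; ++xo) {
    double fx = (xo + 0.5) * sx - 0.5;
    for (int yo = 0; yo < Ho; ++yo) {
      double fy = (yo + 0.5) * sy - 0.5;
      double* dst = op + (R_xlen_t)D * (yo + (R_xlen_t)Ho * xo);
      if (method == 1) {
        int yi = std::min(H - 1, std::max(0, (int)std::lround(fy)));
        int xi = std::min(W - 1, std::max(0, (int)std::lround(fx)));
        std::memcpy(dst, xp + (R_xlen_t)D * (yi + (R_xlen_t)H * xi), sizeof(double) * D);
      } else {
        double cy = std::min((double)(H - 1), std::max(0.0, fy));
        double cx = std::min((double)(W - 1), std::max(0.0, fx));
        int y0 = (int)std::floor(cy), x0 = (int)std::floor(cx);
        int y1 = std::min(y0 + 1, H - 1), x1 = std::min(x0 + 1, W - 1);
        double wy = cy - y0, wx = cx - x0;
        const double* s00 = xp + (R_xlen_t)D * (y0 + (R_xlen_t)H * x0);
        const double* s10 = xp + (R_xlen_t)D * (y1 + (R_xlen_t)H * x0);
        const double* s01 = xp + (R_xlen_t)D * (y0 + (R_xlen_t)H * x1);
        const double* s11 = xp + (R_xlen_t)D * (y1 + (R_xlen_t)H * x1);
        for (int z = 0; z < D; ++z)
          dst[z] = (1 - wy) * (1 - wx) * s00[z] + wy * (1 - wx) * s10[z] +
                   (1 - wy) * wx * s01[z] + wy * wx * s11[z];
      }
    }
  }
  return out;
}
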