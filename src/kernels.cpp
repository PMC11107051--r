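// Low-level numerical kernels for the autodiff engine and metrics.
//
// Tensor memory layout throughout: a dense array with dim = (C, Z, Y, X),
// i.e. channel fastest, then z (slices), then y, then x. Spatial positions
// are enumerated z-fastest so that a (C x P) matrix reshapes directly into
// (C, Z, Y, X).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline int out_dim(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

// Unfold a (C,Z,Y,X) array into a (C*kz*ky*kx) x (Zo*Yo*Xo) matrix with
// zero padding. Row index r = c + C*(dz + kz*(dy + ky*dx)); column index
// p = zo + Zo*(yo + Yo*xo). Convolution is then W (Cout x K) %*% cols.
// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, IntegerVector dims,
                         IntegerVector ksize, IntegerVector stride,
                         IntegerVector pad) {
  const int C = dims[0], Z = dims[1], Y = dims[2], X = dims[3];
  const int kz = ksize[0], ky = ksize[1], kx = ksize[2];
  const int sz = stride[0], sy = stride[1], sx = stride[2];
  const int pz = pad[0], py = pad[1], px = pad[2];
  const int Zo = out_dim(Z, kz, sz, pz), Yo = out_dim(Y, ky, sy, py),
            Xo = out_dim(X, kx, sx, px);
  const int K = C * kz * ky * kx, P = Zo * Yo * Xo;
  NumericMatrix cols(K, P);
  const double* xp = x.begin();
  double* cp = cols.begin();
  for (int xo = 0; xo < Xo; ++xo) {
    for (int yo = 0; yo < Yo; ++yo) {
      for (int zo = 0; zo < Zo; ++zo) {
        const int p = zo + Zo * (yo + Yo * xo);
        double* col = cp + (R_xlen_t)p * K;
        for (int dx = 0; dx < kx; ++dx) {
          const int xi = xo * sx - px + dx;
          for (int dy = 0; dy < ky; ++dy) {
            const int yi = yo * sy - py + dy;
            for (int dz = 0; dz < kz; ++dz) {
              const int zi = zo * sz - pz + dz;
              double* dst = col + C * (dz + kz * (dy + ky * dx));
              if (zi < 0 || zi >= Z || yi < 0 || yi >= Y || xi < 0 || xi >= X) {
                for (int c = 0; c < C; ++c) dst[c] = 0.0;
              } else {
                const double* src = xp + (R_xlen_t)C * (zi + Z * (yi + Y * xi));
                for (int c = 0; c < C; ++c) dst[c] = src[c];
              }
            }
          }
        }
      }
    }
  }
  return cols;
}

// Adjoint of cpp_im2col: scatter column gradients back onto the input grid.
// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix cols, IntegerVector dims,
                         IntegerVector ksize, IntegerVector stride,
                         IntegerVector pad) {
  const int C = dims[0], Z = dims[1], Y = dims[2], X = dims[3];
  const int kz = ksize[0], ky = ksize[1], kx = ksize[2];
  const int sz = stride[0], sy = stride[1], sx = stride[2];
  const int pz = pad[0], py = pad[1], px = pad[2];
  const int Zo = out_dim(Z, kz, sz, pz), Yo = out_dim(Y, ky, sy, py),
            Xo = out_dim(X, kx, sx, px);
  const int K = C * kz * ky * kx;
  NumericVector out((R_xlen_t)C * Z * Y * X);
  double* op = out.begin();
  const double* cp = cols.begin();
  for (int xo = 0; xo < Xo; ++xo) {
    for (int yo = 0; yo < Yo; ++yo) {
      for (int zo = 0; zo < Zo; ++zo) {
        const int p = zo + Zo * (yo + Yo * xo);
        const double* col = cp + (R_xlen_t)p * K;
        for (int dx = 0; dx < kx; ++dx) {
          const int xi = xo * sx - px + dx;
          if (xi < 0 || xi >= X) continue;
          for (int dy = 0; dy < ky; ++dy) {
            const int yi = yo * sy - py + dy;
            if (yi < 0 || yi >= Y) continue;
            for (int dz = 0; dz < kz; ++dz) {
              const int zi = zo * sz - pz + dz;
              if (zi < 0 || zi >= Z) continue;
              const double* src = col + C * (dz + kz * (dy + ky * dx));
              double* dst = op + (R_xlen_t)C * (zi + Z * (yi + Y * xi));
              for (int c = 0; c < C; ++c) dst[c] += src[c];
            }
          }
        }
      }
    }
  }
  return out;
}

// Stride-1 "same" windowed sum along one axis (zero padding outside),
// applied in place on a working copy. axis: 0=z, 1=y, 2=x.
static void winsum_axis(std::vector<double>& v, int C, int Z, int Y, int X,
                        int k, int axis) {
  const int h = k / 2;
  int n, nlines;
  if (axis == 0) { n = Z; nlines = C * Y * X; }
  else if (axis == 1) { n = Y; nlines = C * Z * X; }
  else { n = X; nlines = C * Z * Y; }
  std::vector<double> cum(n + 1), line(n);
  for (int li = 0; li < nlines; ++li) {
    // decompose line index into the fixed coordinates, derive base + stride
    R_xlen_t base;
    R_xlen_t stride;
    if (axis == 0) {
      int c = li % C, rest = li / C, y = rest % Y, x = rest / Y;
      base = c + (R_xlen_t)C * (0 + Z * (y + (R_xlen_t)Y * x));
      stride = C;
    } else if (axis == 1) {
      int c = li % C, rest = li / C, z = rest % Z, x = rest / Z;
      base = c + (R_xlen_t)C * (z + Z * (0 + (R_xlen_t)Y * x));
      stride = (R_xlen_t)C * Z;
    } else {
      int c = li % C, rest = li / C, z = rest % Z, y = rest / Z;
      base = c + (R_xlen_t)C * (z + Z * (y + (R_xlen_t)Y * 0));
      stride = (R_xlen_t)C * Z * Y;
    }
    cum[0] = 0.0;
    for (int i = 0; i < n; ++i) cum[i + 1] = cum[i] + v[base + stride * i];
    for (int i = 0; i < n; ++i) {
      int lo = i - h; if (lo < 0) lo = 0;
      int hi = i + h + 1; if (hi > n) hi = n;
      line[i] = cum[hi] - cum[lo];
    }
    for (int i = 0; i < n; ++i) v[base + stride * i] = line[i];
  }
}

// Separable stride-1 "same" box (windowed) sum over a (C,Z,Y,X) array.
// [[Rcpp::export]]
NumericVector cpp_winsum3d(NumericVector x, IntegerVector dims,
                           IntegerVector ksize) {
  const int C = dims[0], Z = dims[1], Y = dims[2], X = dims[3];
  std::vector<double> v(x.begin(), x.end());
  if (ksize[0] > 1) winsum_axis(v, C, Z, Y, X, ksize[0], 0);
  if (ksize[1] > 1) winsum_axis(v, C, Z, Y, X, ksize[1], 1);
  if (ksize[2] > 1) winsum_axis(v, C, Z, Y, X, ksize[2], 2);
  NumericVector out(v.begin(), v.end());
  return out;
}

// Average pooling with stride == kernel (non-overlapping), dims divisible.
// [[Rcpp::export]]
NumericVector cpp_pool_down(NumericVector x, IntegerVector dims,
                            IntegerVector f) {
  const int C = dims[0], Z = dims[1], Y = dims[2], X = dims[3];
  const int fz = f[0], fy = f[1], fx = f[2];
  const int Zo = Z / fz, Yo = Y / fy, Xo = X / fx;
  const double inv = 1.0 / (fz * fy * fx);
  NumericVector out((R_xlen_t)C * Zo * Yo * Xo);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int xo = 0; xo < Xo; ++xo)
    for (int yo = 0; yo < Yo; ++yo)
      for (int zo = 0; zo < Zo; ++zo) {
        double* dst = op + (R_xlen_t)C * (zo + Zo * (yo + (R_xlen_t)Yo * xo));
        for (int dx = 0; dx < fx; ++dx)
          for (int dy = 0; dy < fy; ++dy)
            for (int dz = 0; dz < fz; ++dz) {
              const double* src = xp + (R_xlen_t)C *
                ((zo * fz + dz) + Z * ((yo * fy + dy) + (R_xlen_t)Y * (xo * fx + dx)));
              for (int c = 0; c < C; ++c) dst[c] += src[c];
            }
        for (int c = 0; c < C; ++c) dst[c] *= inv;
      }
  return out;
}

// Gradient of cpp_pool_down: replicate g/(fz*fy*fx) over each block.
// [[Rcpp::export]]
NumericVector cpp_pool_down_grad(NumericVector g, IntegerVector dims,
                                 IntegerVector f) {
  const int C = dims[0], Z = dims[1], Y = dims[2], X = dims[3];
  const int fz = f[0], fy = f[1], fx = f[2];
  const int Zo = Z / fz, Yo = Y / fy, Xo = X / fx;
  const double inv = 1.0 / (fz * fy * fx);
  NumericVector out((R_xlen_t)C * Z * Y * X);
  const double* gp = g.begin();
  double* op = out.begin();
  for (int xo = 0; xo < Xo; ++xo)
    for (int yo = 0; yo < Yo; ++yo)
      for (int zo = 0; zo < Zo; ++zo) {
        const double* src = gp + (R_xlen_t)C * (zo + Zo * (yo + (R_xlen_t)Yo * xo));
        for (int dx = 0; dx < fx; ++dx)
          for (int dy = 0; dy < fy; ++dy)
            for (int dz = 0; dz < fz; ++dz) {
              double* dst = op + (R_xlen_t)C *
                ((zo * fz + dz) + Z * ((yo * fy + dy) + (R_xlen_t)Y * (xo * fx + dx)));
              for (int c = 0; c < C; ++c) dst[c] = src[c] * inv;
            }
      }
  return out;
}

// Scatter for a non-overlapping transpose convolution with kernel == stride.
// y is (Cout*fz*fy*fx) x (Zi*Yi*Xi); output is (Cout, Zi*fz, Yi*fy, Xi*fx).
// [[Rcpp::export]]
NumericVector cpp_block_scatter(NumericMatrix y, int Cout, IntegerVector f,
                                IntegerVector sdims) {
  const int fz = f[0], fy = f[1], fx = f[2];
  const int Zi = sdims[0], Yi = sdims[1], Xi = sdims[2];
  const int Z = Zi * fz, Y = Yi * fy, X = Xi * fx;
  NumericVector out((R_xlen_t)Cout * Z * Y * X);
  double* op = out.begin();
  const double* yp = y.begin();
  const int K = Cout * fz * fy * fx;
  for (int xi = 0; xi < Xi; ++xi)
    for (int yi = 0; yi < Yi; ++yi)
      for (int zi = 0; zi < Zi; ++zi) {
        const int p = zi + Zi * (yi + Yi * xi);
        const double* col = yp + (R_xlen_t)p * K;
        for (int dx = 0; dx < fx; ++dx)
          for (int dy = 0; dy < fy; ++dy)
            for (int dz = 0; dz < fz; ++dz) {
              const double* src = col + Cout * (dz + fz * (dy + fy * dx));
              double* dst = op + (R_xlen_t)Cout *
                ((zi * fz + dz) + Z * ((yi * fy + dy) + (R_xlen_t)Y * (xi * fx + dx)));
              for (int c = 0; c < Cout; ++c) dst[c] = src[c];
            }
      }
  return out;
}

// Gather: adjoint of cpp_block_scatter.
// [[Rcpp::export]]
NumericMatrix cpp_block_gather(NumericVector g, int Cout, IntegerVector f,
                               IntegerVector sdims) {
  const int fz = f[0], fy = f[1], fx = f[2];
  const int Zi = sdims[0], Yi = sdims[1], Xi = sdims[2];
  const int Z = Zi * fz, Y = Yi * fy, X = Xi * fx;
  const int K = Cout * fz * fy * fx, P = Zi * Yi * Xi;
  NumericMatrix out(K, P);
  double* op = out.begin();
  const double* gp = g.begin();
  for (int xi = 0; xi < Xi; ++xi)
    for (int yi = 0; yi < Yi; ++yi)
      for (int zi = 0; zi < Zi; ++zi) {
        const int p = zi + Zi * (yi + Yi * xi);
        double* col = op + (R_xlen_t)p * K;
        for (int dx = 0; dx < fx; ++dx)
          for (int dy = 0; dy < fy; ++dy)
            for (int dz = 0; dz < fz; ++dz) {
              double* dst = col + Cout * (dz + fz * (dy + fy * dx));
              const double* src = gp + (R_xlen_t)Cout *
                ((zi * fz + dz) + Z * ((yi * fy + dy) + (R_xlen_t)Y * (xi * fx + dx)));
              for (int c = 0; c < Cout; ++c) dst[c] = src[c];
            }
      }
  return out;
}

struct LinW { int i0, i1; double w0, w1; };

static inline LinW lin_weights(double t, int n) {
  LinW r;
  // !(t > 0) also catches NaN; clamping keeps indices in range for any
  // (possibly non-finite) coordinate
  if (!(t > 0)) { r.i0 = 0; r.i1 = 0; r.w0 = 1; r.w1 = 0; return r; }
  if (t >= n - 1) { r.i0 = n - 1; r.i1 = n - 1; r.w0 = 1; r.w1 = 0; return r; }
  r.i0 = (int)std::floor(t); r.i1 = r.i0 + 1;
  r.w1 = t - r.i0; r.w0 = 1.0 - r.w1;
  return r;
}

// Trilinear resize (align-corners / node-centered) to a new spatial shape.
// [[Rcpp::export]]
NumericVector cpp_resize_trilinear(NumericVector x, IntegerVector dims,
                                   IntegerVector odims) {
  const int C = dims[0], Z = dims[1], Y = dims[2], X = dims[3];
  const int Zo = odims[0], Yo = odims[1], Xo = odims[2];
  const double sz = Zo > 1 ? (double)(Z - 1) / (Zo - 1) : 0.0;
  const double sy = Yo > 1 ? (double)(Y - 1) / (Yo - 1) : 0.0;
  const double sx = Xo > 1 ? (double)(X - 1) / (Xo - 1) : 0.0;
  NumericVector out((R_xlen_t)C * Zo * Yo * Xo);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int xo = 0; xo < Xo; ++xo) {
    LinW wx = lin_weights(xo * sx, X);
    for (int yo = 0; yo < Yo; ++yo) {
      LinW wy = lin_weights(yo * sy, Y);
      for (int zo = 0; zo < Zo; ++zo) {
        LinW wz = lin_weights(zo * sz, Z);
        double* dst = op + (R_xlen_t)C * (zo + Zo * (yo + (R_xlen_t)Yo * xo));
        for (int c = 0; c < C; ++c) {
          double acc = 0.0;
          for (int ax = 0; ax < 2; ++ax) {
            int xi = ax ? wx.i1 : wx.i0; double ww_x = ax ? wx.w1 : wx.w0;
            if (ww_x == 0) continue;
            for (int ay = 0; ay < 2; ++ay) {
              int yi = ay ? wy.i1 : wy.i0; double ww_y = ay ? wy.w1 : wy.w0;
              if (ww_y == 0) continue;
              for (int az = 0; az < 2; ++az) {
                int zi = az ? wz.i1 : wz.i0; double ww_z = az ? wz.w1 : wz.w0;
                if (ww_z == 0) continue;
                acc += ww_x * ww_y * ww_z *
                  xp[c + (R_xlen_t)C * (zi + Z * (yi + (R_xlen_t)Y * xi))];
              }
            }
          }
          dst[c] = acc;
        }
      }
    }
  }
  return out;
}

// Adjoint of cpp_resize_trilinear.
// [[Rcpp::export]]
NumericVector cpp_resize_trilinear_grad(NumericVector g, IntegerVector dims,
                                        IntegerVector odims) {
  const int C = dims[0], Z = dims[1], Y = dims[2], X = dims[3];
  const int Zo = odims[0], Yo = odims[1], Xo = odims[2];
  const double sz = Zo > 1 ? (double)(Z - 1) / (Zo - 1) : 0.0;
  const double sy = Yo > 1 ? (double)(Y - 1) / (Yo - 1) : 0.0;
  const double sx = Xo > 1 ? (double)(X - 1) / (Xo - 1) : 0.0;
  NumericVector out((R_xlen_t)C * Z * Y * X);
  const double* gp = g.begin();
  double* op = out.begin();
  for (int xo = 0; xo < Xo; ++xo) {
    LinW wx = lin_weights(xo * sx, X);
    for (int yo = 0; yo < Yo; ++yo) {
      LinW wy = lin_weights(yo * sy, Y);
      for (int zo = 0; zo < Zo; ++zo) {
        LinW wz = lin_weights(zo * sz, Z);
        const double* src = gp + (R_xlen_t)C * (zo + Zo * (yo + (R_xlen_t)Yo * xo));
        for (int ax = 0; ax < 2; ++ax) {
          int xi = ax ? wx.i1 : wx.i0; double ww_x = ax ? wx.w1 : wx.w0;
          if (ww_x == 0) continue;
          for (int ay = 0; ay < 2; ++ay) {
            int yi = ay ? wy.i1 : wy.i0; double ww_y = ay ? wy.w1 : wy.w0;
            if (ww_y == 0) continue;
            for (int az = 0; az < 2; ++az) {
              int zi = az ? wz.i1 : wz.i0; double ww_z = az ? wz.w1 : wz.w0;
              if (ww_z == 0) continue;
              double w = ww_x * ww_y * ww_z;
              double* dst = op + (R_xlen_t)C * (zi + Z * (yi + (R_xlen_t)Y * xi));
              for (int c = 0; c < C; ++c) dst[c] += w * src[c];
            }
          }
        }
      }
    }
  }
  return out;
}

// ---- Multi-scale deformable self-attention sampling --------------------
//
// vals: list of L feature arrays, level l with dim (d, Zl, Yl, Xl).
// loc:  (3, K, L, H, N) absolute (z,y,x) voxel coordinates per level.
// w:    (K, L, H, N) attention weights (already softmaxed over K*L).
// Head h reads channels [h*dh, (h+1)*dh). Output: (d, N).
// [[Rcpp::export]]
NumericMatrix cpp_msdmsa_fwd(List vals, IntegerMatrix ldims, NumericVector loc,
                             NumericVector w, int H, int N, int K) {
  const int L = vals.size();
  const int d = ldims(0, 0);
  const int dh = d / H;
  NumericMatrix out(d, N);
  std::vector<const double*> vp(L);
  for (int l = 0; l < L; ++l) vp[l] = NumericVector(vals[l]).begin();
  const double* lp = loc.begin();
  const double* wp = w.begin();
  double* op = out.begin();
  for (int i = 0; i < N; ++i) {
    for (int h = 0; h < H; ++h) {
      double* dst = op + (R_xlen_t)i * d + h * dh;
      for (int l = 0; l < L; ++l) {
        const int Z = ldims(l, 1), Y = ldims(l, 2), X = ldims(l, 3);
        for (int k = 0; k < K; ++k) {
          const R_xlen_t bi = (R_xlen_t)(k + K * (l + L * (h + (R_xlen_t)H * i)));
          const double ww = wp[bi];
          if (ww == 0) continue;
          const double* lco = lp + 3 * bi;
          LinW wz = lin_weights(lco[0], Z);
          LinW wy = lin_weights(lco[1], Y);
          LinW wx = lin_weights(lco[2], X);
          for (int ax = 0; ax < 2; ++ax) {
            int xi = ax ? wx.i1 : wx.i0; double fx = ax ? wx.w1 : wx.w0;
            if (fx == 0) continue;
            for (int ay = 0; ay < 2; ++ay) {
              int yi = ay ? wy.i1 : wy.i0; double fy = ay ? wy.w1 : wy.w0;
              if (fy == 0) continue;
              for (int az = 0; az < 2; ++az) {
                int zi = az ? wz.i1 : wz.i0; double fz = az ? wz.w1 : wz.w0;
                if (fz == 0) continue;
                const double f = ww * fx * fy * fz;
                const double* src = vp[l] +
                  (R_xlen_t)d * (zi + Z * (yi + (R_xlen_t)Y * xi)) + h * dh;
                for (int j = 0; j < dh; ++j) dst[j] += f * src[j];
              }
            }
          }
        }
      }
    }
  }
  return out;
}

// Backward pass: gradients w.r.t. values, sampling locations and weights.
// Locations clamped outside the grid get zero positional gradient.
// [[Rcpp::export]]
List cpp_msdmsa_bwd(List vals, IntegerMatrix ldims, NumericVector loc,
                    NumericVector w, int H, int N, int K, NumericMatrix gout) {
  const int L = vals.size();
  const int d = ldims(0, 0);
  const int dh = d / H;
  List gvals(L);
  std::vector<const double*> vp(L);
  std::vector<double*> gvp(L);
  for (int l = 0; l < L; ++l) {
    NumericVector v = vals[l];
    vp[l] = v.begin();
    NumericVector gv((R_xlen_t)v.size());
    gvals[l] = gv;
    gvp[l] = NumericVector(gvals[l]).begin();
  }
  NumericVector gloc((R_xlen_t)loc.size());
  NumericVector gw((R_xlen_t)w.size());
  const double* lp = loc.begin();
  const double* wp = w.begin();
  const double* gp = gout.begin();
  double* glp = gloc.begin();
  double* gwp = gw.begin();
  for (int i = 0; i < N; ++i) {
    for (int h = 0; h < H; ++h) {
      const double* go = gp + (R_xlen_t)i * d + h * dh;
      for (int l = 0; l < L; ++l) {
        const int Z = ldims(l, 1), Y = ldims(l, 2), X = ldims(l, 3);
        for (int k = 0; k < K; ++k) {
          const R_xlen_t bi = (R_xlen_t)(k + K * (l + L * (h + (R_xlen_t)H * i)));
          const double ww = wp[bi];
          const double* lco = lp + 3 * bi;
          const bool in_z = lco[0] > 0 && lco[0] < Z - 1;
          const bool in_y = lco[1] > 0 && lco[1] < Y - 1;
          const bool in_x = lco[2] > 0 && lco[2] < X - 1;
          LinW wz = lin_weights(lco[0], Z);
          LinW wy = lin_weights(lco[1], Y);
          LinW wx = lin_weights(lco[2], X);
          double sampled_dot = 0.0, dz_dot = 0.0, dy_dot = 0.0, dx_dot = 0.0;
          for (int ax = 0; ax < 2; ++ax) {
            int xi = ax ? wx.i1 : wx.i0; double fx = ax ? wx.w1 : wx.w0;
            double dfx = ax ? 1.0 : -1.0;
            for (int ay = 0; ay < 2; ++ay) {
              int yi = ay ? wy.i1 : wy.i0; double fy = ay ? wy.w1 : wy.w0;
              double dfy = ay ? 1.0 : -1.0;
              for (int az = 0; az < 2; ++az) {
                int zi = az ? wz.i1 : wz.i0; double fz = az ? wz.w1 : wz.w0;
                double dfz = az ? 1.0 : -1.0;
                const R_xlen_t off =
                  (R_xlen_t)d * (zi + Z * (yi + (R_xlen_t)Y * xi)) + h * dh;
                const double* src = vp[l] + off;
                double dot = 0.0;
                for (int j = 0; j < dh; ++j) dot += go[j] * src[j];
                sampled_dot += fx * fy * fz * dot;
                if (in_z) dz_dot += dfz * fy * fx * dot;
                if (in_y) dy_dot += fz * dfy * fx * dot;
                if (in_x) dx_dot += fz * fy * dfx * dot;
                const double f = ww * fx * fy * fz;
                if (f != 0) {
                  double* gdst = gvp[l] + off;
                  for (int j = 0; j < dh; ++j) gdst[j] += f * go[j];
                }
              }
            }
          }
          gwp[bi] = sampled_dot;
          glp[3 * bi + 0] = ww * dz_dot;
          glp[3 * bi + 1] = ww * dy_dot;
          glp[3 * bi + 2] = ww * dx_dot;
        }
      }
    }
  }
  return List::create(_["gvals"] = gvals, _["gloc"] = gloc, _["gw"] = gw);
}

// ---- Surface-distance support ------------------------------------------
//
// Surface voxels: foreground voxels with at least one face-adjacent
// background voxel; the outside of the grid counts as background.
// mask dims here are (Z, Y, X), z fastest.
// [[Rcpp::export]]
IntegerMatrix cpp_surface_points(IntegerVector mask, IntegerVector dims) {
  const int Z = dims[0], Y = dims[1], X = dims[2];
  const int* m = mask.begin();
  std::vector<int> zs, ys, xs;
  for (int x = 0; x < X; ++x)
    for (int y = 0; y < Y; ++y)
      for (int z = 0; z < Z; ++z) {
        if (!m[z + Z * (y + (R_xlen_t)Y * x)]) continue;
        bool surf =
          z == 0 || z == Z - 1 || y == 0 || y == Y - 1 || x == 0 || x == X - 1;
        if (!surf) {
          surf = !m[(z - 1) + Z * (y + (R_xlen_t)Y * x)] ||
                 !m[(z + 1) + Z * (y + (R_xlen_t)Y * x)] ||
                 !m[z + Z * ((y - 1) + (R_xlen_t)Y * x)] ||
                 !m[z + Z * ((y + 1) + (R_xlen_t)Y * x)] ||
                 !m[z + Z * (y + (R_xlen_t)Y * (x - 1))] ||
                 !m[z + Z * (y + (R_xlen_t)Y * (x + 1))];
        }
        if (surf) { zs.push_back(z); ys.push_back(y); xs.push_back(x); }
      }
  IntegerMatrix out(zs.size(), 3);
  for (size_t i = 0; i < zs.size(); ++i) {
    out(i, 0) = zs[i]; out(i, 1) = ys[i]; out(i, 2) = xs[i];
  }
  return out;
}

// For every row of A (physical mm coordinates), the Euclidean distance to
// the nearest row of B.
// [[Rcpp::export]]
NumericVector cpp_min_dists(NumericMatrix A, NumericMatrix B) {
  const int n = A.nrow(), m = B.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double az = A(i, 0), ay = A(i, 1), ax = A(i, 2);
    double best = R_PosInf;
    for (int j = 0; j < m; ++j) {
      const double dz = az - B(j, 0), dy = ay - B(j, 1), dx = ax - B(j, 2);
      const double d2 = dz * dz + dy * dy + dx * dx;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// ---- direct small-channel 3D convolution --------------------------------
//
// Same weight layout as the im2col path: W is (Cout x Cin*kz*ky*kx) with
// column index r = cin + Cin*(dz + kz*(dy + ky*dx)). Loops run with the
// kernel offset outermost so the inner position loops are branch-free and
// stream contiguously; this dominates the im2col route for the narrow
// networks used here.

struct ConvGeom {
  int C, Z, Y, X, kz, ky, kx, sz, sy, sx, pz, py, px, Zo, Yo, Xo;
};

static ConvGeom conv_geom(IntegerVector dims, IntegerVector ksize,
                          IntegerVector stride, IntegerVector pad) {
  ConvGeom g;
  g.C = dims[0]; g.Z = dims[1]; g.Y = dims[2]; g.X = dims[3];
  g.kz = ksize[0]; g.ky = ksize[1]; g.kx = ksize[2];
  g.sz = stride[0]; g.sy = stride[1]; g.sx = stride[2];
  g.pz = pad[0]; g.py = pad[1]; g.px = pad[2];
  g.Zo = out_dim(g.Z, g.kz, g.sz, g.pz);
  g.Yo = out_dim(g.Y, g.ky, g.sy, g.py);
  g.Xo = out_dim(g.X, g.kx, g.sx, g.px);
  return g;
}

// Valid output-index range [lo, hi) along one axis for kernel offset d:
// input index i = o*s - p + d must lie in [0, n).
static inline void valid_range(int n, int no, int s, int p, int d,
                               int& lo, int& hi) {
  lo = 0;
  while (lo < no && lo * s - p + d < 0) ++lo;
  hi = no;
  while (hi > lo && (hi - 1) * s - p + d >= n) --hi;
}

// [[Rcpp::export]]
NumericMatrix cpp_conv3d_fwd(NumericVector x, IntegerVector dims,
                             NumericMatrix W, IntegerVector ksize,
                             IntegerVector stride, IntegerVector pad) {
  const ConvGeom g = conv_geom(dims, ksize, stride, pad);
  const int Cout = W.nrow();
  NumericMatrix out(Cout, g.Zo * g.Yo * g.Xo);
  const double* xp = x.begin();
  const double* wp = W.begin();
  double* op = out.begin();
  for (int dx = 0; dx < g.kx; ++dx) {
    int xlo, xhi; valid_range(g.X, g.Xo, g.sx, g.px, dx, xlo, xhi);
    for (int dy = 0; dy < g.ky; ++dy) {
      int ylo, yhi; valid_range(g.Y, g.Yo, g.sy, g.py, dy, ylo, yhi);
      for (int dz = 0; dz < g.kz; ++dz) {
        int zlo, zhi; valid_range(g.Z, g.Zo, g.sz, g.pz, dz, zlo, zhi);
        const double* wk = wp + (R_xlen_t)g.C * (dz + g.kz * (dy + g.ky * dx)) * Cout;
        for (int xo = xlo; xo < xhi; ++xo) {
          const int xi = xo * g.sx - g.px + dx;
          for (int yo = ylo; yo < yhi; ++yo) {
            const int yi = yo * g.sy - g.py + dy;
            const double* xrow = xp + (R_xlen_t)g.C *
              ((zlo * g.sz - g.pz + dz) + g.Z * (yi + (R_xlen_t)g.Y * xi));
            double* orow = op + (R_xlen_t)Cout *
              (zlo + g.Zo * (yo + (R_xlen_t)g.Yo * xo));
            const R_xlen_t xstep = (R_xlen_t)g.C * g.sz;
            for (int zo = zlo; zo < zhi; ++zo) {
              for (int c = 0; c < g.C; ++c) {
                const double xv = xrow[c];
                if (xv != 0.0) {
                  const double* wc = wk + (R_xlen_t)c * Cout;
                  for (int co = 0; co < Cout; ++co) orow[co] += wc[co] * xv;
                }
              }
              xrow += xstep;
              orow += Cout;
            }
          }
        }
      }
    }
  }
  return out;
}

// Gradient w.r.t. the weights.
// [[Rcpp::export]]
NumericMatrix cpp_conv3d_gw(NumericVector x, IntegerVector dims,
                            NumericMatrix gout, int Cout, IntegerVector ksize,
                            IntegerVector stride, IntegerVector pad) {
  const ConvGeom g = conv_geom(dims, ksize, stride, pad);
  NumericMatrix gw(Cout, g.C * g.kz * g.ky * g.kx);
  const double* xp = x.begin();
  const double* gp = gout.begin();
  double* wp = gw.begin();
  for (int dx = 0; dx < g.kx; ++dx) {
    int xlo, xhi; valid_range(g.X, g.Xo, g.sx, g.px, dx, xlo, xhi);
    for (int dy = 0; dy < g.ky; ++dy) {
      int ylo, yhi; valid_range(g.Y, g.Yo, g.sy, g.py, dy, ylo, yhi);
      for (int dz = 0; dz < g.kz; ++dz) {
        int zlo, zhi; valid_range(g.Z, g.Zo, g.sz, g.pz, dz, zlo, zhi);
        double* wk = wp + (R_xlen_t)g.C * (dz + g.kz * (dy + g.ky * dx)) * Cout;
        for (int xo = xlo; xo < xhi; ++xo) {
          const int xi = xo * g.sx - g.px + dx;
          for (int yo = ylo; yo < yhi; ++yo) {
            const int yi = yo * g.sy - g.py + dy;
            const double* xrow = xp + (R_xlen_t)g.C *
              ((zlo * g.sz - g.pz + dz) + g.Z * (yi + (R_xlen_t)g.Y * xi));
            const double* grow = gp + (R_xlen_t)Cout *
              (zlo + g.Zo * (yo + (R_xlen_t)g.Yo * xo));
            const R_xlen_t xstep = (R_xlen_t)g.C * g.sz;
            for (int zo = zlo; zo < zhi; ++zo) {
              for (int c = 0; c < g.C; ++c) {
                const double xv = xrow[c];
                if (xv != 0.0) {
                  double* wc = wk + (R_xlen_t)c * Cout;
                  for (int co = 0; co < Cout; ++co) wc[co] += grow[co] * xv;
                }
              }
              xrow += xstep;
              grow += Cout;
            }
          }
        }
      }
    }
  }
  return gw;
}

// Gradient w.r.t. the input.
// [[Rcpp::export]]
NumericVector cpp_conv3d_gx(IntegerVector dims, NumericMatrix W,
                            NumericMatrix gout, IntegerVector ksize,
                            IntegerVector stride, IntegerVector pad) {
  const ConvGeom g = conv_geom(dims, ksize, stride, pad);
  const int Cout = W.nrow();
  NumericVector gx((R_xlen_t)g.C * g.Z * g.Y * g.X);
  const double* wp = W.begin();
  const double* gp = gout.begin();
  double* xp = gx.begin();
  for (int dx = 0; dx < g.kx; ++dx) {
    int xlo, xhi; valid_range(g.X, g.Xo, g.sx, g.px, dx, xlo, xhi);
    for (int dy = 0; dy < g.ky; ++dy) {
      int ylo, yhi; valid_range(g.Y, g.Yo, g.sy, g.py, dy, ylo, yhi);
      for (int dz = 0; dz < g.kz; ++dz) {
        int zlo, zhi; valid_range(g.Z, g.Zo, g.sz, g.pz, dz, zlo, zhi);
        const double* wk = wp + (R_xlen_t)g.C * (dz + g.kz * (dy + g.ky * dx)) * Cout;
        for (int xo = xlo; xo < xhi; ++xo) {
          const int xi = xo * g.sx - g.px + dx;
          for (int yo = ylo; yo < yhi; ++yo) {
            const int yi = yo * g.sy - g.py + dy;
            double* xrow = xp + (R_xlen_t)g.C *
              ((zlo * g.sz - g.pz + dz) + g.Z * (yi + (R_xlen_t)g.Y * xi));
            const double* grow = gp + (R_xlen_t)Cout *
              (zlo + g.Zo * (yo + (R_xlen_t)g.Yo * xo));
            const R_xlen_t xstep = (R_xlen_t)g.C * g.sz;
            for (int zo = zlo; zo < zhi; ++zo) {
              for (int c = 0; c < g.C; ++c) {
                const double* wc = wk + (R_xlen_t)c * Cout;
                double acc = 0.0;
                for (int co = 0; co < Cout; ++co) acc += wc[co] * grow[co];
                xrow[c] += acc;
              }
              xrow += xstep;
              grow += Cout;
            }
          }
        }
      }
    }
  }
  return gx;
}
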