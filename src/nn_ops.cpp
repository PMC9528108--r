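// Low-level numeric kernels for the small CNNs used by the detector and the
// joint classifiers, plus a bilinear affine warp shared by resizing, cropping
// and geometric augmentation. Tensors are R arrays in (N, H, W, C) layout
// (column-major, so index = n + N*(h + H*(w + W*c))). Convolutions are
// stride-1 with symmetric zero padding; pooling/upsampling are fixed 2x2.

#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#include <vector>
#ifndef FCONE
#define FCONE
#endif
using namespace Rcpp;

static inline R_xlen_t id4(int n, int h, int w, int c, int N, int H, int W) {
  return (R_xlen_t)n + (R_xlen_t)N * ((R_xlen_t)h + (R_xlen_t)H * ((R_xlen_t)w + (R_xlen_t)W * c));
}

// Gather one sample's receptive fields into a (P x K) matrix,
// P = Ho*Wo output positions (column-major over ho then wo),
// K = kh*kw*Ci kernel taps ordered to match the (kh, kw, Cin, Cout)
// weight layout, so the convolution is a single GEMM: y = cols * W.
static void im2col(const double *xp, int n, int N, int H, int W, int Ci,
                   int kh, int kw, int pad, int Ho, int Wo, double *cols) {
  const int P = Ho * Wo;
  int k = 0;
  for (int ci = 0; ci < Ci; ++ci) {
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh, ++k) {
        double *col = cols + (R_xlen_t)P * k;
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo + dw - pad;
          double *dst = col + (R_xlen_t)Ho * wo;
          if (wi < 0 || wi >= W) {
            for (int ho = 0; ho < Ho; ++ho) dst[ho] = 0.0;
            continue;
          }
          const double *src = xp + (R_xlen_t)n + (R_xlen_t)N * H * ((R_xlen_t)wi + (R_xlen_t)W * ci);
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho + dh - pad;
            dst[ho] = (hi < 0 || hi >= H) ? 0.0 : src[(R_xlen_t)N * hi];
          }
        }
      }
    }
  }
}

// Scatter-add a (P x K) gradient matrix back onto the padded input.
static void col2im_add(const double *cols, int n, int N, int H, int W, int Ci,
                       int kh, int kw, int pad, int Ho, int Wo, double *dxp) {
  const int P = Ho * Wo;
  int k = 0;
  for (int ci = 0; ci < Ci; ++ci) {
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh, ++k) {
        const double *col = cols + (R_xlen_t)P * k;
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo + dw - pad;
          if (wi < 0 || wi >= W) continue;
          const double *src = col + (R_xlen_t)Ho * wo;
          double *dst = dxp + (R_xlen_t)n + (R_xlen_t)N * H * ((R_xlen_t)wi + (R_xlen_t)W * ci);
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho + dh - pad;
            if (hi >= 0 && hi < H) dst[(R_xlen_t)N * hi] += src[ho];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector x, NumericVector w, NumericVector b, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int N = xd[0], H = xd[1], W = xd[2], Ci = xd[3];
  int kh = wd[0], kw = wd[1], Co = wd[3];
  if (wd[2] != Ci) stop("conv2d: input channel mismatch");
  int Ho = H + 2 * pad - kh + 1, Wo = W + 2 * pad - kw + 1;
  if (Ho <= 0 || Wo <= 0) stop("conv2d: kernel larger than padded input");
  const int P = Ho * Wo, K = kh * kw * Ci;
  NumericVector y((R_xlen_t)N * P * Co);
  y.attr("dim") = IntegerVector::create(N, Ho, Wo, Co);
  const double *xp = x.begin(), *wp = w.begin();
  double *yp = y.begin();
  std::vector<double> cols((R_xlen_t)P * K), ybuf((R_xlen_t)P * Co);
  const double one = 1.0, zero = 0.0;
  for (int n = 0; n < N; ++n) {
    im2col(xp, n, N, H, W, Ci, kh, kw, pad, Ho, Wo, cols.data());
    F77_CALL(dgemm)("N", "N", &P, &Co, &K, &one, cols.data(), &P,
                    wp, &K, &zero, ybuf.data(), &P FCONE FCONE);
    for (int co = 0; co < Co; ++co) {
      const double *src = ybuf.data() + (R_xlen_t)P * co;
      const double bc = b[co];
      double *dst = yp + (R_xlen_t)n + (R_xlen_t)N * P * co;
      for (int p = 0; p < P; ++p) dst[(R_xlen_t)N * p] = src[p] + bc;
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x, NumericVector w, NumericVector dy, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  IntegerVector yd = dy.attr("dim");
  int N = xd[0], H = xd[1], W = xd[2], Ci = xd[3];
  int kh = wd[0], kw = wd[1], Co = wd[3];
  int Ho = yd[1], Wo = yd[2];
  const int P = Ho * Wo, K = kh * kw * Ci;
  NumericVector dx((R_xlen_t)N * H * W * Ci);
  dx.attr("dim") = IntegerVector::create(N, H, W, Ci);
  NumericVector dw_((R_xlen_t)K * Co);
  dw_.attr("dim") = IntegerVector::create(kh, kw, Ci, Co);
  NumericVector db(Co);
  const double *xp = x.begin(), *wp = w.begin(), *dyp = dy.begin();
  double *dxp = dx.begin(), *dwp = dw_.begin();
  std::vector<double> cols((R_xlen_t)P * K), dybuf((R_xlen_t)P * Co),
      dcols((R_xlen_t)P * K);
  const double one = 1.0, zero = 0.0;
  for (int n = 0; n < N; ++n) {
    for (int co = 0; co < Co; ++co) {
      const double *src = dyp + (R_xlen_t)n + (R_xlen_t)N * P * co;
      double *dst = dybuf.data() + (R_xlen_t)P * co;
      double acc = 0.0;
      for (int p = 0; p < P; ++p) {
        dst[p] = src[(R_xlen_t)N * p];
        acc += dst[p];
      }
      db[co] += acc;
    }
    im2col(xp, n, N, H, W, Ci, kh, kw, pad, Ho, Wo, cols.data());
    // dW += cols^T * dy   (K x Co)
    F77_CALL(dgemm)("T", "N", &K, &Co, &P, &one, cols.data(), &P,
                    dybuf.data(), &P, &one, dwp, &K FCONE FCONE);
    // dcols = dy * W^T    (P x K)
    F77_CALL(dgemm)("N", "T", &P, &K, &Co, &one, dybuf.data(), &P,
                    wp, &K, &zero, dcols.data(), &P FCONE FCONE);
    col2im_add(dcols.data(), n, N, H, W, Ci, kh, kw, pad, Ho, Wo, dxp);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw_, _["db"] = db);
}

// [[Rcpp::export]]
NumericVector cpp_avgpool2_fw(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int N = xd[0], H = xd[1], W = xd[2], C = xd[3];
  if (H % 2 || W % 2) stop("avgpool2: H and W must be even");
  int Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)N * Ho * Wo * C);
  y.attr("dim") = IntegerVector::create(N, Ho, Wo, C);
  const double *xp = x.begin();
  double *yp = y.begin();
  for (int c = 0; c < C; ++c)
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho)
        for (int n = 0; n < N; ++n) {
          double s = xp[id4(n, 2 * ho, 2 * wo, c, N, H, W)] +
                     xp[id4(n, 2 * ho + 1, 2 * wo, c, N, H, W)] +
                     xp[id4(n, 2 * ho, 2 * wo + 1, c, N, H, W)] +
                     xp[id4(n, 2 * ho + 1, 2 * wo + 1, c, N, H, W)];
          yp[id4(n, ho, wo, c, N, Ho, Wo)] = 0.25 * s;
        }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool2_bw(NumericVector dy) {
  IntegerVector yd = dy.attr("dim");
  int N = yd[0], Ho = yd[1], Wo = yd[2], C = yd[3];
  int H = 2 * Ho, W = 2 * Wo;
  NumericVector dx((R_xlen_t)N * H * W * C);
  dx.attr("dim") = IntegerVector::create(N, H, W, C);
  const double *dyp = dy.begin();
  double *dxp = dx.begin();
  for (int c = 0; c < C; ++c)
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho)
        for (int n = 0; n < N; ++n) {
          double g = 0.25 * dyp[id4(n, ho, wo, c, N, Ho, Wo)];
          dxp[id4(n, 2 * ho, 2 * wo, c, N, H, W)] = g;
          dxp[id4(n, 2 * ho + 1, 2 * wo, c, N, H, W)] = g;
          dxp[id4(n, 2 * ho, 2 * wo + 1, c, N, H, W)] = g;
          dxp[id4(n, 2 * ho + 1, 2 * wo + 1, c, N, H, W)] = g;
        }
  return dx;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_fw(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int N = xd[0], H = xd[1], W = xd[2], C = xd[3];
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((R_xlen_t)N * Ho * Wo * C);
  y.attr("dim") = IntegerVector::create(N, Ho, Wo, C);
  const double *xp = x.begin();
  double *yp = y.begin();
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h)
        for (int n = 0; n < N; ++n) {
          double v = xp[id4(n, h, w, c, N, H, W)];
          yp[id4(n, 2 * h, 2 * w, c, N, Ho, Wo)] = v;
          yp[id4(n, 2 * h + 1, 2 * w, c, N, Ho, Wo)] = v;
          yp[id4(n, 2 * h, 2 * w + 1, c, N, Ho, Wo)] = v;
          yp[id4(n, 2 * h + 1, 2 * w + 1, c, N, Ho, Wo)] = v;
        }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_bw(NumericVector dy) {
  IntegerVector yd = dy.attr("dim");
  int N = yd[0], Ho = yd[1], Wo = yd[2], C = yd[3];
  int H = Ho / 2, W = Wo / 2;
  NumericVector dx((R_xlen_t)N * H * W * C);
  dx.attr("dim") = IntegerVector::create(N, H, W, C);
  const double *dyp = dy.begin();
  double *dxp = dx.begin();
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h)
        for (int n = 0; n < N; ++n) {
          dxp[id4(n, h, w, c, N, H, W)] =
            dyp[id4(n, 2 * h, 2 * w, c, N, Ho, Wo)] +
            dyp[id4(n, 2 * h + 1, 2 * w, c, N, Ho, Wo)] +
            dyp[id4(n, 2 * h, 2 * w + 1, c, N, Ho, Wo)] +
            dyp[id4(n, 2 * h + 1, 2 * w + 1, c, N, Ho, Wo)];
        }
  return dx;
}

// Affine warp with bilinear interpolation and zero fill. `a` has length 6:
// (a11, a12, a13, a21, a22, a23) mapping OUTPUT pixel coordinates (x, y)
// (0-based, x = column, y = row) to input coordinates:
//   xs = a11*x + a12*y + a13 ; ys = a21*x + a22*y + a23.
// [[Rcpp::export]]
NumericMatrix cpp_warp_affine(NumericMatrix img, NumericVector a, int outH, int outW) {
  int H = img.nrow(), W = img.ncol();
  NumericMatrix out(outH, outW);
  for (int j = 0; j < outW; ++j) {
    for (int i = 0; i < outH; ++i) {
      double xs = a[0] * j + a[1] * i + a[2];
      double ys = a[3] * j + a[4] * i + a[5];
      int x0 = (int)std::floor(xs), y0 = (int)std::floor(ys);
      double fx = xs - x0, fy = ys - y0;
      double v = 0.0;
      for (int dy = 0; dy <= 1; ++dy) {
        int yy = y0 + dy;
        if (yy < 0 || yy >= H) continue;
        double wy = dy ? fy : 1.0 - fy;
        for (int dx = 0; dx <= 1; ++dx) {
          int xx = x0 + dx;
          if (xx < 0 || xx >= W) continue;
          double wx = dx ? fx : 1.0 - fx;
          v += wy * wx * img(yy, xx);
        }
      }
      out(i, j) = v;
    }
  }
  return out;
}
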