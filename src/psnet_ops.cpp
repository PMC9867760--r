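// Compiled inner kernels for the convolution primitives.
//
// Arrays follow the package layout: column-major with dims (b, c, h, w),
// i.e. index = bi + B*(ci + C*(hi + H*wi)). Only the memory-bound loops
// live here (depthwise convolution, im2col/col2im, per-channel sums);
// channel-mixing matrix products go through R's BLAS.

#include <Rcpp.h>
using namespace Rcpp;

static inline int out_len(int n, int k, int s, int p, int d) {
  return (n + 2 * p - d * (k - 1) - 1) / s + 1;
}

// Gather one (h, w) plane of a (b,c,h,w) array into contiguous storage.
static inline void gather_plane(const double* x, double* buf,
                                int b, int c, int B, int C, int H, int W) {
  const long stride = (long)B * C;
  for (int wi = 0; wi < W; ++wi) {
    const double* col = x + b + B * ((long)c + (long)C * (long)H * wi);
    double* bc = buf + (long)H * wi;
    for (int hi = 0; hi < H; ++hi) bc[hi] = col[stride * hi];
  }
}

static inline void scatter_plane_add(double* x, const double* buf,
                                     int b, int c, int B, int C, int H, int W) {
  const long stride = (long)B * C;
  for (int wi = 0; wi < W; ++wi) {
    double* col = x + b + B * ((long)c + (long)C * (long)H * wi);
    const double* bc = buf + (long)H * wi;
    for (int hi = 0; hi < H; ++hi) col[stride * hi] += bc[hi];
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv_dw_fwd(NumericVector x, IntegerVector xdim,
                              NumericVector w, IntegerVector wdim,
                              NumericVector bias, int stride,
                              int ph, int pw, int dil) {
  const int B = xdim[0], C = xdim[1], H = xdim[2], W = xdim[3];
  const int KH = wdim[1], KW = wdim[2];
  const int OH = out_len(H, KH, stride, ph, dil);
  const int OW = out_len(W, KW, stride, pw, dil);
  NumericVector y(B * C * OH * OW);
  const bool has_bias = bias.size() == C;
  std::vector<double> xin((long)H * W), yout((long)OH * OW);
  for (int c = 0; c < C; ++c) {
    for (int b = 0; b < B; ++b) {
      gather_plane(&x[0], xin.data(), b, c, B, C, H, W);
      const double bv = has_bias ? bias[c] : 0.0;
      for (int wo = 0; wo < OW; ++wo) {
        for (int ho = 0; ho < OH; ++ho) {
          double acc = bv;
          for (int kj = 0; kj < KW; ++kj) {
            const int wi = wo * stride + kj * dil - pw;
            if (wi < 0 || wi >= W) continue;
            const double* xcol = xin.data() + (long)H * wi;
            const double* wc = &w[c + C * KH * kj];
            for (int ki = 0; ki < KH; ++ki) {
              const int hi = ho * stride + ki * dil - ph;
              if (hi < 0 || hi >= H) continue;
              acc += wc[C * ki] * xcol[hi];
            }
          }
          yout[ho + (long)OH * wo] = acc;
        }
      }
      const long ystride = (long)B * C;
      for (int wo = 0; wo < OW; ++wo) {
        double* ycol = &y[0] + b + B * ((long)c + (long)C * (long)OH * wo);
        const double* yc = yout.data() + (long)OH * wo;
        for (int ho = 0; ho < OH; ++ho) ycol[ystride * ho] = yc[ho];
      }
    }
  }
  y.attr("dim") = IntegerVector::create(B, C, OH, OW);
  return y;
}

// [[Rcpp::export]]
List cpp_conv_dw_bwd(NumericVector dy, NumericVector x, IntegerVector xdim,
                     NumericVector w, IntegerVector wdim, int stride,
                     int ph, int pw, int dil) {
  const int B = xdim[0], C = xdim[1], H = xdim[2], W = xdim[3];
  const int KH = wdim[1], KW = wdim[2];
  const int OH = out_len(H, KH, stride, ph, dil);
  const int OW = out_len(W, KW, stride, pw, dil);
  NumericVector dx(B * C * H * W);
  NumericVector dw(C * KH * KW);
  NumericVector db(C);
  std::vector<double> xin((long)H * W), dyin((long)OH * OW), dxout((long)H * W);
  for (int c = 0; c < C; ++c) {
    for (int b = 0; b < B; ++b) {
      gather_plane(&x[0], xin.data(), b, c, B, C, H, W);
      gather_plane(&dy[0], dyin.data(), b, c, B, C, OH, OW);
      std::fill(dxout.begin(), dxout.end(), 0.0);
      double dbacc = 0.0;
      for (long i = 0; i < (long)OH * OW; ++i) dbacc += dyin[i];
      db[c] += dbacc;
      for (int kj = 0; kj < KW; ++kj) {
        for (int ki = 0; ki < KH; ++ki) {
          const double wv = w[c + C * (ki + KH * kj)];
          double dwacc = 0.0;
          for (int wo = 0; wo < OW; ++wo) {
            const int wi = wo * stride + kj * dil - pw;
            if (wi < 0 || wi >= W) continue;
            const double* dycol = dyin.data() + (long)OH * wo;
            const double* xcol = xin.data() + (long)H * wi;
            double* dxcol = dxout.data() + (long)H * wi;
            for (int ho = 0; ho < OH; ++ho) {
              const int hi = ho * stride + ki * dil - ph;
              if (hi < 0 || hi >= H) continue;
              const double g = dycol[ho];
              dxcol[hi] += wv * g;
              dwacc += g * xcol[hi];
            }
          }
          dw[c + C * (ki + KH * kj)] += dwacc;
        }
      }
      scatter_plane_add(&dx[0], dxout.data(), b, c, B, C, H, W);
    }
  }
  dx.attr("dim") = xdim;
  dw.attr("dim") = wdim;
  return List::create(Named("dx") = dx, Named("dw") = dw, Named("db") = db);
}

// Unfold an UNPADDED (b,c,h,w) array into the (b*oh*ow, c*kh*kw) im2col
// matrix; padding is implicit (zero rows).
// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, IntegerVector xdim, int kh, int kw,
                         int stride, int ph, int pw, int dil) {
  const int B = xdim[0], C = xdim[1], H = xdim[2], W = xdim[3];
  const int OH = out_len(H, kh, stride, ph, dil);
  const int OW = out_len(W, kw, stride, pw, dil);
  NumericMatrix M(B * OH * OW, C * kh * kw);
  for (int kj = 0; kj < kw; ++kj) {
    for (int ki = 0; ki < kh; ++ki) {
      for (int c = 0; c < C; ++c) {
        double* col = &M(0, c + C * (ki + kh * kj));
        for (int wo = 0; wo < OW; ++wo) {
          int wi = wo * stride + kj * dil - pw;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < OH; ++ho) {
            int hi = ho * stride + ki * dil - ph;
            if (hi < 0 || hi >= H) continue;
            const double* xp = &x[B * (c + C * (hi + H * wi))];
            double* cp = &col[B * (ho + OH * wo)];
            for (int b = 0; b < B; ++b) cp[b] = xp[b];
          }
        }
      }
    }
  }
  return M;
}

// Scatter-add the (b*oh*ow, c*kh*kw) gradient matrix back to input layout.
// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix dM, IntegerVector xdim, int kh, int kw,
                         int stride, int ph, int pw, int dil) {
  const int B = xdim[0], C = xdim[1], H = xdim[2], W = xdim[3];
  const int OH = out_len(H, kh, stride, ph, dil);
  const int OW = out_len(W, kw, stride, pw, dil);
  NumericVector dx(B * C * H * W);
  for (int kj = 0; kj < kw; ++kj) {
    for (int ki = 0; ki < kh; ++ki) {
      for (int c = 0; c < C; ++c) {
        const double* col = &dM(0, c + C * (ki + kh * kj));
        for (int wo = 0; wo < OW; ++wo) {
          int wi = wo * stride + kj * dil - pw;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < OH; ++ho) {
            int hi = ho * stride + ki * dil - ph;
            if (hi < 0 || hi >= H) continue;
            double* dxp = &dx[B * (c + C * (hi + H * wi))];
            const double* cp = &col[B * (ho + OH * wo)];
            for (int b = 0; b < B; ++b) dxp[b] += cp[b];
          }
        }
      }
    }
  }
  dx.attr("dim") = xdim;
  return dx;
}

// Sum over batch and spatial dims, per channel.
// [[Rcpp::export]]
NumericVector cpp_channel_sum(NumericVector x, IntegerVector xdim) {
  const int B = xdim[0], C = xdim[1], HW = xdim[2] * xdim[3];
  NumericVector out(C);
  for (int s = 0; s < HW; ++s) {
    const double* xs = &x[B * C * s];
    for (int c = 0; c < C; ++c) {
      const double* xp = &xs[B * c];
      double acc = 0.0;
      for (int b = 0; b < B; ++b) acc += xp[b];
      out[c] += acc;
    }
  }
  return out;
}
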