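// Compiled kernels for the 3D network: im2col-GEMM convolution with stride
// and dilation, max/adaptive-average pooling, and trilinear resampling with
// exact transpose backward passes. Tensors are column-major R arrays laid
// out (D, H, W, C, B); weights are (kd, kh, kw, Cin, Cout).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_dim(int in, int k, int s, int d, int p) {
  int eff = k + (k - 1) * (d - 1);
  return (in + 2 * p - eff) / s + 1;
}

// Fill the im2col matrix (K x P) for one sample.
// x: pointer to (D,H,W,C) block. K = kd*kh*kw*C, P = Do*Ho*Wo.
static void im2col(const double* x, int D, int H, int W, int C,
                   int kd, int kh, int kw,
                   int sd, int sh, int sw,
                   int dd, int dh, int dw,
                   int pd, int ph, int pw,
                   int Do, int Ho, int Wo,
                   arma::mat& col) {
  const int T = kd * kh * kw;
  col.zeros();
  for (int ow = 0; ow < Wo; ++ow) {
    for (int oh = 0; oh < Ho; ++oh) {
      for (int od = 0; od < Do; ++od) {
        const int p = od + Do * (oh + Ho * ow);
        double* cp = col.colptr(p);
        for (int iw = 0; iw < kw; ++iw) {
          const int w_in = ow * sw - pw + iw * dw;
          if (w_in < 0 || w_in >= W) continue;
          for (int ih = 0; ih < kh; ++ih) {
            const int h_in = oh * sh - ph + ih * dh;
            if (h_in < 0 || h_in >= H) continue;
            for (int id = 0; id < kd; ++id) {
              const int d_in = od * sd - pd + id * dd;
              if (d_in < 0 || d_in >= D) continue;
              const int t = id + kd * (ih + kh * iw);
              const size_t xoff = (size_t)d_in + (size_t)D * (h_in + (size_t)H * w_in);
              for (int c = 0; c < C; ++c) {
                cp[t + T * c] = x[xoff + (size_t)D * H * W * c];
              }
            }
          }
        }
      }
    }
  }
}

// Scatter-add a col matrix back into a (D,H,W,C) gradient block.
static void col2im(const arma::mat& col, double* gx,
                   int D, int H, int W, int C,
                   int kd, int kh, int kw,
                   int sd, int sh, int sw,
                   int dd, int dh, int dw,
                   int pd, int ph, int pw,
                   int Do, int Ho, int Wo) {
  const int T = kd * kh * kw;
  for (int ow = 0; ow < Wo; ++ow) {
    for (int oh = 0; oh < Ho; ++oh) {
      for (int od = 0; od < Do; ++od) {
        const int p = od + Do * (oh + Ho * ow);
        const double* cp = col.colptr(p);
        for (int iw = 0; iw < kw; ++iw) {
          const int w_in = ow * sw - pw + iw * dw;
          if (w_in < 0 || w_in >= W) continue;
          for (int ih = 0; ih < kh; ++ih) {
            const int h_in = oh * sh - ph + ih * dh;
            if (h_in < 0 || h_in >= H) continue;
            for (int id = 0; id < kd; ++id) {
              const int d_in = od * sd - pd + id * dd;
              if (d_in < 0 || d_in >= D) continue;
              const int t = id + kd * (ih + kh * iw);
              const size_t xoff = (size_t)d_in + (size_t)D * (h_in + (size_t)H * w_in);
              for (int c = 0; c < C; ++c) {
                gx[xoff + (size_t)D * H * W * c] += cp[t + T * c];
              }
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector x, NumericVector w, NumericVector b,
                             IntegerVector stride, IntegerVector dil,
                             IntegerVector pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int D = xd[0], H = xd[1], W = xd[2], C = xd[3], B = xd[4];
  const int kd = wd[0], kh = wd[1], kw = wd[2], Ci = wd[3], Co = wd[4];
  if (Ci != C) stop("conv3d: input has %d channels, kernel expects %d", C, Ci);
  const int sd = stride[0], sh = stride[1], sw = stride[2];
  const int dd = dil[0], dh = dil[1], dw = dil[2];
  const int pd = pad[0], ph = pad[1], pw = pad[2];
  const int Do = out_dim(D, kd, sd, dd, pd);
  const int Ho = out_dim(H, kh, sh, dh, ph);
  const int Wo = out_dim(W, kw, sw, dw, pw);
  if (Do < 1 || Ho < 1 || Wo < 1)
    stop("conv3d: effective kernel exceeds padded input extent");
  const int K = kd * kh * kw * C;
  const size_t P = (size_t)Do * Ho * Wo;

  NumericVector y(P * Co * B);
  y.attr("dim") = IntegerVector::create(Do, Ho, Wo, Co, B);

  arma::mat Wk(const_cast<double*>(w.begin()), K, Co, false, true);
  arma::mat col(K, P);
  const size_t xstride = (size_t)D * H * W * C;
  const size_t ystride = P * Co;
  for (int bb = 0; bb < B; ++bb) {
    im2col(x.begin() + xstride * bb, D, H, W, C, kd, kh, kw,
           sd, sh, sw, dd, dh, dw, pd, ph, pw, Do, Ho, Wo, col);
    arma::mat Y(y.begin() + ystride * bb, P, Co, false, true);
    Y = col.t() * Wk;             // P x Co
    for (int o = 0; o < Co; ++o) Y.col(o) += b[o];
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv3d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                    IntegerVector stride, IntegerVector dil, IntegerVector pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  IntegerVector yd = gy.attr("dim");
  const int D = xd[0], H = xd[1], W = xd[2], C = xd[3], B = xd[4];
  const int kd = wd[0], kh = wd[1], kw = wd[2], Co = wd[4];
  const int Do = yd[0], Ho = yd[1], Wo = yd[2];
  const int sd = stride[0], sh = stride[1], sw = stride[2];
  const int dd = dil[0], dh = dil[1], dw = dil[2];
  const int pd = pad[0], ph = pad[1], pw = pad[2];
  const int K = kd * kh * kw * C;
  const size_t P = (size_t)Do * Ho * Wo;

  NumericVector gx(x.size());
  gx.attr("dim") = xd;
  NumericVector gw(w.size());
  gw.attr("dim") = wd;
  NumericVector gb(Co);

  arma::mat Wk(const_cast<double*>(w.begin()), K, Co, false, true);
  arma::mat GW(gw.begin(), K, Co, false, true);
  arma::vec GB(gb.begin(), Co, false, true);
  arma::mat col(K, P);
  const size_t xstride = (size_t)D * H * W * C;
  const size_t ystride = P * Co;
  for (int bb = 0; bb < B; ++bb) {
    im2col(x.begin() + xstride * bb, D, H, W, C, kd, kh, kw,
           sd, sh, sw, dd, dh, dw, pd, ph, pw, Do, Ho, Wo, col);
    arma::mat G(const_cast<double*>(gy.begin()) + ystride * bb, P, Co, false, true);
    GW += col * G;
    GB += arma::sum(G, 0).t();
    arma::mat gcol = Wk * G.t();  // K x P
    col2im(gcol, gx.begin() + xstride * bb, D, H, W, C, kd, kh, kw,
           sd, sh, sw, dd, dh, dw, pd, ph, pw, Do, Ho, Wo);
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
List cpp_maxpool3d_fwd(NumericVector x, IntegerVector ksize, IntegerVector stride) {
  IntegerVector xd = x.attr("dim");
  const int D = xd[0], H = xd[1], W = xd[2], C = xd[3], B = xd[4];
  const int kd = ksize[0], kh = ksize[1], kw = ksize[2];
  const int sd = stride[0], sh = stride[1], sw = stride[2];
  const int Do = (D - kd) / sd + 1, Ho = (H - kh) / sh + 1, Wo = (W - kw) / sw + 1;
  if (Do < 1 || Ho < 1 || Wo < 1) stop("maxpool3d: input smaller than kernel");
  const size_t P = (size_t)Do * Ho * Wo;

  NumericVector y(P * C * B);
  y.attr("dim") = IntegerVector::create(Do, Ho, Wo, C, B);
  IntegerVector arg(P * C * B);   // linear index into the (D,H,W) block

  const size_t xs = (size_t)D * H * W;
  size_t q = 0;
  for (int bb = 0; bb < B; ++bb) {
    for (int c = 0; c < C; ++c) {
      const double* xp = x.begin() + xs * (c + (size_t)C * bb);
      for (int ow = 0; ow < Wo; ++ow)
        for (int oh = 0; oh < Ho; ++oh)
          for (int od = 0; od < Do; ++od) {
            double best = R_NegInf; int besti = -1;
            for (int iw = 0; iw < kw; ++iw)
              for (int ih = 0; ih < kh; ++ih)
                for (int id = 0; id < kd; ++id) {
                  const int dI = od * sd + id, hI = oh * sh + ih, wI = ow * sw + iw;
                  const size_t li = (size_t)dI + (size_t)D * (hI + (size_t)H * wI);
                  if (xp[li] > best) { best = xp[li]; besti = (int)li; }
                }
            const size_t yi = (size_t)(od + Do * (oh + (size_t)Ho * ow)) + P * (c + (size_t)C * bb);
            y[yi] = best; arg[yi] = besti;
            ++q;
          }
    }
  }
  (void)q;
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool3d_bwd(NumericVector gy, IntegerVector argmax,
                                IntegerVector xdim) {
  IntegerVector yd = gy.attr("dim");
  const int C = yd[3], B = yd[4];
  const size_t P = (size_t)yd[0] * yd[1] * yd[2];
  const size_t xs = (size_t)xdim[0] * xdim[1] * xdim[2];
  NumericVector gx((size_t)xs * C * B);
  gx.attr("dim") = xdim;
  for (int bb = 0; bb < B; ++bb)
    for (int c = 0; c < C; ++c) {
      double* gp = gx.begin() + xs * (c + (size_t)C * bb);
      const size_t off = P * (c + (size_t)C * bb);
      for (size_t p = 0; p < P; ++p) gp[argmax[off + p]] += gy[off + p];
    }
  return gx;
}

static inline void ada_bounds(int i, int in, int out, int* lo, int* hi) {
  *lo = (int)std::floor((double)i * in / out);
  *hi = (int)std::ceil((double)(i + 1) * in / out);
}

// [[Rcpp::export]]
NumericVector cpp_adapool3d_fwd(NumericVector x, IntegerVector odim) {
  IntegerVector xd = x.attr("dim");
  const int D = xd[0], H = xd[1], W = xd[2], C = xd[3], B = xd[4];
  const int Do = odim[0], Ho = odim[1], Wo = odim[2];
  const size_t P = (size_t)Do * Ho * Wo, xs = (size_t)D * H * W;
  NumericVector y(P * C * B);
  y.attr("dim") = IntegerVector::create(Do, Ho, Wo, C, B);
  for (int bb = 0; bb < B; ++bb)
    for (int c = 0; c < C; ++c) {
      const double* xp = x.begin() + xs * (c + (size_t)C * bb);
      double* yp = y.begin() + P * (c + (size_t)C * bb);
      for (int ow = 0; ow < Wo; ++ow) {
        int wlo, whi; ada_bounds(ow, W, Wo, &wlo, &whi);
        for (int oh = 0; oh < Ho; ++oh) {
          int hlo, hhi; ada_bounds(oh, H, Ho, &hlo, &hhi);
          for (int od = 0; od < Do; ++od) {
            int dlo, dhi; ada_bounds(od, D, Do, &dlo, &dhi);
            double s = 0.0;
            for (int wI = wlo; wI < whi; ++wI)
              for (int hI = hlo; hI < hhi; ++hI)
                for (int dI = dlo; dI < dhi; ++dI)
                  s += xp[(size_t)dI + (size_t)D * (hI + (size_t)H * wI)];
            yp[od + Do * (oh + (size_t)Ho * ow)] =
              s / ((dhi - dlo) * (double)(hhi - hlo) * (whi - wlo));
          }
        }
      }
    }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_adapool3d_bwd(NumericVector gy, IntegerVector xdim) {
  IntegerVector yd = gy.attr("dim");
  const int Do = yd[0], Ho = yd[1], Wo = yd[2], C = yd[3], B = yd[4];
  const int D = xdim[0], H = xdim[1], W = xdim[2];
  const size_t P = (size_t)Do * Ho * Wo, xs = (size_t)D * H * W;
  NumericVector gx(xs * C * B);
  gx.attr("dim") = xdim;
  for (int bb = 0; bb < B; ++bb)
    for (int c = 0; c < C; ++c) {
      double* gp = gx.begin() + xs * (c + (size_t)C * bb);
      const double* yp = gy.begin() + P * (c + (size_t)C * bb);
      for (int ow = 0; ow < Wo; ++ow) {
        int wlo, whi; ada_bounds(ow, W, Wo, &wlo, &whi);
        for (int oh = 0; oh < Ho; ++oh) {
          int hlo, hhi; ada_bounds(oh, H, Ho, &hlo, &hhi);
          for (int od = 0; od < Do; ++od) {
            int dlo, dhi; ada_bounds(od, D, Do, &dlo, &dhi);
            const double g = yp[od + Do * (oh + (size_t)Ho * ow)] /
              ((dhi - dlo) * (double)(hhi - hlo) * (whi - wlo));
            for (int wI = wlo; wI < whi; ++wI)
              for (int hI = hlo; hI < hhi; ++hI)
                for (int dI = dlo; dI < dhi; ++dI)
                  gp[(size_t)dI + (size_t)D * (hI + (size_t)H * wI)] += g;
          }
        }
      }
    }
  return gx;
}

struct LinW { int i0, i1; double w0, w1; };

static void lin_weights(int out, int in, std::vector<LinW>& tab) {
  tab.resize(out);
  const double scale = (double)in / out;
  for (int i = 0; i < out; ++i) {
    double src = (i + 0.5) * scale - 0.5;
    if (src < 0) src = 0;
    if (src > in - 1) src = in - 1;
    const int i0 = (int)std::floor(src);
    const int i1 = std::min(i0 + 1, in - 1);
    const double f = src - i0;
    tab[i] = {i0, i1, 1.0 - f, f};
  }
}

// [[Rcpp::export]]
NumericVector cpp_resize3d_fwd(NumericVector x, IntegerVector odim) {
  IntegerVector xd = x.attr("dim");
  const int D = xd[0], H = xd[1], W = xd[2], C = xd[3], B = xd[4];
  const int Do = odim[0], Ho = odim[1], Wo = odim[2];
  const size_t P = (size_t)Do * Ho * Wo, xs = (size_t)D * H * W;
  std::vector<LinW> td, th, tw;
  lin_weights(Do, D, td); lin_weights(Ho, H, th); lin_weights(Wo, W, tw);
  NumericVector y(P * C * B);
  y.attr("dim") = IntegerVector::create(Do, Ho, Wo, C, B);
  for (int bb = 0; bb < B; ++bb)
    for (int c = 0; c < C; ++c) {
      const double* xp = x.begin() + xs * (c + (size_t)C * bb);
      double* yp = y.begin() + P * (c + (size_t)C * bb);
      for (int ow = 0; ow < Wo; ++ow)
        for (int oh = 0; oh < Ho; ++oh)
          for (int od = 0; od < Do; ++od) {
            const LinW &a = td[od], &b2 = th[oh], &c2 = tw[ow];
            double s = 0.0;
            s += a.w0 * b2.w0 * c2.w0 * xp[(size_t)a.i0 + (size_t)D * (b2.i0 + (size_t)H * c2.i0)];
            s += a.w1 * b2.w0 * c2.w0 * xp[(size_t)a.i1 + (size_t)D * (b2.i0 + (size_t)H * c2.i0)];
            s += a.w0 * b2.w1 * c2.w0 * xp[(size_t)a.i0 + (size_t)D * (b2.i1 + (size_t)H * c2.i0)];
            s += a.w1 * b2.w1 * c2.w0 * xp[(size_t)a.i1 + (size_t)D * (b2.i1 + (size_t)H * c2.i0)];
            s += a.w0 * b2.w0 * c2.w1 * xp[(size_t)a.i0 + (size_t)D * (b2.i0 + (size_t)H * c2.i1)];
            s += a.w1 * b2.w0 * c2.w1 * xp[(size_t)a.i1 + (size_t)D * (b2.i0 + (size_t)H * c2.i1)];
            s += a.w0 * b2.w1 * c2.w1 * xp[(size_t)a.i0 + (size_t)D * (b2.i1 + (size_t)H * c2.i1)];
            s += a.w1 * b2.w1 * c2.w1 * xp[(size_t)a.i1 + (size_t)D * (b2.i1 + (size_t)H * c2.i1)];
            yp[od + Do * (oh + (size_t)Ho * ow)] = s;
          }
    }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_resize3d_bwd(NumericVector gy, IntegerVector xdim) {
  IntegerVector yd = gy.attr("dim");
  const int Do = yd[0], Ho = yd[1], Wo = yd[2], C = yd[3], B = yd[4];
  const int D = xdim[0], H = xdim[1], W = xdim[2];
  const size_t P = (size_t)Do * Ho * Wo, xs = (size_t)D * H * W;
  std::vector<LinW> td, th, tw;
  lin_weights(Do, D, td); lin_weights(Ho, H, th); lin_weights(Wo, W, tw);
  NumericVector gx(xs * C * B);
  gx.attr("dim") = xdim;
  for (int bb = 0; bb < B; ++bb)
    for (int c = 0; c < C; ++c) {
      double* gp = gx.begin() + xs * (c + (size_t)C * bb);
      const double* yp = gy.begin() + P * (c + (size_t)C * bb);
      for (int ow = 0; ow < Wo; ++ow)
        for (int oh = 0; oh < Ho; ++oh)
          for (int od = 0; od < Do; ++od) {
            const LinW &a = td[od], &b2 = th[oh], &c2 = tw[ow];
            const double g = yp[od + Do * (oh + (size_t)Ho * ow)];
            gp[(size_t)a.i0 + (size_t)D * (b2.i0 + (size_t)H * c2.i0)] += g * a.w0 * b2.w0 * c2.w0;
            gp[(size_t)a.i1 + (size_t)D * (b2.i0 + (size_t)H * c2.i0)] += g * a.w1 * b2.w0 * c2.w0;
            gp[(size_t)a.i0 + (size_t)D * (b2.i1 + (size_t)H * c2.i0)] += g * a.w0 * b2.w1 * c2.w0;
            gp[(size_t)a.i1 + (size_t)D * (b2.i1 + (size_t)H * c2.i0)] += g * a.w1 * b2.w1 * c2.w0;
            gp[(size_t)a.i0 + (size_t)D * (b2.i0 + (size_t)H * c2.i1)] += g * a.w0 * b2.w0 * c2.w1;
            gp[(size_t)a.i1 + (size_t)D * (b2.i0 + (size_t)H * c2.i1)] += g * a.w1 * b2.w0 * c2.w1;
            gp[(size_t)a.i0 + (size_t)D * (b2.i1 + (size_t)H * c2.i1)] += g * a.w0 * b2.w1 * c2.w1;
            gp[(size_t)a.i1 + (size_t)D * (b2.i1 + (size_t)H * c2.i1)] += g * a.w1 * b2.w1 * c2.w1;
          }
    }
  return gx;
}

// --- small fused elementwise helpers (avoid large R temporaries) -----------

// y[p + P*j] = x[p + P*j] * sc[j] + off[j], for j in 0..(ncol-1)
// [[Rcpp::export]]
NumericVector cpp_col_scale_shift(NumericVector x, int P, NumericVector sc,
                                  NumericVector off) {
  const R_xlen_t N = x.size();
  const int J = (int)(N / P);
  NumericVector y(N);
  for (int j = 0; j < J; ++j) {
    const double s = sc[j], o = off[j];
    const double* xp = x.begin() + (size_t)P * j;
    double* yp = y.begin() + (size_t)P * j;
    for (int p = 0; p < P; ++p) yp[p] = xp[p] * s + o;
  }
  y.attr("dim") = x.attr("dim");
  return y;
}

// gx = (gm - a[j] - xhat * b[j]) * sc[j]  (fused BN training backward)
// [[Rcpp::export]]
NumericVector cpp_bn_bwd_fused(NumericVector gm, NumericVector xhat, int P,
                               NumericVector a, NumericVector b,
                               NumericVector sc) {
  const R_xlen_t N = gm.size();
  const int J = (int)(N / P);
  NumericVector gx(N);
  for (int j = 0; j < J; ++j) {
    const double aj = a[j], bj = b[j], sj = sc[j];
    const double* gp = gm.begin() + (size_t)P * j;
    const double* xp = xhat.begin() + (size_t)P * j;
    double* op = gx.begin() + (size_t)P * j;
    for (int p = 0; p < P; ++p) op[p] = (gp[p] - aj - xp[p] * bj) * sj;
  }
  gx.attr("dim") = gm.attr("dim");
  return gx;
}

// [[Rcpp::export]]
NumericVector cpp_relu_fwd(NumericVector x) {
  NumericVector y(x.size());
  const double* xp = x.begin(); double* yp = y.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) yp[i] = xp[i] > 0 ? xp[i] : 0.0;
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_relu_bwd(NumericVector g, NumericVector y) {
  NumericVector gx(g.size());
  const double* gp = g.begin(); const double* yp = y.begin();
  double* op = gx.begin();
  for (R_xlen_t i = 0; i < g.size(); ++i) op[i] = yp[i] > 0 ? gp[i] : 0.0;
  gx.attr("dim") = g.attr("dim");
  return gx;
}

// gate forward: y[p + P*(c + C*b)] = x[...] * alpha[p + P*b]
// [[Rcpp::export]]
NumericVector cpp_gate_fwd(NumericVector x, NumericVector alpha, int P, int C,
                           int B) {
  NumericVector y(x.size());
  for (int bb = 0; bb < B; ++bb) {
    const double* ap = alpha.begin() + (size_t)P * bb;
    for (int c = 0; c < C; ++c) {
      const size_t off = (size_t)P * (c + (size_t)C * bb);
      const double* xp = x.begin() + off;
      double* yp = y.begin() + off;
      for (int p = 0; p < P; ++p) yp[p] = xp[p] * ap[p];
    }
  }
  y.attr("dim") = x.attr("dim");
  return y;
}

// gate backward: gx = g * alpha (broadcast); galpha[p,b] = sum_c g*x
// [[Rcpp::export]]
List cpp_gate_bwd(NumericVector g, NumericVector x, NumericVector alpha,
                  int P, int C, int B) {
  NumericVector gx(x.size());
  NumericVector ga((size_t)P * B);
  for (int bb = 0; bb < B; ++bb) {
    const double* ap = alpha.begin() + (size_t)P * bb;
    double* gap = ga.begin() + (size_t)P * bb;
    for (int c = 0; c < C; ++c) {
      const size_t off = (size_t)P * (c + (size_t)C * bb);
      const double* gp = g.begin() + off;
      const double* xp = x.begin() + off;
      double* gxp = gx.begin() + off;
      for (int p = 0; p < P; ++p) {
        gxp[p] = gp[p] * ap[p];
        gap[p] += gp[p] * xp[p];
      }
    }
  }
  gx.attr("dim") = x.attr("dim");
  return List::create(_["gx"] = gx, _["galpha"] = ga);
}
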