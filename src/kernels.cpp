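// Numeric kernels for the detector scaffold.
//
// All feature maps are dense R arrays with dim (H, W, C, N), column-major,
// so x[h, w, c, n] sits at h + H*(w + W*(c + C*n)).  Convolution weights
// are stored (k, k, Cin/groups, Cout).  Forward and backward passes are
// paired; the R-level tape calls the backward twin with the upstream
// gradient and scatters parameter gradients itself.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline IntegerVector arr_dim(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  return d;
}

// im2col for one image (channels [c0, c0+Cg) of image n).
// cols is (k*k*Cg) x (Ho*Wo); row index r = kh + k*kw + k*k*ci.
template <typename M>
static void im2col(const double* x, int H, int W, int C, int n,
                   int c0, int Cg, int k, int stride, int pad,
                   int Ho, int Wo, M& cols) {
  const double* xb = x + (size_t)H * W * C * n;
  for (int ci = 0; ci < Cg; ++ci) {
    const double* xc = xb + (size_t)H * W * (c0 + ci);
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        int r = kh + k * kw + k * k * ci;
        for (int ow = 0; ow < Wo; ++ow) {
          int iw = ow * stride - pad + kw;
          if (iw < 0 || iw >= W) {
            for (int oh = 0; oh < Ho; ++oh)
              cols(r, oh + Ho * ow) = 0.0;
            continue;
          }
          const double* xcol = xc + (size_t)H * iw;
          for (int oh = 0; oh < Ho; ++oh) {
            int ih = oh * stride - pad + kh;
            cols(r, oh + Ho * ow) =
              (ih < 0 || ih >= H) ? 0.0 : xcol[ih];
          }
        }
      }
    }
  }
}

// col2im accumulate (transpose of im2col).
template <typename M>
static void col2im(const M& cols, double* dx, int H, int W, int C,
                   int n, int c0, int Cg, int k, int stride, int pad,
                   int Ho, int Wo) {
  double* xb = dx + (size_t)H * W * C * n;
  for (int ci = 0; ci < Cg; ++ci) {
    double* xc = xb + (size_t)H * W * (c0 + ci);
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        int r = kh + k * kw + k * k * ci;
        for (int ow = 0; ow < Wo; ++ow) {
          int iw = ow * stride - pad + kw;
          if (iw < 0 || iw >= W) continue;
          double* xcol = xc + (size_t)H * iw;
          for (int oh = 0; oh < Ho; ++oh) {
            int ih = oh * stride - pad + kh;
            if (ih < 0 || ih >= H) continue;
            xcol[ih] += cols(r, oh + Ho * ow);
          }
        }
      }
    }
  }
}

// im2col over the whole batch: cols is (k*k*Cg) x (N*Ho*Wo)
template <typename M>
static void im2col_batch(const double* x, int H, int W, int C, int N,
                         int c0, int Cg, int k, int stride, int pad,
                         int Ho, int Wo, M& cols) {
  for (int n = 0; n < N; ++n) {
    M sub(cols.colptr((size_t)n * Ho * Wo), cols.n_rows,
          (size_t)Ho * Wo, false, true);
    im2col(x, H, W, C, n, c0, Cg, k, stride, pad, Ho, Wo, sub);
  }
}

template <typename M>
static void col2im_batch(const M& cols, double* dx, int H, int W,
                         int C, int N, int c0, int Cg, int k, int stride,
                         int pad, int Ho, int Wo) {
  for (int n = 0; n < N; ++n) {
    M sub(const_cast<typename M::elem_type*>(
            cols.colptr((size_t)n * Ho * Wo)),
          cols.n_rows, (size_t)Ho * Wo, false, true);
    col2im(sub, dx, H, W, C, n, c0, Cg, k, stride, pad, Ho, Wo);
  }
}

// fused conv (+ optional batch-norm) (+ optional SiLU), training mode.
// Returns y and the caches the backward pass needs.
// [[Rcpp::export]]
List cpp_cbs_fwd(NumericVector x, NumericVector w, int stride, int pad,
                 int groups, NumericVector gamma, NumericVector beta,
                 double eps, bool act) {
  IntegerVector xd = arr_dim(x), wd = arr_dim(w);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0], Cg = wd[2], Cout = wd[3];
  int Cout_g = Cout / groups;
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  size_t HWo = (size_t)Ho * Wo;
  NumericVector z(HWo * Cout * N);        // pre-activation (post-BN)
  z.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)k * k * Cg, Cout,
               false);
  arma::fmat Wf = arma::conv_to<arma::fmat>::from(Wm);
  arma::fmat cols((size_t)(k == 1 && stride == 1 && pad == 0 &&
                           groups == 1 ? 0 : k * k * Cg),
                  (size_t)(k == 1 && stride == 1 && pad == 0 &&
                           groups == 1 ? 0 : HWo * N));
  NumericVector mean(Cout), var(Cout);
  bool pointwise = (k == 1 && stride == 1 && pad == 0 && groups == 1);
  if (pointwise) {
    // 1x1 conv: each image is already an (HW x C) matrix
    for (int n = 0; n < N; ++n) {
      arma::mat Xn(const_cast<double*>(x.begin()) + (size_t)H * W * C * n,
                   (size_t)H * W, C, false);
      arma::fmat Zn = arma::conv_to<arma::fmat>::from(Xn) * Wf;
      double* zp = z.begin() + HWo * Cout * (size_t)n;
      const float* sp = Zn.memptr();
      for (size_t i = 0; i < HWo * Cout; ++i) zp[i] = sp[i];
    }
  } else {
  // conv into z (temporarily raw conv output); gemm in single precision
  for (int g = 0; g < groups; ++g) {
    im2col_batch(x.begin(), H, W, C, N, g * Cg, Cg, k, stride, pad, Ho, Wo,
                 cols);
    arma::fmat Wg = Wf.cols(g * Cout_g, (g + 1) * Cout_g - 1);
    arma::fmat out = Wg.t() * cols; // Cout_g x (N*Ho*Wo)
    for (int co = 0; co < Cout_g; ++co)
      for (int n = 0; n < N; ++n) {
        double* zp = z.begin() + HWo * (g * Cout_g + co) +
          HWo * Cout * n;
        const float* op = out.colptr((size_t)n * HWo) + co;
        for (size_t i = 0; i < HWo; ++i) zp[i] = op[i * Cout_g];
      }
  }
  }
  // batch norm statistics + normalise + silu
  size_t m = HWo * N;
  for (int c = 0; c < Cout; ++c) {
    double s = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* zp = z.begin() + HWo * (c + (size_t)Cout * n);
      for (size_t i = 0; i < HWo; ++i) s += zp[i];
    }
    mean[c] = s / m;
    double v = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* zp = z.begin() + HWo * (c + (size_t)Cout * n);
      for (size_t i = 0; i < HWo; ++i) {
        double d = zp[i] - mean[c];
        v += d * d;
      }
    }
    var[c] = v / m;
  }
  NumericVector xhat(z.size()), y(z.size());
  xhat.attr("dim") = z.attr("dim");
  y.attr("dim") = z.attr("dim");
  NumericVector zkeep(act ? z.size() : 0);
  for (int c = 0; c < Cout; ++c) {
    double inv = 1.0 / std::sqrt(var[c] + eps);
    for (int n = 0; n < N; ++n) {
      size_t off = HWo * (c + (size_t)Cout * n);
      const double* zp = z.begin() + off;
      double* hp = xhat.begin() + off;
      double* yp = y.begin() + off;
      for (size_t i = 0; i < HWo; ++i) {
        hp[i] = (zp[i] - mean[c]) * inv;
        double zz = gamma[c] * hp[i] + beta[c];
        if (act) {
          zkeep[off + i] = zz;
          yp[i] = zz / (1.0 + std::exp(-zz));
        } else {
          yp[i] = zz;
        }
      }
    }
  }
  if (act) zkeep.attr("dim") = z.attr("dim");
  return List::create(_["y"] = y, _["xhat"] = xhat, _["z"] = zkeep,
                      _["mean"] = mean, _["var"] = var);
}

// [[Rcpp::export]]
List cpp_cbs_bwd(NumericVector x, NumericVector w, NumericVector dy,
                 NumericVector xhat, NumericVector z, NumericVector gamma,
                 NumericVector var, double eps, int stride, int pad,
                 int groups, bool act) {
  IntegerVector xd = arr_dim(x), wd = arr_dim(w), yd = arr_dim(dy);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0], Cg = wd[2], Cout = wd[3];
  int Cout_g = Cout / groups;
  int Ho = yd[0], Wo = yd[1];
  size_t HWo = (size_t)Ho * Wo;
  size_t m = HWo * N;
  // silu backward into dz (post-BN gradient)
  NumericVector dz(dy.size());
  if (act) {
    for (R_xlen_t i = 0; i < dy.size(); ++i) {
      double zz = z[i];
      double s = 1.0 / (1.0 + std::exp(-zz));
      dz[i] = dy[i] * s * (1.0 + zz * (1.0 - s));
    }
  } else {
    dz = clone(dy);
  }
  // batch-norm backward into dconv
  NumericVector dgamma(Cout), dbeta(Cout);
  NumericVector dconv(dy.size());
  for (int c = 0; c < Cout; ++c) {
    double sdy = 0.0, sdyh = 0.0;
    for (int n = 0; n < N; ++n) {
      size_t off = HWo * (c + (size_t)Cout * n);
      const double* dp = dz.begin() + off;
      const double* hp = xhat.begin() + off;
      for (size_t i = 0; i < HWo; ++i) {
        sdy += dp[i];
        sdyh += dp[i] * hp[i];
      }
    }
    dgamma[c] = sdyh;
    dbeta[c] = sdy;
    double inv = gamma[c] / std::sqrt(var[c] + eps);
    double mdy = sdy / m, mdyh = sdyh / m;
    for (int n = 0; n < N; ++n) {
      size_t off = HWo * (c + (size_t)Cout * n);
      const double* dp = dz.begin() + off;
      const double* hp = xhat.begin() + off;
      double* cp = dconv.begin() + off;
      for (size_t i = 0; i < HWo; ++i)
        cp[i] = inv * (dp[i] - mdy - hp[i] * mdyh);
    }
  }
  // conv backward (batched gemm)
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = xd;
  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)k * k * Cg, Cout,
               false);
  arma::fmat Wf = arma::conv_to<arma::fmat>::from(Wm);
  arma::mat dWm(dw.begin(), (size_t)k * k * Cg, Cout, false, true);
  bool pointwise = (k == 1 && stride == 1 && pad == 0 && groups == 1);
  if (pointwise) {
    arma::fmat dWf((size_t)C, Cout, arma::fill::zeros);
    for (int n = 0; n < N; ++n) {
      arma::mat Xn(const_cast<double*>(x.begin()) + (size_t)H * W * C * n,
                   (size_t)H * W, C, false);
      arma::mat Dn(dconv.begin() + HWo * Cout * (size_t)n, HWo, Cout,
                   false);
      arma::fmat Xf = arma::conv_to<arma::fmat>::from(Xn);
      arma::fmat Df = arma::conv_to<arma::fmat>::from(Dn);
      dWf += Xf.t() * Df;
      arma::fmat dXf = Df * Wf.t();
      double* dp = dx.begin() + (size_t)H * W * C * n;
      const float* sp = dXf.memptr();
      for (size_t i = 0; i < (size_t)H * W * C; ++i) dp[i] = sp[i];
    }
    dWm += arma::conv_to<arma::mat>::from(dWf);
    return List::create(_["dx"] = dx, _["dw"] = dw, _["dgamma"] = dgamma,
                        _["dbeta"] = dbeta);
  }
  arma::fmat cols((size_t)k * k * Cg, HWo * N);
  arma::fmat dyg(Cout_g, HWo * N);
  for (int g = 0; g < groups; ++g) {
    im2col_batch(x.begin(), H, W, C, N, g * Cg, Cg, k, stride, pad, Ho, Wo,
                 cols);
    for (int co = 0; co < Cout_g; ++co)
      for (int n = 0; n < N; ++n) {
        const double* dp = dconv.begin() + HWo * (g * Cout_g + co) +
          HWo * Cout * n;
        float* gp = dyg.colptr((size_t)n * HWo) + co;
        for (size_t i = 0; i < HWo; ++i) gp[i * Cout_g] = (float)dp[i];
      }
    arma::fmat dWf = cols * dyg.t();
    dWm.cols(g * Cout_g, (g + 1) * Cout_g - 1) +=
      arma::conv_to<arma::mat>::from(dWf);
    arma::fmat Wg = Wf.cols(g * Cout_g, (g + 1) * Cout_g - 1);
    arma::fmat dcols = Wg * dyg;
    col2im_batch(dcols, dx.begin(), H, W, C, N, g * Cg, Cg, k, stride, pad,
                 Ho, Wo);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// fused conv + affine (folded running-stat BN) + optional SiLU, eval mode
// [[Rcpp::export]]
NumericVector cpp_cbs_eval(NumericVector x, NumericVector w, int stride,
                           int pad, int groups, NumericVector scale,
                           NumericVector shift, bool act) {
  IntegerVector xd = arr_dim(x), wd = arr_dim(w);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0], Cg = wd[2], Cout = wd[3];
  int Cout_g = Cout / groups;
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  size_t HWo = (size_t)Ho * Wo;
  NumericVector y(HWo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)k * k * Cg, Cout,
               false);
  arma::fmat Wf = arma::conv_to<arma::fmat>::from(Wm);
  if (k == 1 && stride == 1 && pad == 0 && groups == 1) {
    for (int n = 0; n < N; ++n) {
      arma::mat Xn(const_cast<double*>(x.begin()) + (size_t)H * W * C * n,
                   (size_t)H * W, C, false);
      arma::fmat Zn = arma::conv_to<arma::fmat>::from(Xn) * Wf;
      double* yp = y.begin() + HWo * Cout * (size_t)n;
      const float* sp = Zn.memptr();
      for (int c = 0; c < Cout; ++c)
        for (size_t i = 0; i < HWo; ++i) {
          double zz = (double)sp[(size_t)c * HWo + i] * scale[c] + shift[c];
          yp[(size_t)c * HWo + i] = act ? zz / (1.0 + std::exp(-zz)) : zz;
        }
    }
    return y;
  }
  arma::fmat cols((size_t)k * k * Cg, HWo * N);
  for (int g = 0; g < groups; ++g) {
    im2col_batch(x.begin(), H, W, C, N, g * Cg, Cg, k, stride, pad, Ho, Wo,
                 cols);
    arma::fmat Wg = Wf.cols(g * Cout_g, (g + 1) * Cout_g - 1);
    arma::fmat out = Wg.t() * cols;
    for (int co = 0; co < Cout_g; ++co) {
      int c = g * Cout_g + co;
      for (int n = 0; n < N; ++n) {
        double* yp = y.begin() + HWo * (c + (size_t)Cout * n);
        const float* op = out.colptr((size_t)n * HWo) + co;
        for (size_t i = 0; i < HWo; ++i) {
          double zz = op[i * Cout_g] * scale[c] + shift[c];
          yp[i] = act ? zz / (1.0 + std::exp(-zz)) : zz;
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w,
                             Nullable<NumericVector> bias,
                             int stride, int pad, int groups) {
  IntegerVector xd = arr_dim(x), wd = arr_dim(w);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0], Cg = wd[2], Cout = wd[3];
  if (C != Cg * groups) stop("conv2d: channel/group mismatch");
  int Cout_g = Cout / groups;
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector y((size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)k * k * Cg, Cout, false);
  arma::mat cols((size_t)k * k * Cg, (size_t)Ho * Wo);
  bool has_b = bias.isNotNull();
  NumericVector bv;
  if (has_b) bv = bias.get();
  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < groups; ++g) {
      im2col(x.begin(), H, W, C, n, g * Cg, Cg, k, stride, pad, Ho, Wo, cols);
      arma::mat Wg = Wm.cols(g * Cout_g, (g + 1) * Cout_g - 1);
      arma::mat out = Wg.t() * cols; // Cout_g x (Ho*Wo)
      for (int co = 0; co < Cout_g; ++co) {
        double* yp = y.begin() +
          (size_t)Ho * Wo * (g * Cout_g + co) + (size_t)Ho * Wo * Cout * n;
        double b = has_b ? bv[g * Cout_g + co] : 0.0;
        for (size_t i = 0; i < (size_t)Ho * Wo; ++i) yp[i] = out(co, i) + b;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                    int stride, int pad, int groups, bool has_bias) {
  IntegerVector xd = arr_dim(x), wd = arr_dim(w), yd = arr_dim(dy);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0], Cg = wd[2], Cout = wd[3];
  int Cout_g = Cout / groups;
  int Ho = yd[0], Wo = yd[1];
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = xd;
  NumericVector dw((size_t)k * k * Cg * Cout);
  dw.attr("dim") = wd;
  NumericVector db(has_bias ? Cout : 0);
  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)k * k * Cg, Cout, false);
  arma::mat dWm(dw.begin(), (size_t)k * k * Cg, Cout, false, true);
  arma::mat cols((size_t)k * k * Cg, (size_t)Ho * Wo);
  arma::mat dcols((size_t)k * k * Cg, (size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < groups; ++g) {
      im2col(x.begin(), H, W, C, n, g * Cg, Cg, k, stride, pad, Ho, Wo, cols);
      // dy block for this group: Cout_g x (Ho*Wo)
      arma::mat dyg(Cout_g, (size_t)Ho * Wo);
      for (int co = 0; co < Cout_g; ++co) {
        const double* dyp = dy.begin() +
          (size_t)Ho * Wo * (g * Cout_g + co) + (size_t)Ho * Wo * Cout * n;
        for (size_t i = 0; i < (size_t)Ho * Wo; ++i) dyg(co, i) = dyp[i];
        if (has_bias) {
          double s = 0.0;
          for (size_t i = 0; i < (size_t)Ho * Wo; ++i) s += dyp[i];
          db[g * Cout_g + co] += s;
        }
      }
      dWm.cols(g * Cout_g, (g + 1) * Cout_g - 1) += cols * dyg.t();
      arma::mat Wg = Wm.cols(g * Cout_g, (g + 1) * Cout_g - 1);
      dcols = Wg * dyg;
      col2im(dcols, dx.begin(), H, W, C, n, g * Cg, Cg, k, stride, pad, Ho, Wo);
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = arr_dim(x);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx((size_t)Ho * Wo * C * N); // 0-based linear index into x
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xp = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      for (int ow = 0; ow < Wo; ++ow)
        for (int oh = 0; oh < Ho; ++oh) {
          double best = -std::numeric_limits<double>::infinity();
          int bi = -1;
          for (int kw = 0; kw < k; ++kw) {
            int iw = ow * stride - pad + kw;
            if (iw < 0 || iw >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              int ih = oh * stride - pad + kh;
              if (ih < 0 || ih >= H) continue;
              double v = xp[ih + (size_t)H * iw];
              if (v > best) { best = v; bi = ih + H * iw; }
            }
          }
          size_t oo = (size_t)(oh + Ho * ow) + (size_t)Ho * Wo * (c + (size_t)C * n);
          y[oo] = best;
          idx[oo] = bi + (int)((size_t)H * W * (c + (size_t)C * n));
          ++o;
        }
    }
  (void)o;
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector dy, IntegerVector idx,
                              IntegerVector xdim) {
  size_t nx = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(nx);
  dx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[idx[i]] += dy[i];
  return dx;
}

// [[Rcpp::export]]
NumericVector cpp_upsample_nn_fwd(NumericVector x, int f) {
  IntegerVector xd = arr_dim(x);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = H * f, Wo = W * f;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xp = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      double* yp = y.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int ow = 0; ow < Wo; ++ow) {
        int iw = ow / f;
        for (int oh = 0; oh < Ho; ++oh)
          yp[oh + (size_t)Ho * ow] = xp[(oh / f) + (size_t)H * iw];
      }
    }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample_nn_bwd(NumericVector dy, int f) {
  IntegerVector yd = arr_dim(dy);
  int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  int H = Ho / f, W = Wo / f;
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* dyp = dy.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      double* dxp = dx.begin() + (size_t)H * W * (c + (size_t)C * n);
      for (int ow = 0; ow < Wo; ++ow) {
        int iw = ow / f;
        for (int oh = 0; oh < Ho; ++oh)
          dxp[(oh / f) + (size_t)H * iw] += dyp[oh + (size_t)Ho * ow];
      }
    }
  return dx;
}

// Batch norm over (H, W, N) per channel, training mode.
// [[Rcpp::export]]
List cpp_bn_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
                double eps) {
  IntegerVector xd = arr_dim(x);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  size_t m = (size_t)H * W * N;
  NumericVector mean(C), var(C);
  for (int c = 0; c < C; ++c) {
    double s = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* xp = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      for (size_t i = 0; i < (size_t)H * W; ++i) s += xp[i];
    }
    mean[c] = s / m;
    double v = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* xp = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      for (size_t i = 0; i < (size_t)H * W; ++i) {
        double d = xp[i] - mean[c];
        v += d * d;
      }
    }
    var[c] = v / m;
  }
  NumericVector xhat(x.size()), y(x.size());
  xhat.attr("dim") = xd;
  y.attr("dim") = xd;
  for (int c = 0; c < C; ++c) {
    double inv = 1.0 / std::sqrt(var[c] + eps);
    for (int n = 0; n < N; ++n) {
      size_t off = (size_t)H * W * (c + (size_t)C * n);
      const double* xp = x.begin() + off;
      double* hp = xhat.begin() + off;
      double* yp = y.begin() + off;
      for (size_t i = 0; i < (size_t)H * W; ++i) {
        hp[i] = (xp[i] - mean[c]) * inv;
        yp[i] = gamma[c] * hp[i] + beta[c];
      }
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["mean"] = mean,
                      _["var"] = var);
}

// [[Rcpp::export]]
List cpp_bn_bwd(NumericVector dy, NumericVector xhat, NumericVector gamma,
                NumericVector var, double eps) {
  IntegerVector xd = arr_dim(dy);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  size_t m = (size_t)H * W * N;
  NumericVector dgamma(C), dbeta(C);
  NumericVector dx(dy.size());
  dx.attr("dim") = xd;
  for (int c = 0; c < C; ++c) {
    double sdy = 0.0, sdyh = 0.0;
    for (int n = 0; n < N; ++n) {
      size_t off = (size_t)H * W * (c + (size_t)C * n);
      const double* dp = dy.begin() + off;
      const double* hp = xhat.begin() + off;
      for (size_t i = 0; i < (size_t)H * W; ++i) {
        sdy += dp[i];
        sdyh += dp[i] * hp[i];
      }
    }
    dgamma[c] = sdyh;
    dbeta[c] = sdy;
    double inv = gamma[c] / std::sqrt(var[c] + eps);
    double mdy = sdy / m, mdyh = sdyh / m;
    for (int n = 0; n < N; ++n) {
      size_t off = (size_t)H * W * (c + (size_t)C * n);
      const double* dp = dy.begin() + off;
      const double* hp = xhat.begin() + off;
      double* xp = dx.begin() + off;
      for (size_t i = 0; i < (size_t)H * W; ++i)
        xp[i] = inv * (dp[i] - mdy - hp[i] * mdyh);
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// Eval-mode batch norm with running statistics.
// [[Rcpp::export]]
NumericVector cpp_bn_eval(NumericVector x, NumericVector gamma,
                          NumericVector beta, NumericVector rmean,
                          NumericVector rvar, double eps) {
  IntegerVector xd = arr_dim(x);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector y(x.size());
  y.attr("dim") = xd;
  for (int c = 0; c < C; ++c) {
    double inv = gamma[c] / std::sqrt(rvar[c] + eps);
    double b = beta[c] - rmean[c] * inv;
    for (int n = 0; n < N; ++n) {
      size_t off = (size_t)H * W * (c + (size_t)C * n);
      const double* xp = x.begin() + off;
      double* yp = y.begin() + off;
      for (size_t i = 0; i < (size_t)H * W; ++i) yp[i] = xp[i] * inv + b;
    }
  }
  return y;
}

// Sliding-window dilated attention, one dilation rate, multi-head over
// contiguous channel slices of width head_dim.  Out-of-bounds neighbours
// are excluded from the softmax (masked), so each output position is a
// convex combination of in-bounds value vectors.
// [[Rcpp::export]]
NumericVector cpp_swda_fwd(NumericVector q, NumericVector k, NumericVector v,
                           int rate, int kern, double scale, int head_dim) {
  IntegerVector xd = arr_dim(q);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int nh = C / head_dim;
  int half = (kern - 1) / 2;
  int K2 = kern * kern;
  NumericVector y(q.size());
  y.attr("dim") = xd;
  std::vector<double> logit(K2);
  std::vector<int> nbh(K2), nbw(K2);
  for (int n = 0; n < N; ++n)
    for (int h = 0; h < nh; ++h) {
      int c0 = h * head_dim;
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i) {
          int nn = 0;
          double mx = -1e300;
          for (int b = -half; b <= half; ++b) {
            int jj = j + b * rate;
            if (jj < 0 || jj >= W) continue;
            for (int a = -half; a <= half; ++a) {
              int ii = i + a * rate;
              if (ii < 0 || ii >= H) continue;
              double dot = 0.0;
              for (int c = 0; c < head_dim; ++c) {
                size_t oq = (size_t)i + H * ((size_t)j + W * ((size_t)(c0 + c) + (size_t)C * n));
                size_t ok = (size_t)ii + H * ((size_t)jj + W * ((size_t)(c0 + c) + (size_t)C * n));
                dot += q[oq] * k[ok];
              }
              logit[nn] = dot * scale;
              nbh[nn] = ii; nbw[nn] = jj;
              if (logit[nn] > mx) mx = logit[nn];
              ++nn;
            }
          }
          double Z = 0.0;
          for (int t = 0; t < nn; ++t) { logit[t] = std::exp(logit[t] - mx); Z += logit[t]; }
          for (int c = 0; c < head_dim; ++c) {
            double acc = 0.0;
            for (int t = 0; t < nn; ++t) {
              size_t ov = (size_t)nbh[t] + H * ((size_t)nbw[t] + W * ((size_t)(c0 + c) + (size_t)C * n));
              acc += (logit[t] / Z) * v[ov];
            }
            size_t oy = (size_t)i + H * ((size_t)j + W * ((size_t)(c0 + c) + (size_t)C * n));
            y[oy] = acc;
          }
        }
    }
  return y;
}

// [[Rcpp::export]]
List cpp_swda_bwd(NumericVector q, NumericVector k, NumericVector v,
                  NumericVector dy, int rate, int kern, double scale,
                  int head_dim) {
  IntegerVector xd = arr_dim(q);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int nh = C / head_dim;
  int half = (kern - 1) / 2;
  int K2 = kern * kern;
  NumericVector dq(q.size()), dk(q.size()), dv(q.size());
  dq.attr("dim") = xd; dk.attr("dim") = xd; dv.attr("dim") = xd;
  std::vector<double> p(K2), dyv(K2);
  std::vector<int> nbh(K2), nbw(K2);
  for (int n = 0; n < N; ++n)
    for (int h = 0; h < nh; ++h) {
      int c0 = h * head_dim;
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i) {
          int nn = 0;
          double mx = -1e300;
          for (int b = -half; b <= half; ++b) {
            int jj = j + b * rate;
            if (jj < 0 || jj >= W) continue;
            for (int a = -half; a <= half; ++a) {
              int ii = i + a * rate;
              if (ii < 0 || ii >= H) continue;
              double dot = 0.0;
              for (int c = 0; c < head_dim; ++c) {
                size_t oq = (size_t)i + H * ((size_t)j + W * ((size_t)(c0 + c) + (size_t)C * n));
                size_t ok = (size_t)ii + H * ((size_t)jj + W * ((size_t)(c0 + c) + (size_t)C * n));
                dot += q[oq] * k[ok];
              }
              p[nn] = dot * scale;
              nbh[nn] = ii; nbw[nn] = jj;
              if (p[nn] > mx) mx = p[nn];
              ++nn;
            }
          }
          double Z = 0.0;
          for (int t = 0; t < nn; ++t) { p[t] = std::exp(p[t] - mx); Z += p[t]; }
          for (int t = 0; t < nn; ++t) p[t] /= Z;
          // dyv[t] = <dy_ij, v_t>;  dv_t += p_t * dy_ij
          double sum_pd = 0.0;
          for (int t = 0; t < nn; ++t) {
            double d = 0.0;
            for (int c = 0; c < head_dim; ++c) {
              size_t oy = (size_t)i + H * ((size_t)j + W * ((size_t)(c0 + c) + (size_t)C * n));
              size_t ov = (size_t)nbh[t] + H * ((size_t)nbw[t] + W * ((size_t)(c0 + c) + (size_t)C * n));
              d += dy[oy] * v[ov];
              dv[ov] += p[t] * dy[oy];
            }
            dyv[t] = d;
            sum_pd += p[t] * d;
          }
          for (int t = 0; t < nn; ++t) {
            double dl = p[t] * (dyv[t] - sum_pd) * scale;
            for (int c = 0; c < head_dim; ++c) {
              size_t oq = (size_t)i + H * ((size_t)j + W * ((size_t)(c0 + c) + (size_t)C * n));
              size_t ok = (size_t)nbh[t] + H * ((size_t)nbw[t] + W * ((size_t)(c0 + c) + (size_t)C * n));
              dq[oq] += dl * k[ok];
              dk[ok] += dl * q[oq];
            }
          }
        }
    }
  return List::create(_["dq"] = dq, _["dk"] = dk, _["dv"] = dv);
}
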