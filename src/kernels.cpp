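// Low-level numeric kernels for the network and the preprocessing pipeline.
// Tensor layout throughout: column-major R arrays dim (H, W, C, N);
// convolution weights dim (kh, kw, Cin/groups, Cout). Convolutions use a
// whole-batch im2col so each group costs a single GEMM.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int H, int k, int stride, int dil, int pad) {
  return (H + 2 * pad - dil * (k - 1) - 1) / stride + 1;
}

// Unpack group-g channels of every sample into (kh*kw*Cg) x (Ho*Wo*N).
static void im2col_batch(const double* x, int H, int W, int Cin, int N,
                         int kh, int kw, int stride, int dil, int pad,
                         int g, int Cg, int Ho, int Wo, arma::mat& col) {
  const int R = col.n_rows;
  const size_t plane = (size_t)H * W;
  const size_t sample = plane * Cin;
  const size_t ocols = (size_t)Ho * Wo;
  for (int n = 0; n < N; ++n) {
    const double* xn = x + sample * n;
    double* coln = col.memptr() + (size_t)R * ocols * n;
    for (int cg = 0; cg < Cg; ++cg) {
      const double* xc = xn + plane * (g * Cg + cg);
      for (int kj = 0; kj < kw; ++kj) {
        for (int ki = 0; ki < kh; ++ki) {
          const int r = ki + kh * (kj + kw * cg);
          double* dst = coln + r;
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo * stride - pad + dil * kj;
            const bool wok = (wi >= 0 && wi < W);
            const double* xw = xc + (size_t)H * wi;
            for (int ho = 0; ho < Ho; ++ho) {
              const int hi = ho * stride - pad + dil * ki;
              dst[(size_t)R * (ho + (size_t)Ho * wo)] =
                  (wok && hi >= 0 && hi < H) ? xw[hi] : 0.0;
            }
          }
        }
      }
    }
  }
}

static void col2im_batch(double* dx, int H, int W, int Cin, int N,
                         int kh, int kw, int stride, int dil, int pad,
                         int g, int Cg, int Ho, int Wo,
                         const arma::mat& dcol) {
  const int R = dcol.n_rows;
  const size_t plane = (size_t)H * W;
  const size_t sample = plane * Cin;
  const size_t ocols = (size_t)Ho * Wo;
  for (int n = 0; n < N; ++n) {
    double* dxn = dx + sample * n;
    const double* dcn = dcol.memptr() + (size_t)R * ocols * n;
    for (int cg = 0; cg < Cg; ++cg) {
      double* xc = dxn + plane * (g * Cg + cg);
      for (int kj = 0; kj < kw; ++kj) {
        for (int ki = 0; ki < kh; ++ki) {
          const int r = ki + kh * (kj + kw * cg);
          const double* src = dcn + r;
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo * stride - pad + dil * kj;
            if (wi < 0 || wi >= W) continue;
            double* xw = xc + (size_t)H * wi;
            for (int ho = 0; ho < Ho; ++ho) {
              const int hi = ho * stride - pad + dil * ki;
              if (hi >= 0 && hi < H)
                xw[hi] += src[(size_t)R * (ho + (size_t)Ho * wo)];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fw_cpp(NumericVector x, IntegerVector xdim,
                            NumericVector w, IntegerVector wdim,
                            int stride, int dil, int pad, int groups) {
  const int H = xdim[0], W = xdim[1], Cin = xdim[2], N = xdim[3];
  const int kh = wdim[0], kw = wdim[1], Cg = wdim[2], Cout = wdim[3];
  if (Cg * groups != Cin) stop("conv2d: channel/group mismatch");
  const int Coutg = Cout / groups;
  const int Ho = out_size(H, kh, stride, dil, pad);
  const int Wo = out_size(W, kw, stride, dil, pad);
  if (Ho < 1 || Wo < 1) stop("conv2d: input smaller than receptive field");
  const int R = kh * kw * Cg;
  const size_t ocols = (size_t)Ho * Wo;
  NumericVector out(ocols * Cout * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  // 1x1 stride-1 convolution: pure channel mixing, per-sample GEMM on views
  if (kh == 1 && kw == 1 && stride == 1 && pad == 0 && groups == 1) {
    arma::mat Wm(w.begin(), Cin, Cout, false, true);
    const size_t hw = (size_t)H * W;
    for (int n = 0; n < N; ++n) {
      arma::mat Xn(const_cast<double*>(x.begin()) + hw * Cin * n, hw, Cin,
                   false, true);
      arma::mat On(out.begin() + ocols * (size_t)Cout * n, ocols, Cout,
                   false, true);
      On = Xn * Wm;
    }
    return out;
  }
  arma::mat Wm(w.begin(), R, Cout, false, true);
  arma::mat col(R, ocols * N);
  for (int g = 0; g < groups; ++g) {
    im2col_batch(x.begin(), H, W, Cin, N, kh, kw, stride, dil, pad, g, Cg,
                 Ho, Wo, col);
    arma::mat outm = col.t() * Wm.cols(g * Coutg, (g + 1) * Coutg - 1);
    // outm rows: (ho,wo,n); columns: local out channel
    for (int cl = 0; cl < Coutg; ++cl) {
      const double* src = outm.colptr(cl);
      for (int n = 0; n < N; ++n)
        std::memcpy(out.begin() + ocols * (g * Coutg + cl) +
                        ocols * (size_t)Cout * n,
                    src + ocols * n, sizeof(double) * ocols);
    }
  }
  return out;
}

// [[Rcpp::export]]
List conv2d_bw_cpp(NumericVector x, IntegerVector xdim,
                   NumericVector w, IntegerVector wdim,
                   NumericVector dout, int stride, int dil, int pad,
                   int groups, bool need_dx) {
  const int H = xdim[0], W = xdim[1], Cin = xdim[2], N = xdim[3];
  const int kh = wdim[0], kw = wdim[1], Cg = wdim[2], Cout = wdim[3];
  const int Coutg = Cout / groups;
  const int Ho = out_size(H, kh, stride, dil, pad);
  const int Wo = out_size(W, kw, stride, dil, pad);
  const int R = kh * kw * Cg;
  const size_t ocols = (size_t)Ho * Wo;
  NumericVector dx(need_dx ? (size_t)H * W * Cin * N : (size_t)0);
  if (need_dx) dx.attr("dim") = xdim;
  NumericVector dw((size_t)R * Cout);
  dw.attr("dim") = wdim;
  if (kh == 1 && kw == 1 && stride == 1 && pad == 0 && groups == 1) {
    arma::mat Wm(w.begin(), Cin, Cout, false, true);
    arma::mat dWm(dw.begin(), Cin, Cout, false, true);
    const size_t hw = (size_t)H * W;
    for (int n = 0; n < N; ++n) {
      arma::mat Xn(const_cast<double*>(x.begin()) + hw * Cin * n, hw, Cin,
                   false, true);
      arma::mat dOn(const_cast<double*>(dout.begin()) +
                        ocols * (size_t)Cout * n,
                    ocols, Cout, false, true);
      dWm += Xn.t() * dOn;
      if (need_dx) {
        arma::mat dXn(dx.begin() + hw * Cin * n, hw, Cin, false, true);
        dXn = dOn * Wm.t();
      }
    }
    return List::create(_["dx"] = dx, _["dw"] = dw);
  }
  arma::mat Wm(w.begin(), R, Cout, false, true);
  arma::mat dWm(dw.begin(), R, Cout, false, true);
  arma::mat col(R, ocols * N);
  arma::mat dOm(ocols * N, Coutg);
  for (int g = 0; g < groups; ++g) {
    im2col_batch(x.begin(), H, W, Cin, N, kh, kw, stride, dil, pad, g, Cg,
                 Ho, Wo, col);
    for (int cl = 0; cl < Coutg; ++cl) {
      double* dst = dOm.colptr(cl);
      for (int n = 0; n < N; ++n)
        std::memcpy(dst + ocols * n,
                    dout.begin() + ocols * (g * Coutg + cl) +
                        ocols * (size_t)Cout * n,
                    sizeof(double) * ocols);
    }
    dWm.cols(g * Coutg, (g + 1) * Coutg - 1) = col * dOm;
    if (need_dx) {
      arma::mat dcol = Wm.cols(g * Coutg, (g + 1) * Coutg - 1) * dOm.t();
      col2im_batch(dx.begin(), H, W, Cin, N, kh, kw, stride, dil, pad, g,
                   Cg, Ho, Wo, dcol);
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// [[Rcpp::export]]
List maxpool_fw_cpp(NumericVector x, IntegerVector xdim, int k, int stride,
                    int pad) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = out_size(H, k, stride, 1, pad);
  const int Wo = out_size(W, k, stride, 1, pad);
  NumericVector out((size_t)Ho * Wo * C * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector arg((size_t)Ho * Wo * C * N);
  const size_t planes = (size_t)C * N;
  for (size_t p = 0; p < planes; ++p) {
    const double* plane = x.begin() + (size_t)H * W * p;
    const size_t off = (size_t)Ho * Wo * p;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        double best = R_NegInf;
        int besti = -1;
        for (int kj = 0; kj < k; ++kj) {
          const int wi = wo * stride - pad + kj;
          if (wi < 0 || wi >= W) continue;
          for (int ki = 0; ki < k; ++ki) {
            const int hi = ho * stride - pad + ki;
            if (hi < 0 || hi >= H) continue;
            const double v = plane[hi + (size_t)H * wi];
            if (v > best) { best = v; besti = hi + H * wi; }
          }
        }
        out[off + ho + (size_t)Ho * wo] = (besti < 0) ? 0.0 : best;
        arg[off + ho + (size_t)Ho * wo] = besti;
      }
    }
  }
  return List::create(_["out"] = out, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool_bw_cpp(NumericVector dout, IntegerVector arg,
                             IntegerVector xdim, IntegerVector odim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = odim[0], Wo = odim[1];
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = xdim;
  const size_t planes = (size_t)C * N;
  for (size_t p = 0; p < planes; ++p) {
    double* dplane = dx.begin() + (size_t)H * W * p;
    const size_t off = (size_t)Ho * Wo * p;
    for (size_t i = 0; i < (size_t)Ho * Wo; ++i) {
      const int a = arg[off + i];
      if (a >= 0) dplane[a] += dout[off + i];
    }
  }
  return dx;
}

// Per-channel mean and population variance over (H, W, N).
// [[Rcpp::export]]
List bn_stats_cpp(NumericVector x, IntegerVector xdim) {
  const int C = xdim[2], N = xdim[3];
  const size_t hw = (size_t)xdim[0] * xdim[1];
  NumericVector mu(C), var(C);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + hw * C * n;
    for (int c = 0; c < C; ++c) {
      const double* xc = xn + hw * c;
      double s = 0, s2 = 0;
      for (size_t i = 0; i < hw; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
      mu[c] += s;
      var[c] += s2;
    }
  }
  const double m = (double)hw * N;
  for (int c = 0; c < C; ++c) {
    mu[c] /= m;
    var[c] = std::max(var[c] / m - mu[c] * mu[c], 0.0);
  }
  return List::create(_["mean"] = mu, _["var"] = var);
}

// [[Rcpp::export]]
NumericVector bn_norm_cpp(NumericVector x, IntegerVector xdim,
                          NumericVector mu, NumericVector inv_std,
                          NumericVector gamma, NumericVector beta) {
  const int C = xdim[2], N = xdim[3];
  const size_t hw = (size_t)xdim[0] * xdim[1];
  NumericVector out(x.size());
  out.attr("dim") = xdim;
  for (int n = 0; n < N; ++n) {
    const size_t off_n = hw * C * n;
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + off_n + hw * c;
      double* oc = out.begin() + off_n + hw * c;
      const double a = gamma[c] * inv_std[c];
      const double b = beta[c] - a * mu[c];
      for (size_t i = 0; i < hw; ++i) oc[i] = a * xc[i] + b;
    }
  }
  return out;
}

// [[Rcpp::export]]
List bn_bw_cpp(NumericVector x, IntegerVector xdim, NumericVector mu,
               NumericVector inv_std, NumericVector gamma,
               NumericVector dout, bool batch_stats) {
  const int C = xdim[2], N = xdim[3];
  const size_t hw = (size_t)xdim[0] * xdim[1];
  const double m = (double)hw * N;
  NumericVector dgamma(C), dbeta(C), s1(C), s2(C);
  for (int n = 0; n < N; ++n) {
    const size_t off_n = hw * C * n;
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + off_n + hw * c;
      const double* dc = dout.begin() + off_n + hw * c;
      double a = 0, b = 0;
      for (size_t i = 0; i < hw; ++i) {
        const double xhat = (xc[i] - mu[c]) * inv_std[c];
        a += dc[i] * xhat;
        b += dc[i];
      }
      dgamma[c] += a;
      dbeta[c] += b;
    }
  }
  NumericVector dx(x.size());
  dx.attr("dim") = xdim;
  for (int c = 0; c < C; ++c) {
    s1[c] = gamma[c] * dbeta[c] / m;          // mean of dxhat
    s2[c] = gamma[c] * dgamma[c] / m;         // mean of dxhat * xhat
  }
  for (int n = 0; n < N; ++n) {
    const size_t off_n = hw * C * n;
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + off_n + hw * c;
      const double* dc = dout.begin() + off_n + hw * c;
      double* dxc = dx.begin() + off_n + hw * c;
      const double g = gamma[c];
      if (batch_stats) {
        for (size_t i = 0; i < hw; ++i) {
          const double xhat = (xc[i] - mu[c]) * inv_std[c];
          dxc[i] = (dc[i] * g - s1[c] - xhat * s2[c]) * inv_std[c];
        }
      } else {
        for (size_t i = 0; i < hw; ++i) dxc[i] = dc[i] * g * inv_std[c];
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// [[Rcpp::export]]
NumericVector relu_fw_cpp(NumericVector x) {
  NumericVector out(x.size());
  out.attr("dim") = x.attr("dim");
  const double* xi = x.begin();
  double* oi = out.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) oi[i] = xi[i] > 0 ? xi[i] : 0;
  return out;
}

// [[Rcpp::export]]
NumericVector relu_bw_cpp(NumericVector dout, NumericVector out) {
  NumericVector dx(dout.size());
  dx.attr("dim") = dout.attr("dim");
  const double* d = dout.begin();
  const double* o = out.begin();
  double* r = dx.begin();
  for (R_xlen_t i = 0; i < dout.size(); ++i) r[i] = o[i] > 0 ? d[i] : 0;
  return dx;
}

// Non-overlapping median pooling along the rows (time axis) of a T x S map.
// Even windows use the mean of the two central order statistics.
// [[Rcpp::export]]
NumericMatrix median_pool_cpp(NumericMatrix m, int win) {
  const int T = m.nrow(), S = m.ncol();
  if (win < 1 || T % win != 0)
    stop("median_pool: T_raw (%d) not divisible by window (%d)", T, win);
  const int To = T / win;
  NumericMatrix out(To, S);
  std::vector<double> buf(win);
  for (int s = 0; s < S; ++s) {
    for (int t = 0; t < To; ++t) {
      for (int i = 0; i < win; ++i) buf[i] = m(t * win + i, s);
      std::sort(buf.begin(), buf.end());
      out(t, s) = (win % 2 == 1)
                      ? buf[win / 2]
                      : 0.5 * (buf[win / 2 - 1] + buf[win / 2]);
    }
  }
  return out;
}

// Concatenate equal-shaped (H,W,C,N) tensors along the channel axis.
// [[Rcpp::export]]
NumericVector cat_channels_cpp(List xs) {
  const int nb = xs.size();
  NumericVector x0 = xs[0];
  IntegerVector d = x0.attr("dim");
  const size_t hw = (size_t)d[0] * d[1];
  const int C = d[2], N = d[3];
  NumericVector out(hw * C * nb * N);
  out.attr("dim") = IntegerVector::create(d[0], d[1], C * nb, N);
  const size_t block = hw * C;
  for (int b = 0; b < nb; ++b) {
    NumericVector xb = xs[b];
    for (int n = 0; n < N; ++n)
      std::memcpy(out.begin() + block * (b + (size_t)nb * n),
                  xb.begin() + block * n, sizeof(double) * block);
  }
  return out;
}

// Extract channels [from, to] (1-based, inclusive) of an (H,W,C,N) tensor.
// [[Rcpp::export]]
NumericVector slice_channels_cpp(NumericVector x, int from, int to) {
  IntegerVector d = x.attr("dim");
  const size_t hw = (size_t)d[0] * d[1];
  const int C = d[2], N = d[3];
  const int Cs = to - from + 1;
  NumericVector out(hw * Cs * N);
  out.attr("dim") = IntegerVector::create(d[0], d[1], Cs, N);
  for (int n = 0; n < N; ++n)
    std::memcpy(out.begin() + hw * Cs * (size_t)n,
                x.begin() + hw * ((size_t)(from - 1) + (size_t)C * n),
                sizeof(double) * hw * Cs);
  return out;
}

// Forward for groups == 1 convolutions that also returns the im2col matrix
// so the backward pass can reuse it.
// [[Rcpp::export]]
List conv2d_fwcol_cpp(NumericVector x, IntegerVector xdim,
                      NumericVector w, IntegerVector wdim,
                      int stride, int dil, int pad) {
  const int H = xdim[0], W = xdim[1], Cin = xdim[2], N = xdim[3];
  const int kh = wdim[0], kw = wdim[1], Cout = wdim[3];
  const int Ho = out_size(H, kh, stride, dil, pad);
  const int Wo = out_size(W, kw, stride, dil, pad);
  if (Ho < 1 || Wo < 1) stop("conv2d: input smaller than receptive field");
  const int R = kh * kw * Cin;
  const size_t ocols = (size_t)Ho * Wo;
  NumericVector out(ocols * Cout * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  NumericVector colv((size_t)R * ocols * N);
  arma::mat col(colv.begin(), R, ocols * N, false, true);
  im2col_batch(x.begin(), H, W, Cin, N, kh, kw, stride, dil, pad, 0, Cin,
               Ho, Wo, col);
  arma::mat Wm(w.begin(), R, Cout, false, true);
  arma::mat outm = col.t() * Wm;
  for (int cl = 0; cl < Cout; ++cl) {
    const double* src = outm.colptr(cl);
    for (int n = 0; n < N; ++n)
      std::memcpy(out.begin() + ocols * cl + ocols * (size_t)Cout * n,
                  src + ocols * n, sizeof(double) * ocols);
  }
  return List::create(_["out"] = out, _["col"] = colv);
}

// Backward reusing a cached im2col matrix (groups == 1).
// [[Rcpp::export]]
List conv2d_bwcol_cpp(NumericVector colv, IntegerVector xdim,
                      NumericVector w, IntegerVector wdim,
                      NumericVector dout, int stride, int dil, int pad,
                      bool need_dx) {
  const int H = xdim[0], W = xdim[1], Cin = xdim[2], N = xdim[3];
  const int kh = wdim[0], kw = wdim[1], Cout = wdim[3];
  const int Ho = out_size(H, kh, stride, dil, pad);
  const int Wo = out_size(W, kw, stride, dil, pad);
  const int R = kh * kw * Cin;
  const size_t ocols = (size_t)Ho * Wo;
  arma::mat col(const_cast<double*>(colv.begin()), R, ocols * N, false,
                true);
  NumericVector dx(need_dx ? (size_t)H * W * Cin * N : (size_t)0);
  if (need_dx) dx.attr("dim") = xdim;
  NumericVector dw((size_t)R * Cout);
  dw.attr("dim") = wdim;
  arma::mat Wm(w.begin(), R, Cout, false, true);
  arma::mat dWm(dw.begin(), R, Cout, false, true);
  arma::mat dOm(ocols * N, Cout);
  for (int cl = 0; cl < Cout; ++cl) {
    double* dst = dOm.colptr(cl);
    for (int n = 0; n < N; ++n)
      std::memcpy(dst + ocols * n,
                  dout.begin() + ocols * cl + ocols * (size_t)Cout * n,
                  sizeof(double) * ocols);
  }
  dWm = col * dOm;
  if (need_dx) {
    arma::mat dcol = Wm * dOm.t();
    col2im_batch(dx.begin(), H, W, Cin, N, kh, kw, stride, dil, pad, 0,
                 Cin, Ho, Wo, dcol);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// Direct depthwise convolution (groups == Cin == Cout), no im2col.
// [[Rcpp::export]]
NumericVector depthwise_fw_cpp(NumericVector x, IntegerVector xdim,
                               NumericVector w, IntegerVector wdim,
                               int stride, int pad) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int kh = wdim[0], kw = wdim[1];
  const int Ho = out_size(H, kh, stride, 1, pad);
  const int Wo = out_size(W, kw, stride, 1, pad);
  NumericVector out((size_t)Ho * Wo * C * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const size_t plane = (size_t)H * W, oplane = (size_t)Ho * Wo;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + plane * (c + (size_t)C * n);
      const double* wc = w.begin() + (size_t)kh * kw * c;
      double* oc = out.begin() + oplane * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double acc = 0;
          for (int kj = 0; kj < kw; ++kj) {
            const int wi = wo * stride - pad + kj;
            if (wi < 0 || wi >= W) continue;
            for (int ki = 0; ki < kh; ++ki) {
              const int hi = ho * stride - pad + ki;
              if (hi < 0 || hi >= H) continue;
              acc += xc[hi + (size_t)H * wi] * wc[ki + kh * kj];
            }
          }
          oc[ho + (size_t)Ho * wo] = acc;
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List depthwise_bw_cpp(NumericVector x, IntegerVector xdim,
                      NumericVector w, IntegerVector wdim,
                      NumericVector dout, int stride, int pad,
                      bool need_dx) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int kh = wdim[0], kw = wdim[1];
  const int Ho = out_size(H, kh, stride, 1, pad);
  const int Wo = out_size(W, kw, stride, 1, pad);
  NumericVector dx(need_dx ? x.size() : (R_xlen_t)0);
  if (need_dx) dx.attr("dim") = xdim;
  NumericVector dw(w.size());
  dw.attr("dim") = wdim;
  const size_t plane = (size_t)H * W, oplane = (size_t)Ho * Wo;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + plane * (c + (size_t)C * n);
      const double* wc = w.begin() + (size_t)kh * kw * c;
      const double* dc = dout.begin() + oplane * (c + (size_t)C * n);
      double* dwc = dw.begin() + (size_t)kh * kw * c;
      double* dxc = need_dx ? dx.begin() + plane * (c + (size_t)C * n)
                            : (double*)nullptr;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          const double g = dc[ho + (size_t)Ho * wo];
          if (g == 0) continue;
          for (int kj = 0; kj < kw; ++kj) {
            const int wi = wo * stride - pad + kj;
            if (wi < 0 || wi >= W) continue;
            for (int ki = 0; ki < kh; ++ki) {
              const int hi = ho * stride - pad + ki;
              if (hi < 0 || hi >= H) continue;
              dwc[ki + kh * kj] += xc[hi + (size_t)H * wi] * g;
              if (need_dx) dxc[hi + (size_t)H * wi] += wc[ki + kh * kj] * g;
            }
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}
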