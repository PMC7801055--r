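// Low-level numeric kernels for the segmentation network and ROI detection.
// Feature maps are stored as R arrays with dim = c(H, W, C, N): column-major,
// row index fastest.  Convolution uses im2col + BLAS matrix products.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int conv_out_dim(int n, int k, int stride, int dil, int pad) {
  return (n + 2 * pad - dil * (k - 1) - 1) / stride + 1;
}

// col has shape (kh*kw*C) x (Ho*Wo); x points at one sample [H,W,C]
static void im2col(const double *x, int H, int W, int C,
                   int kh, int kw, int stride, int dil, int pad,
                   int Ho, int Wo, arma::mat &col) {
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int row = ki + kh * (kj + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + kj * dil;
          const bool w_ok = (wi >= 0 && wi < W);
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * stride - pad + ki * dil;
            double v = 0.0;
            if (w_ok && hi >= 0 && hi < H) v = x[hi + (size_t)H * (wi + (size_t)W * c)];
            col(row, ho + (size_t)Ho * wo) = v;
          }
        }
      }
    }
  }
}

// scatter-add of col back into gx (one sample)
static void col2im(const arma::mat &col, double *gx, int H, int W, int C,
                   int kh, int kw, int stride, int dil, int pad,
                   int Ho, int Wo) {
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int row = ki + kh * (kj + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + kj * dil;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * stride - pad + ki * dil;
            if (hi < 0 || hi >= H) continue;
            gx[hi + (size_t)H * (wi + (size_t)W * c)] += col(row, ho + (size_t)Ho * wo);
          }
        }
      }
    }
  }
}

// weights w: array [kh, kw, Cin, Cout] -> matrix (Cout x kh*kw*Cin)
static arma::mat weight_matrix(const NumericVector &w, int kh, int kw, int Cin, int Cout) {
  arma::mat Wm(Cout, kh * kw * Cin);
  const double *wp = w.begin();
  for (int co = 0; co < Cout; ++co)
    for (int c = 0; c < Cin; ++c)
      for (int kj = 0; kj < kw; ++kj)
        for (int ki = 0; ki < kh; ++ki)
          Wm(co, ki + kh * (kj + kw * c)) =
            wp[ki + (size_t)kh * (kj + (size_t)kw * (c + (size_t)Cin * co))];
  return Wm;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_forward(NumericVector x, IntegerVector xdim,
                                 NumericVector w, IntegerVector wdim,
                                 NumericVector bias,
                                 int stride, int dilation, int pad) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int kh = wdim[0], kw = wdim[1], Cin = wdim[2], Cout = wdim[3];
  if (Cin != C) stop("channel mismatch in convolution");
  const int Ho = conv_out_dim(H, kh, stride, dilation, pad);
  const int Wo = conv_out_dim(W, kw, stride, dilation, pad);
  if (Ho < 1 || Wo < 1) stop("convolution output would be empty");

  arma::mat Wm = weight_matrix(w, kh, kw, Cin, Cout);
  NumericVector y((size_t)Ho * Wo * Cout * N);
  arma::mat col(kh * kw * C, (size_t)Ho * Wo);

  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, stride, dilation, pad,
           Ho, Wo, col);
    arma::mat out = Wm * col;  // Cout x (Ho*Wo)
    double *yp = y.begin() + (size_t)Ho * Wo * Cout * n;
    for (int co = 0; co < Cout; ++co) {
      const double b = bias[co];
      for (size_t p = 0; p < (size_t)Ho * Wo; ++p)
        yp[p + (size_t)Ho * Wo * co] = out(co, p) + b;
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, IntegerVector xdim,
                         NumericVector w, IntegerVector wdim,
                         NumericVector gy,
                         int stride, int dilation, int pad) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int kh = wdim[0], kw = wdim[1], Cin = wdim[2], Cout = wdim[3];
  const int Ho = conv_out_dim(H, kh, stride, dilation, pad);
  const int Wo = conv_out_dim(W, kw, stride, dilation, pad);

  arma::mat Wm = weight_matrix(w, kh, kw, Cin, Cout);
  arma::mat gWm(Cout, kh * kw * Cin, arma::fill::zeros);
  NumericVector gb(Cout);
  NumericVector gx(x.size());
  arma::mat col(kh * kw * C, (size_t)Ho * Wo);
  arma::mat G(Cout, (size_t)Ho * Wo);

  for (int n = 0; n < N; ++n) {
    const double *gyp = gy.begin() + (size_t)Ho * Wo * Cout * n;
    for (int co = 0; co < Cout; ++co)
      for (size_t p = 0; p < (size_t)Ho * Wo; ++p)
        G(co, p) = gyp[p + (size_t)Ho * Wo * co];

    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, stride, dilation, pad,
           Ho, Wo, col);
    gWm += G * col.t();
    for (int co = 0; co < Cout; ++co) gb[co] += arma::accu(G.row(co));

    arma::mat gcol = Wm.t() * G;
    col2im(gcol, gx.begin() + (size_t)H * W * C * n, H, W, C, kh, kw,
           stride, dilation, pad, Ho, Wo);
  }

  NumericVector gw(w.size());
  double *gwp = gw.begin();
  for (int co = 0; co < Cout; ++co)
    for (int c = 0; c < Cin; ++c)
      for (int kj = 0; kj < kw; ++kj)
        for (int ki = 0; ki < kh; ++ki)
          gwp[ki + (size_t)kh * (kj + (size_t)kw * (c + (size_t)Cin * co))] =
            gWm(co, ki + kh * (kj + kw * c));

  gx.attr("dim") = xdim;
  gw.attr("dim") = wdim;
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x bilinear upsampling, half-pixel centres (align_corners = FALSE).
// Precompute, for each output index, the two source indices and weights.
static void up2_coeffs(int n_out, int n_in, std::vector<int> &i0,
                       std::vector<int> &i1, std::vector<double> &a) {
  i0.resize(n_out); i1.resize(n_out); a.resize(n_out);
  for (int i = 0; i < n_out; ++i) {
    double src = (i + 0.5) / 2.0 - 0.5;
    int lo = (int)std::floor(src);
    double frac = src - lo;
    int l0 = std::min(std::max(lo, 0), n_in - 1);
    int l1 = std::min(std::max(lo + 1, 0), n_in - 1);
    i0[i] = l0; i1[i] = l1; a[i] = frac;
  }
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_forward(NumericVector x, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = 2 * H, Wo = 2 * W;
  std::vector<int> h0, h1, w0, w1; std::vector<double> ah, aw;
  up2_coeffs(Ho, H, h0, h1, ah);
  up2_coeffs(Wo, W, w0, w1, aw);

  NumericVector y((size_t)Ho * Wo * C * N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double *xp = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      double *yp = y.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo) {
        const int wl = w0[wo], wr = w1[wo]; const double fw = aw[wo];
        for (int ho = 0; ho < Ho; ++ho) {
          const int ht = h0[ho], hb = h1[ho]; const double fh = ah[ho];
          double v = (1 - fh) * (1 - fw) * xp[ht + (size_t)H * wl]
                   + fh       * (1 - fw) * xp[hb + (size_t)H * wl]
                   + (1 - fh) * fw       * xp[ht + (size_t)H * wr]
                   + fh       * fw       * xp[hb + (size_t)H * wr];
          yp[ho + (size_t)Ho * wo] = v;
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_backward(NumericVector gy, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = 2 * H, Wo = 2 * W;
  std::vector<int> h0, h1, w0, w1; std::vector<double> ah, aw;
  up2_coeffs(Ho, H, h0, h1, ah);
  up2_coeffs(Wo, W, w0, w1, aw);

  NumericVector gx((size_t)H * W * C * N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      double *gp = gx.begin() + (size_t)H * W * (c + (size_t)C * n);
      const double *gyp = gy.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo) {
        const int wl = w0[wo], wr = w1[wo]; const double fw = aw[wo];
        for (int ho = 0; ho < Ho; ++ho) {
          const int ht = h0[ho], hb = h1[ho]; const double fh = ah[ho];
          const double g = gyp[ho + (size_t)Ho * wo];
          gp[ht + (size_t)H * wl] += (1 - fh) * (1 - fw) * g;
          gp[hb + (size_t)H * wl] += fh       * (1 - fw) * g;
          gp[ht + (size_t)H * wr] += (1 - fh) * fw       * g;
          gp[hb + (size_t)H * wr] += fh       * fw       * g;
        }
      }
    }
  }
  gx.attr("dim") = xdim;
  return gx;
}

// 8-connected component labeling of a binary matrix (0 background).
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(IntegerMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<std::pair<int, int>> stack;
  int next = 0;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back({i, j});
      lab(i, j) = next;
      while (!stack.empty()) {
        auto [ci, cj] = stack.back();
        stack.pop_back();
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            const int ni = ci + di, nj = cj + dj;
            if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
            if (mask(ni, nj) != 0 && lab(ni, nj) == 0) {
              lab(ni, nj) = next;
              stack.push_back({ni, nj});
            }
          }
        }
      }
    }
  }
  return lab;
}
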