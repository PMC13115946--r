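// Native tensor kernels for the pestnet network stack.
//
// Feature maps are R arrays with dim c(H, W, C) (column-major, so H is the
// fastest index), mapped onto arma::cube(H, W, C). Convolution weights are
// R arrays with dim c(KH, KW, IC, OC); their flat column-major layout is
// reinterpreted as a (KH*KW*IC) x OC matrix, which matches the im2col row
// ordering used below. All "convolutions" are cross-correlations (CNN
// convention; no kernel flip), so the fixed Sobel kernels respond with the
// usual sign.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline int conv_out_dim(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

static mat im2col(const cube& x, int kh, int kw, int stride, int pad,
                  int oh, int ow) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat col(kh * kw * C, (size_t)oh * ow, fill::zeros);
  for (int ox = 0; ox < ow; ++ox) {
    for (int oy = 0; oy < oh; ++oy) {
      const size_t opix = (size_t)oy + (size_t)ox * oh;
      double* dst = col.colptr(opix);
      for (int c = 0; c < C; ++c) {
        for (int kj = 0; kj < kw; ++kj) {
          const int ix = ox * stride - pad + kj;
          for (int ki = 0; ki < kh; ++ki) {
            const int iy = oy * stride - pad + ki;
            const size_t r = (size_t)ki + (size_t)kj * kh + (size_t)c * kh * kw;
            if (iy >= 0 && iy < H && ix >= 0 && ix < W)
              dst[r] = x(iy, ix, c);
          }
        }
      }
    }
  }
  return col;
}

static void col2im_add(cube& x, const mat& col, int kh, int kw, int stride,
                       int pad, int oh, int ow) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  for (int ox = 0; ox < ow; ++ox) {
    for (int oy = 0; oy < oh; ++oy) {
      const size_t opix = (size_t)oy + (size_t)ox * oh;
      const double* src = col.colptr(opix);
      for (int c = 0; c < C; ++c) {
        for (int kj = 0; kj < kw; ++kj) {
          const int ix = ox * stride - pad + kj;
          for (int ki = 0; ki < kh; ++ki) {
            const int iy = oy * stride - pad + ki;
            const size_t r = (size_t)ki + (size_t)kj * kh + (size_t)c * kh * kw;
            if (iy >= 0 && iy < H && ix >= 0 && ix < W)
              x(iy, ix, c) += src[r];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::cube conv2d_fwd_cpp(const arma::cube& x, const arma::vec& w,
                          const arma::vec& b, int kh, int kw, int oc,
                          int stride, int pad) {
  const int C = x.n_slices;
  const int oh = conv_out_dim(x.n_rows, kh, stride, pad);
  const int ow = conv_out_dim(x.n_cols, kw, stride, pad);
  if ((int)w.n_elem != kh * kw * C * oc)
    Rcpp::stop("conv2d: weight size does not match input channels (got %d channels)", C);
  const mat wm(const_cast<double*>(w.memptr()), kh * kw * C, oc, false, true);
  mat col = im2col(x, kh, kw, stride, pad, oh, ow);
  mat out = wm.t() * col;  // oc x npix
  out.each_col() += b;
  cube y(oh, ow, oc);
  for (int c = 0; c < oc; ++c)
    for (int ox = 0; ox < ow; ++ox)
      for (int oy = 0; oy < oh; ++oy)
        y(oy, ox, c) = out(c, (size_t)oy + (size_t)ox * oh);
  return y;
}

// [[Rcpp::export]]
Rcpp::List conv2d_bwd_cpp(const arma::cube& x, const arma::vec& w,
                          const arma::cube& dy, int kh, int kw, int stride,
                          int pad) {
  const int C = x.n_slices;
  const int oh = dy.n_rows, ow = dy.n_cols, oc = dy.n_slices;
  const mat wm(const_cast<double*>(w.memptr()), kh * kw * C, oc, false, true);
  mat dym(oc, (size_t)oh * ow);
  for (int c = 0; c < oc; ++c)
    for (int ox = 0; ox < ow; ++ox)
      for (int oy = 0; oy < oh; ++oy)
        dym(c, (size_t)oy + (size_t)ox * oh) = dy(oy, ox, c);
  mat col = im2col(x, kh, kw, stride, pad, oh, ow);
  mat dwm = col * dym.t();                 // (kh*kw*C) x oc
  vec db = sum(dym, 1);
  mat dcol = wm * dym;                     // (kh*kw*C) x npix
  cube dx(x.n_rows, x.n_cols, C, fill::zeros);
  col2im_add(dx, dcol, kh, kw, stride, pad, oh, ow);
  Rcpp::NumericVector dw(dwm.begin(), dwm.end());
  dw.attr("dim") = Rcpp::IntegerVector::create(kh, kw, C, oc);
  return Rcpp::List::create(Rcpp::Named("dx") = dx, Rcpp::Named("dw") = dw,
                            Rcpp::Named("db") = Rcpp::NumericVector(db.begin(), db.end()));
}

// Depthwise 3x3 cross-correlation with zero same-padding, stride 1. Each
// channel is filtered independently with the same fixed kernel (used for the
// Sobel edge priors, which carry no learnable weights).
// [[Rcpp::export]]
arma::cube depthwise3x3_cpp(const arma::cube& x, const arma::mat& k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube y(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        double acc = 0.0;
        for (int kj = -1; kj <= 1; ++kj) {
          const int jj = j + kj;
          if (jj < 0 || jj >= W) continue;
          for (int ki = -1; ki <= 1; ++ki) {
            const int ii = i + ki;
            if (ii < 0 || ii >= H) continue;
            acc += k(ki + 1, kj + 1) * x(ii, jj, c);
          }
        }
        y(i, j, c) = acc;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
Rcpp::List maxpool2_fwd_cpp(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int oh = H / 2, ow = W / 2;
  cube y(oh, ow, C);
  Rcpp::IntegerVector idx((size_t)oh * ow * C);  // 1-based flat index into x
  size_t t = 0;
  for (int c = 0; c < C; ++c) {
    for (int ox = 0; ox < ow; ++ox) {
      for (int oy = 0; oy < oh; ++oy) {
        double best = -datum::inf;
        size_t bi = 0;
        for (int kj = 0; kj < 2; ++kj) {
          for (int ki = 0; ki < 2; ++ki) {
            const int iy = 2 * oy + ki, ix = 2 * ox + kj;
            const double v = x(iy, ix, c);
            if (v > best) {
              best = v;
              bi = (size_t)iy + (size_t)ix * H + (size_t)c * H * W;
            }
          }
        }
        y(oy, ox, c) = best;
        idx[t++] = (int)(bi + 1);
      }
    }
  }
  // column-major fill order above matches dim c(oh, ow, C)? t runs over
  // (oy, ox) inner, c outer -> index = oy + ox*oh + c*oh*ow: yes.
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube maxpool2_bwd_cpp(const arma::cube& dy, const Rcpp::IntegerVector& idx,
                            int H, int W, int C) {
  cube dx(H, W, C, fill::zeros);
  const double* src = dy.memptr();
  double* dst = dx.memptr();
  for (R_xlen_t t = 0; t < idx.size(); ++t) dst[idx[t] - 1] += src[t];
  return dx;
}

// Bilinear resize (half-pixel centers), per channel.
// [[Rcpp::export]]
arma::cube resize_bilinear_cpp(const arma::cube& x, int oh, int ow) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube y(oh, ow, C);
  const double sy = (double)H / oh, sx = (double)W / ow;
  for (int j = 0; j < ow; ++j) {
    double fx = (j + 0.5) * sx - 0.5;
    if (fx < 0) fx = 0;
    if (fx > W - 1) fx = W - 1;
    const int x0 = (int)std::floor(fx), x1 = std::min(x0 + 1, W - 1);
    const double wx = fx - x0;
    for (int i = 0; i < oh; ++i) {
      double fy = (i + 0.5) * sy - 0.5;
      if (fy < 0) fy = 0;
      if (fy > H - 1) fy = H - 1;
      const int y0 = (int)std::floor(fy), y1 = std::min(y0 + 1, H - 1);
      const double wy = fy - y0;
      for (int c = 0; c < C; ++c) {
        const double v =
            (1 - wy) * ((1 - wx) * x(y0, x0, c) + wx * x(y0, x1, c)) +
            wy * ((1 - wx) * x(y1, x0, c) + wx * x(y1, x1, c));
        y(i, j, c) = v;
      }
    }
  }
  return y;
}
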