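// Minimal CPU tensor primitives for the package's convolutional networks.
// Tensors are R arrays in (H, W, C, N) layout (column-major, H fastest).
// Convolutions use 'same' padding in the TensorFlow convention:
//   out = ceil(in / stride); pad_total = max((out-1)*stride + k - in, 0)
// with the smaller half of the padding before the data.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int in, int k, int stride) {
  return (in + stride - 1) / stride;
}
static inline int pad_before(int in, int k, int stride) {
  int out = out_size(in, k, stride);
  int tot = (out - 1) * stride + k - in;
  if (tot < 0) tot = 0;
  return tot / 2;
}

// im2col for one sample: x (H, W, C) slice of the batch, columns are
// receptive fields, rows indexed f = i + k*(j + k*c) (i row-offset, j col-offset).
static void im2col(const double* x, int H, int W, int C,
                   int k, int stride, arma::mat& col) {
  const int Ho = out_size(H, k, stride);
  const int Wo = out_size(W, k, stride);
  const int ph = pad_before(H, k, stride);
  const int pw = pad_before(W, k, stride);
  col.zeros(k * k * C, Ho * Wo);
  for (int ow = 0; ow < Wo; ++ow) {
    for (int oh = 0; oh < Ho; ++oh) {
      const int cidx = oh + Ho * ow;
      const int h0 = oh * stride - ph;
      const int w0 = ow * stride - pw;
      for (int c = 0; c < C; ++c) {
        for (int j = 0; j < k; ++j) {
          const int w = w0 + j;
          if (w < 0 || w >= W) continue;
          for (int i = 0; i < k; ++i) {
            const int h = h0 + i;
            if (h < 0 || h >= H) continue;
            col(i + k * (j + k * c), cidx) = x[h + H * (w + W * c)];
          }
        }
      }
    }
  }
}

// scatter-add transpose of im2col
static void col2im(const arma::mat& col, int H, int W, int C,
                   int k, int stride, double* dx) {
  const int Ho = out_size(H, k, stride);
  const int Wo = out_size(W, k, stride);
  const int ph = pad_before(H, k, stride);
  const int pw = pad_before(W, k, stride);
  for (int ow = 0; ow < Wo; ++ow) {
    for (int oh = 0; oh < Ho; ++oh) {
      const int cidx = oh + Ho * ow;
      const int h0 = oh * stride - ph;
      const int w0 = ow * stride - pw;
      for (int c = 0; c < C; ++c) {
        for (int j = 0; j < k; ++j) {
          const int w = w0 + j;
          if (w < 0 || w >= W) continue;
          for (int i = 0; i < k; ++i) {
            const int h = h0 + i;
            if (h < 0 || h >= H) continue;
            dx[h + H * (w + W * c)] += col(i + k * (j + k * c), cidx);
          }
        }
      }
    }
  }
}

static IntegerVector dims4(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d (H, W, C, N) array");
  return d;
}

// [[Rcpp::export(name = ".nn_conv2d_fwd")]]
NumericVector nn_conv2d_fwd(NumericVector x, NumericVector w,
                            NumericVector b, int stride) {
  IntegerVector xd = dims4(x);
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 4) stop("weights must be (k, k, Cin, Cout)");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cin = wd[2], Cout = wd[3];
  if (wd[1] != k || Cin != C) stop("weight shape mismatch");
  const int Ho = out_size(H, k, stride), Wo = out_size(W, k, stride);

  // weight matrix (Cout x k*k*Cin), row co holds filter co flattened like im2col rows
  arma::mat Wm(Cout, k * k * Cin);
  for (int co = 0; co < Cout; ++co)
    for (int f = 0; f < k * k * Cin; ++f)
      Wm(co, f) = w[f + k * k * Cin * co];

  NumericVector y(Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat col;
  for (int n = 0; n < N; ++n) {
    im2col(&x[0] + (size_t)H * W * C * n, H, W, C, k, stride, col);
    arma::mat out = Wm * col;              // (Cout, Ho*Wo)
    double* yp = &y[0] + (size_t)Ho * Wo * Cout * n;
    for (int co = 0; co < Cout; ++co) {
      const double bc = b[co];
      for (int p = 0; p < Ho * Wo; ++p)
        yp[p + Ho * Wo * co] = out(co, p) + bc;
    }
  }
  return y;
}

// [[Rcpp::export(name = ".nn_conv2d_bwd")]]
List nn_conv2d_bwd(NumericVector x, NumericVector w,
                   NumericVector dy, int stride) {
  IntegerVector xd = dims4(x);
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  const int Ho = out_size(H, k, stride), Wo = out_size(W, k, stride);

  arma::mat Wm(Cout, k * k * C);
  for (int co = 0; co < Cout; ++co)
    for (int f = 0; f < k * k * C; ++f)
      Wm(co, f) = w[f + k * k * C * co];

  arma::mat dWm(Cout, k * k * C, arma::fill::zeros);
  NumericVector db(Cout);
  NumericVector dx(x.size());
  dx.attr("dim") = xd;

  arma::mat col, dyM(Cout, Ho * Wo);
  for (int n = 0; n < N; ++n) {
    const double* dyp = &dy[0] + (size_t)Ho * Wo * Cout * n;
    for (int co = 0; co < Cout; ++co)
      for (int p = 0; p < Ho * Wo; ++p)
        dyM(co, p) = dyp[p + Ho * Wo * co];
    im2col(&x[0] + (size_t)H * W * C * n, H, W, C, k, stride, col);
    dWm += dyM * col.t();
    for (int co = 0; co < Cout; ++co) db[co] += arma::accu(dyM.row(co));
    arma::mat dcol = Wm.t() * dyM;         // (k*k*C, Ho*Wo)
    col2im(dcol, H, W, C, k, stride, &dx[0] + (size_t)H * W * C * n);
  }

  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  for (int co = 0; co < Cout; ++co)
    for (int f = 0; f < k * k * C; ++f)
      dw[f + k * k * C * co] = dWm(co, f);
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// depthwise 2-d convolution: w is (k, k, C), one filter per input channel
// [[Rcpp::export(name = ".nn_dwconv2d_fwd")]]
NumericVector nn_dwconv2d_fwd(NumericVector x, NumericVector w,
                              NumericVector b, int stride) {
  IntegerVector xd = dims4(x);
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 3) stop("depthwise weights must be (k, k, C)");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0];
  if (wd[2] != C) stop("depthwise weight channels mismatch");
  const int Ho = out_size(H, k, stride), Wo = out_size(W, k, stride);
  const int ph = pad_before(H, k, stride), pw = pad_before(W, k, stride);

  NumericVector y(Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n) {
    const double* xp = &x[0] + (size_t)H * W * C * n;
    double* yp = &y[0] + (size_t)Ho * Wo * C * n;
    for (int c = 0; c < C; ++c) {
      const double* wc = &w[0] + k * k * c;
      for (int ow = 0; ow < Wo; ++ow) {
        for (int oh = 0; oh < Ho; ++oh) {
          double acc = b[c];
          const int h0 = oh * stride - ph, w0 = ow * stride - pw;
          for (int j = 0; j < k; ++j) {
            const int ww = w0 + j;
            if (ww < 0 || ww >= W) continue;
            for (int i = 0; i < k; ++i) {
              const int hh = h0 + i;
              if (hh < 0 || hh >= H) continue;
              acc += wc[i + k * j] * xp[hh + H * (ww + W * c)];
            }
          }
          yp[oh + Ho * (ow + Wo * c)] = acc;
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".nn_dwconv2d_bwd")]]
List nn_dwconv2d_bwd(NumericVector x, NumericVector w,
                     NumericVector dy, int stride) {
  IntegerVector xd = dims4(x);
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0];
  const int Ho = out_size(H, k, stride), Wo = out_size(W, k, stride);
  const int ph = pad_before(H, k, stride), pw = pad_before(W, k, stride);

  NumericVector dx(x.size()); dx.attr("dim") = xd;
  NumericVector dw(w.size()); dw.attr("dim") = wd;
  NumericVector db(C);
  for (int n = 0; n < N; ++n) {
    const double* xp = &x[0] + (size_t)H * W * C * n;
    const double* dyp = &dy[0] + (size_t)Ho * Wo * C * n;
    double* dxp = &dx[0] + (size_t)H * W * C * n;
    for (int c = 0; c < C; ++c) {
      const double* wc = &w[0] + k * k * c;
      double* dwc = &dw[0] + k * k * c;
      for (int ow = 0; ow < Wo; ++ow) {
        for (int oh = 0; oh < Ho; ++oh) {
          const double g = dyp[oh + Ho * (ow + Wo * c)];
          db[c] += g;
          const int h0 = oh * stride - ph, w0 = ow * stride - pw;
          for (int j = 0; j < k; ++j) {
            const int ww = w0 + j;
            if (ww < 0 || ww >= W) continue;
            for (int i = 0; i < k; ++i) {
              const int hh = h0 + i;
              if (hh < 0 || hh >= H) continue;
              dwc[i + k * j] += g * xp[hh + H * (ww + W * c)];
              dxp[hh + H * (ww + W * c)] += g * wc[i + k * j];
            }
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// max pooling with 'same' padding; returns pooled values and 0-based flat
// argmax indices into the input array (for the backward pass)
// [[Rcpp::export(name = ".nn_maxpool_fwd")]]
List nn_maxpool_fwd(NumericVector x, int k, int stride) {
  IntegerVector xd = dims4(x);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = out_size(H, k, stride), Wo = out_size(W, k, stride);
  const int ph = pad_before(H, k, stride), pw = pad_before(W, k, stride);

  NumericVector y(Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  NumericVector idx(y.size());     // double-stored flat indices (can exceed int in theory)
  idx.attr("dim") = y.attr("dim");
  for (int n = 0; n < N; ++n) {
    const double* xp = &x[0] + (size_t)H * W * C * n;
    for (int c = 0; c < C; ++c) {
      for (int ow = 0; ow < Wo; ++ow) {
        for (int oh = 0; oh < Ho; ++oh) {
          const int h0 = oh * stride - ph, w0 = ow * stride - pw;
          double best = -std::numeric_limits<double>::infinity();
          long long bi = -1;
          for (int j = 0; j < k; ++j) {
            const int ww = w0 + j;
            if (ww < 0 || ww >= W) continue;
            for (int i = 0; i < k; ++i) {
              const int hh = h0 + i;
              if (hh < 0 || hh >= H) continue;
              const double v = xp[hh + H * (ww + W * c)];
              if (v > best) { best = v; bi = hh + (long long)H * (ww + (long long)W * c); }
            }
          }
          const size_t o = (size_t)oh + Ho * ((size_t)ow + Wo * ((size_t)c + (size_t)C * n));
          y[o] = best;
          idx[o] = (double)(bi + (long long)H * W * C * n);
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".nn_maxpool_bwd")]]
NumericVector nn_maxpool_bwd(NumericVector idx, NumericVector dy,
                             IntegerVector xdim) {
  size_t n = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(n);
  dx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < dy.size(); ++i)
    dx[(size_t)idx[i]] += dy[i];
  return dx;
}

// nearest-neighbour 2x upsampling
// [[Rcpp::export(name = ".nn_upsample2_fwd")]]
NumericVector nn_upsample2_fwd(NumericVector x) {
  IntegerVector xd = dims4(x);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector y((size_t)4 * H * W * C * N);
  y.attr("dim") = IntegerVector::create(2 * H, 2 * W, C, N);
  const int H2 = 2 * H, W2 = 2 * W;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xp = &x[0] + (size_t)H * W * ((size_t)c + (size_t)C * n);
      double* yp = &y[0] + (size_t)H2 * W2 * ((size_t)c + (size_t)C * n);
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          const double v = xp[h + H * w];
          yp[2 * h     + H2 * (2 * w)]     = v;
          yp[2 * h + 1 + H2 * (2 * w)]     = v;
          yp[2 * h     + H2 * (2 * w + 1)] = v;
          yp[2 * h + 1 + H2 * (2 * w + 1)] = v;
        }
    }
  return y;
}

// [[Rcpp::export(name = ".nn_upsample2_bwd")]]
NumericVector nn_upsample2_bwd(NumericVector dy, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int H2 = 2 * H, W2 = 2 * W;
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = xdim;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* dyp = &dy[0] + (size_t)H2 * W2 * ((size_t)c + (size_t)C * n);
      double* dxp = &dx[0] + (size_t)H * W * ((size_t)c + (size_t)C * n);
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h)
          dxp[h + H * w] =
            dyp[2 * h     + H2 * (2 * w)] +
            dyp[2 * h + 1 + H2 * (2 * w)] +
            dyp[2 * h     + H2 * (2 * w + 1)] +
            dyp[2 * h + 1 + H2 * (2 * w + 1)];
    }
  return dx;
}
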