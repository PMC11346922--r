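// Low-level tensor kernels for the conv-net engine: im2col convolution
// forward/backward, max pooling, and image resizing. Arrays use R's
// column-major layout with dimensions (H, W, C, N).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void im2col(const double* xn, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, arma::mat& cols) {
  cols.zeros();
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < kw; ++j)
      for (int i = 0; i < kh; ++i) {
        int r = i + kh * (j + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          int wx = wo * stride + j - pad;
          if (wx < 0 || wx >= W) continue;
          const double* xcol = xn + (size_t)H * (wx + (size_t)W * c);
          for (int ho = 0; ho < Ho; ++ho) {
            int hx = ho * stride + i - pad;
            if (hx < 0 || hx >= H) continue;
            cols(r, ho + (size_t)Ho * wo) = xcol[hx];
          }
        }
      }
}

// [[Rcpp::export]]
NumericVector conv2d_forward_cpp(NumericVector x, IntegerVector xdim,
                                 NumericVector w, IntegerVector wdim,
                                 NumericVector b, int stride, int pad) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int kh = wdim[0], kw = wdim[1], Cout = wdim[3];
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  const int K = kh * kw * C, Q = Ho * Wo;
  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  NumericVector out((R_xlen_t)Q * Cout * N);
  arma::mat cols(K, Q);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, stride, pad,
           Ho, Wo, cols);
    arma::mat o = Wm.t() * cols;  // Cout x Q
    double* on = out.begin() + (size_t)Q * Cout * n;
    for (int oc = 0; oc < Cout; ++oc) {
      const double bo = b[oc];
      for (int q = 0; q < Q; ++q) on[q + (size_t)Q * oc] = o(oc, q) + bo;
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  return out;
}

// [[Rcpp::export]]
List conv2d_backward_cpp(NumericVector x, IntegerVector xdim,
                         NumericVector w, IntegerVector wdim,
                         NumericVector dout, int stride, int pad) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int kh = wdim[0], kw = wdim[1], Cout = wdim[3];
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  const int K = kh * kw * C, Q = Ho * Wo;
  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::mat dW(K, Cout, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  NumericVector dx((R_xlen_t)H * W * C * N);
  arma::mat cols(K, Q), D(Cout, Q);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, stride, pad,
           Ho, Wo, cols);
    const double* dn = dout.begin() + (size_t)Q * Cout * n;
    for (int oc = 0; oc < Cout; ++oc)
      for (int q = 0; q < Q; ++q) D(oc, q) = dn[q + (size_t)Q * oc];
    dW += cols * D.t();
    db += arma::sum(D, 1);
    arma::mat dcols = Wm * D;  // K x Q
    double* dxn = dx.begin() + (size_t)H * W * C * n;
    for (int c = 0; c < C; ++c)
      for (int j = 0; j < kw; ++j)
        for (int i = 0; i < kh; ++i) {
          int r = i + kh * (j + kw * c);
          for (int wo = 0; wo < Wo; ++wo) {
            int wx = wo * stride + j - pad;
            if (wx < 0 || wx >= W) continue;
            double* dxcol = dxn + (size_t)H * (wx + (size_t)W * c);
            for (int ho = 0; ho < Ho; ++ho) {
              int hx = ho * stride + i - pad;
              if (hx < 0 || hx >= H) continue;
              dxcol[hx] += dcols(r, ho + (size_t)Ho * wo);
            }
          }
        }
  }
  NumericVector dWr(dW.begin(), dW.end());
  dWr.attr("dim") = wdim;
  dx.attr("dim") = xdim;
  return List::create(_["dx"] = dx, _["dW"] = dWr,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// [[Rcpp::export]]
List maxpool_forward_cpp(NumericVector x, IntegerVector xdim,
                         int size, int stride) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = (H - size) / stride + 1;
  const int Wo = (W - size) / stride + 1;
  NumericVector out((R_xlen_t)Ho * Wo * C * N);
  IntegerVector arg((R_xlen_t)Ho * Wo * C * N);  // flat index into x
  R_xlen_t oi = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xn = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      const R_xlen_t base = (R_xlen_t)H * W * (c + (R_xlen_t)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double best = R_NegInf; int besti = 0;
          for (int j = 0; j < size; ++j) {
            int wx = wo * stride + j;
            for (int i = 0; i < size; ++i) {
              int hx = ho * stride + i;
              double v = xn[hx + (size_t)H * wx];
              if (v > best) { best = v; besti = hx + H * wx; }
            }
          }
          R_xlen_t k = (R_xlen_t)(ho + (R_xlen_t)Ho * wo) +
                       (R_xlen_t)Ho * Wo * (c + (R_xlen_t)C * n);
          out[k] = best;
          arg[k] = (int)(base + besti);
          ++oi;
        }
    }
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["out"] = out, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool_backward_cpp(NumericVector dout, IntegerVector arg,
                                   IntegerVector xdim) {
  NumericVector dx((R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  for (R_xlen_t k = 0; k < dout.size(); ++k) dx[arg[k]] += dout[k];
  dx.attr("dim") = xdim;
  return dx;
}

// Resize a single-channel image. method: 0 = nearest, 1 = bilinear
// (half-pixel centre alignment, edges clamped).
// [[Rcpp::export]]
NumericMatrix resize_image_cpp(NumericMatrix x, int out_h, int out_w,
                               int method) {
  const int H = x.nrow(), W = x.ncol();
  NumericMatrix out(out_h, out_w);
  const double sh = (double)H / out_h, sw = (double)W / out_w;
  for (int j = 0; j < out_w; ++j) {
    double sx = (j + 0.5) * sw - 0.5;
    for (int i = 0; i < out_h; ++i) {
      double sy = (i + 0.5) * sh - 0.5;
      if (method == 0) {
        int yi = (int)std::floor(sy + 0.5), xi = (int)std::floor(sx + 0.5);
        yi = std::min(std::max(yi, 0), H - 1);
        xi = std::min(std::max(xi, 0), W - 1);
        out(i, j) = x(yi, xi);
      } else {
        double yc = std::min(std::max(sy, 0.0), (double)(H - 1));
        double xc = std::min(std::max(sx, 0.0), (double)(W - 1));
        int y0 = (int)std::floor(yc), x0 = (int)std::floor(xc);
        int y1 = std::min(y0 + 1, H - 1), x1 = std::min(x0 + 1, W - 1);
        double fy = yc - y0, fx = xc - x0;
        out(i, j) = (1 - fy) * ((1 - fx) * x(y0, x0) + fx * x(y0, x1)) +
                    fy * ((1 - fx) * x(y1, x0) + fx * x(y1, x1));
      }
    }
  }
  return out;
}
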