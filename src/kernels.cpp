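// Low-level numerical kernels for the segmentation network and image ops.
// Tensor layout throughout: R arrays dim (H, W, C, N), column-major, so an
// (h, w, c, n) element sits at h + H*(w + W*(c + C*n)). Convolution weights
// are R arrays dim (kh, kw, Cin, Cout), flattened column-major to a
// (kh*kw*Cin) x Cout matrix.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int conv_out_dim(int in, int k, int stride, int dil, int pad) {
  return (in + 2 * pad - dil * (k - 1) - 1) / stride + 1;
}

// Gather the receptive fields of every output pixel of one sample into a
// (kh*kw*Cin) x (Hout*Wout) matrix; out-of-bounds taps are zero.
static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int stride, int dil, int pad,
                   int Hout, int Wout, arma::mat& K) {
  K.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int row = ki + kh * (kj + kw * c);
        for (int wo = 0; wo < Wout; ++wo) {
          const int wi = wo * stride - pad + kj * dil;
          if (wi < 0 || wi >= W) continue;
          const double* xcol = xc + (size_t)H * wi;
          double* krow = K.memptr() + row;
          const size_t ldK = K.n_rows;
          for (int ho = 0; ho < Hout; ++ho) {
            const int hi = ho * stride - pad + ki * dil;
            if (hi < 0 || hi >= H) continue;
            krow[ldK * (ho + (size_t)Hout * wo)] = xcol[hi];
          }
        }
      }
    }
  }
}

// Scatter-add of the im2col adjoint back onto the input gradient.
static void col2im(const arma::mat& G, int H, int W, int C,
                   int kh, int kw, int stride, int dil, int pad,
                   int Hout, int Wout, double* gx) {
  for (int c = 0; c < C; ++c) {
    double* gc = gx + (size_t)H * W * c;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int row = ki + kh * (kj + kw * c);
        for (int wo = 0; wo < Wout; ++wo) {
          const int wi = wo * stride - pad + kj * dil;
          if (wi < 0 || wi >= W) continue;
          double* gcol = gc + (size_t)H * wi;
          const double* grow = G.memptr() + row;
          const size_t ldG = G.n_rows;
          for (int ho = 0; ho < Hout; ++ho) {
            const int hi = ho * stride - pad + ki * dil;
            if (hi < 0 || hi >= H) continue;
            gcol[hi] += grow[ldG * (ho + (size_t)Hout * wo)];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                         int stride, int dil, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: input has %d channels, weight expects %d", C, Cin);
  const int Hout = conv_out_dim(H, kh, stride, dil, pad);
  const int Wout = conv_out_dim(W, kw, stride, dil, pad);
  if (Hout < 1 || Wout < 1) stop("conv2d: output would be empty");

  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)kh * kw * Cin, Cout, false, true);
  arma::vec bv(const_cast<double*>(b.begin()), Cout, false, true);
  NumericVector y((size_t)Hout * Wout * Cout * N);
  y.attr("dim") = IntegerVector::create(Hout, Wout, Cout, N);

  arma::mat K((size_t)kh * kw * Cin, (size_t)Hout * Wout);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, stride, dil, pad,
           Hout, Wout, K);
    arma::mat Y(y.begin() + (size_t)Hout * Wout * Cout * n,
                (size_t)Hout * Wout, Cout, false, true);
    Y = K.t() * Wm;
    Y.each_row() += bv.t();
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                int stride, int dil, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), gd = gy.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  const int Hout = gd[0], Wout = gd[1];

  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)kh * kw * Cin, Cout, false, true);
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = xd;
  NumericVector gw((size_t)kh * kw * Cin * Cout);
  gw.attr("dim") = wd;
  NumericVector gb(Cout);

  arma::mat Gw(gw.begin(), (size_t)kh * kw * Cin, Cout, false, true);
  arma::vec Gb(gb.begin(), Cout, false, true);
  arma::mat K((size_t)kh * kw * Cin, (size_t)Hout * Wout);
  for (int n = 0; n < N; ++n) {
    arma::mat Gy(const_cast<double*>(gy.begin()) + (size_t)Hout * Wout * Cout * n,
                 (size_t)Hout * Wout, Cout, false, true);
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, stride, dil, pad,
           Hout, Wout, K);
    Gw += K * Gy;
    Gb += arma::sum(Gy, 0).t();
    arma::mat Gk = Wm * Gy.t();  // (kh*kw*Cin) x (Hout*Wout)
    col2im(Gk, H, W, C, kh, kw, stride, dil, pad, Hout, Wout,
           gx.begin() + (size_t)H * W * C * n);
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Half-pixel-centre source coordinate for resampling.
static inline double src_coord(int o, int out, int in) {
  return (o + 0.5) * (double)in / (double)out - 0.5;
}

// [[Rcpp::export(name = ".resize_bilinear_fwd")]]
NumericVector resize_bilinear_fwd(NumericVector x, int Hout, int Wout) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector y((size_t)Hout * Wout * C * N);
  y.attr("dim") = IntegerVector::create(Hout, Wout, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      double* yc = y.begin() + (size_t)Hout * Wout * (c + (size_t)C * n);
      for (int wo = 0; wo < Wout; ++wo) {
        double sx = src_coord(wo, Wout, W);
        int x0 = (int)std::floor(sx);
        double fx = sx - x0;
        int x1 = std::min(std::max(x0 + 1, 0), W - 1);
        x0 = std::min(std::max(x0, 0), W - 1);
        for (int ho = 0; ho < Hout; ++ho) {
          double sy = src_coord(ho, Hout, H);
          int y0 = (int)std::floor(sy);
          double fy = sy - y0;
          int y1 = std::min(std::max(y0 + 1, 0), H - 1);
          y0 = std::min(std::max(y0, 0), H - 1);
          yc[ho + (size_t)Hout * wo] =
            (1 - fy) * (1 - fx) * xc[y0 + (size_t)H * x0] +
            (1 - fy) * fx       * xc[y0 + (size_t)H * x1] +
            fy       * (1 - fx) * xc[y1 + (size_t)H * x0] +
            fy       * fx       * xc[y1 + (size_t)H * x1];
        }
      }
    }
  return y;
}

// [[Rcpp::export(name = ".resize_bilinear_bwd")]]
NumericVector resize_bilinear_bwd(NumericVector gy, int H, int W) {
  IntegerVector gd = gy.attr("dim");
  const int Hout = gd[0], Wout = gd[1], C = gd[2], N = gd[3];
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* gc = gx.begin() + (size_t)H * W * (c + (size_t)C * n);
      const double* gyc = gy.begin() + (size_t)Hout * Wout * (c + (size_t)C * n);
      for (int wo = 0; wo < Wout; ++wo) {
        double sx = src_coord(wo, Wout, W);
        int x0 = (int)std::floor(sx);
        double fx = sx - x0;
        int x1 = std::min(std::max(x0 + 1, 0), W - 1);
        x0 = std::min(std::max(x0, 0), W - 1);
        for (int ho = 0; ho < Hout; ++ho) {
          double sy = src_coord(ho, Hout, H);
          int y0 = (int)std::floor(sy);
          double fy = sy - y0;
          int y1 = std::min(std::max(y0 + 1, 0), H - 1);
          y0 = std::min(std::max(y0, 0), H - 1);
          const double g = gyc[ho + (size_t)Hout * wo];
          gc[y0 + (size_t)H * x0] += (1 - fy) * (1 - fx) * g;
          gc[y0 + (size_t)H * x1] += (1 - fy) * fx * g;
          gc[y1 + (size_t)H * x0] += fy * (1 - fx) * g;
          gc[y1 + (size_t)H * x1] += fy * fx * g;
        }
      }
    }
  return gx;
}

// [[Rcpp::export(name = ".resize_nearest")]]
NumericMatrix resize_nearest(NumericMatrix x, int Hout, int Wout) {
  const int H = x.nrow(), W = x.ncol();
  NumericMatrix y(Hout, Wout);
  for (int wo = 0; wo < Wout; ++wo) {
    int wi = std::min(std::max((int)std::floor((wo + 0.5) * (double)W / Wout), 0), W - 1);
    for (int ho = 0; ho < Hout; ++ho) {
      int hi = std::min(std::max((int)std::floor((ho + 0.5) * (double)H / Hout), 0), H - 1);
      y(ho, wo) = x(hi, wi);
    }
  }
  return y;
}

// Inverse-mapping affine warp of one 2-D image about its centre.
// m = c(a, b, c, d, tx, ty): source = M %*% (dest - centre) + centre + t.
// bilinear = false resamples nearest-neighbour (for label masks).
// [[Rcpp::export(name = ".warp_affine")]]
NumericMatrix warp_affine(NumericMatrix x, NumericVector m, bool bilinear,
                          double fill) {
  const int H = x.nrow(), W = x.ncol();
  NumericMatrix y(H, W);
  const double a = m[0], b = m[1], c = m[2], d = m[3], tx = m[4], ty = m[5];
  const double cy = (H - 1) / 2.0, cx = (W - 1) / 2.0;
  for (int wo = 0; wo < W; ++wo)
    for (int ho = 0; ho < H; ++ho) {
      const double dy = ho - cy, dx = wo - cx;
      const double sy = a * dy + b * dx + cy + ty;
      const double sx = c * dy + d * dx + cx + tx;
      if (bilinear) {
        int y0 = (int)std::floor(sy), x0 = (int)std::floor(sx);
        const double fy = sy - y0, fx = sx - x0;
        double v = 0.0, wsum = 0.0;
        for (int jj = 0; jj <= 1; ++jj)
          for (int ii = 0; ii <= 1; ++ii) {
            const int yy = y0 + ii, xx = x0 + jj;
            const double wgt = (ii ? fy : 1 - fy) * (jj ? fx : 1 - fx);
            if (yy >= 0 && yy < H && xx >= 0 && xx < W) {
              v += wgt * x(yy, xx);
              wsum += wgt;
            }
          }
        y(ho, wo) = wsum > 0 ? v + (1.0 - wsum) * fill : fill;
      } else {
        const int yy = (int)std::lround(sy), xx = (int)std::lround(sx);
        y(ho, wo) = (yy >= 0 && yy < H && xx >= 0 && xx < W) ? x(yy, xx) : fill;
      }
    }
  return y;
}

// Directed/symmetric Hausdorff distance between two point sets given as
// k x 2 coordinate matrices. Plain all-pairs scan; boundary sets are small.
// [[Rcpp::export(name = ".hausdorff_cpp")]]
double hausdorff_cpp(NumericMatrix A, NumericMatrix B) {
  const int na = A.nrow(), nb = B.nrow();
  double hAB = 0.0, hBA = 0.0;
  std::vector<double> minB(nb, std::numeric_limits<double>::infinity());
  for (int i = 0; i < na; ++i) {
    double mn = std::numeric_limits<double>::infinity();
    for (int j = 0; j < nb; ++j) {
      const double d0 = A(i, 0) - B(j, 0), d1 = A(i, 1) - B(j, 1);
      const double d2 = d0 * d0 + d1 * d1;
      if (d2 < mn) mn = d2;
      if (d2 < minB[j]) minB[j] = d2;
    }
    if (mn > hAB) hAB = mn;
  }
  for (int j = 0; j < nb; ++j)
    if (minB[j] > hBA) hBA = minB[j];
  return std::sqrt(std::max(hAB, hBA));
}
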