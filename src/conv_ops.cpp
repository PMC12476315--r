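// Low-level tensor primitives for the U-Net engine.
//
// All image tensors are R arrays in column-major [H, W, C, N] layout
// (row index fastest), matching base R's array semantics so the R side can
// slice and combine activations without copies through aperm().
//
// Convolution weights are matrices of shape (k*k*Cin) x Cout with row index
// c*k*k + dj*k + di  (di = kernel row offset, dj = kernel column offset,
// c = input channel).  Transposed-convolution (2x2, stride 2) weights are
// (Cin) x (4*Cout) with column index co*4 + dj*2 + di.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void dims4(const NumericVector& a, int& H, int& W, int& C, int& N) {
  IntegerVector d = a.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array [H,W,C,N]");
  H = d[0]; W = d[1]; C = d[2]; N = d[3];
}

// im2col for zero-padded 'same' convolution with odd kernel k.
// Output: (H*W) x (k*k*C); row index = h + H*w.
static void im2col(const double* xn, int H, int W, int C, int k, arma::mat& cols) {
  const int pad = k / 2;
  cols.zeros();
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int col = c * k * k + dj * k + di;
        double* dst = cols.colptr(col);
        for (int w = 0; w < W; ++w) {
          const int sw = w + dj - pad;
          if (sw < 0 || sw >= W) continue;
          const double* src = xn + (size_t)H * (sw + (size_t)W * c);
          double* d = dst + (size_t)H * w;
          const int hlo = std::max(0, pad - di);
          const int hhi = std::min(H, H + pad - di);
          for (int h = hlo; h < hhi; ++h) d[h] = src[h + di - pad];
        }
      }
    }
  }
}

// col2im: scatter-add the column representation back onto the image grid.
static void col2im(const arma::mat& cols, int H, int W, int C, int k, double* xn) {
  const int pad = k / 2;
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int col = c * k * k + dj * k + di;
        const double* src = cols.colptr(col);
        for (int w = 0; w < W; ++w) {
          const int sw = w + dj - pad;
          if (sw < 0 || sw >= W) continue;
          double* dst = xn + (size_t)H * (sw + (size_t)W * c);
          const double* s = src + (size_t)H * w;
          const int hlo = std::max(0, pad - di);
          const int hhi = std::min(H, H + pad - di);
          for (int h = hlo; h < hhi; ++h) dst[h + di - pad] += s[h];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector x, NumericMatrix Wm, NumericVector b, int k) {
  int H, W, C, N; dims4(x, H, W, C, N);
  if (Wm.nrow() != k * k * C) stop("conv weight rows do not match k*k*Cin");
  const int Cout = Wm.ncol();
  NumericVector y((R_xlen_t)H * W * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat Wa(Wm.begin(), Wm.nrow(), Cout, false);
  arma::rowvec bv(b.begin(), Cout);
  arma::mat cols(H * W, k * k * C);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, k, cols);
    arma::mat yn(y.begin() + (size_t)H * W * Cout * n, H * W, Cout, false, true);
    yn = cols * Wa;
    yn.each_row() += bv;
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x, NumericMatrix Wm, NumericVector dy, int k) {
  int H, W, C, N; dims4(x, H, W, C, N);
  const int Cout = Wm.ncol();
  arma::mat Wa(Wm.begin(), Wm.nrow(), Cout, false);
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  arma::mat dW(Wm.nrow(), Cout, arma::fill::zeros);
  arma::rowvec db(Cout, arma::fill::zeros);
  arma::mat cols(H * W, k * k * C);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, k, cols);
    arma::mat dyn(dy.begin() + (size_t)H * W * Cout * n, H * W, Cout, false, true);
    dW += cols.t() * dyn;
    db += arma::sum(dyn, 0);
    arma::mat dcols = dyn * Wa.t();
    col2im(dcols, H, W, C, k, dx.begin() + (size_t)H * W * C * n);
  }
  NumericMatrix dWr(Wm.nrow(), Cout);
  std::copy(dW.begin(), dW.end(), dWr.begin());
  NumericVector dbr(Cout);
  std::copy(db.begin(), db.end(), dbr.begin());
  return List::create(_["dx"] = dx, _["dW"] = dWr, _["db"] = dbr);
}

// 2x2 max pooling, stride 2.  idx codes the argmax position di + 2*dj.
// [[Rcpp::export]]
List cpp_maxpool2_fw(NumericVector x) {
  int H, W, C, N; dims4(x, H, W, C, N);
  if (H % 2 || W % 2) stop("maxpool2 requires even spatial dims");
  const int H2 = H / 2, W2 = W / 2;
  NumericVector y((R_xlen_t)H2 * W2 * C * N);
  y.attr("dim") = IntegerVector::create(H2, W2, C, N);
  IntegerVector idx((R_xlen_t)H2 * W2 * C * N);
  idx.attr("dim") = IntegerVector::create(H2, W2, C, N);
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  for (R_xlen_t cn = 0; cn < (R_xlen_t)C * N; ++cn) {
    const double* xs = xp + (size_t)H * W * cn;
    double* ys = yp + (size_t)H2 * W2 * cn;
    int* is = ip + (size_t)H2 * W2 * cn;
    for (int w = 0; w < W2; ++w) {
      for (int h = 0; h < H2; ++h) {
        double best = -1e300; int code = 0;
        for (int dj = 0; dj < 2; ++dj) {
          for (int di = 0; di < 2; ++di) {
            double v = xs[(2 * h + di) + (size_t)H * (2 * w + dj)];
            if (v > best) { best = v; code = di + 2 * dj; }
          }
        }
        ys[h + (size_t)H2 * w] = best;
        is[h + (size_t)H2 * w] = code;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bw(NumericVector dy, IntegerVector idx) {
  int H2, W2, C, N; dims4(dy, H2, W2, C, N);
  const int H = 2 * H2, W = 2 * W2;
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double* dyp = dy.begin();
  const int* ip = idx.begin();
  double* dxp = dx.begin();
  for (R_xlen_t cn = 0; cn < (R_xlen_t)C * N; ++cn) {
    const double* ds = dyp + (size_t)H2 * W2 * cn;
    const int* is = ip + (size_t)H2 * W2 * cn;
    double* xs = dxp + (size_t)H * W * cn;
    for (int w = 0; w < W2; ++w) {
      for (int h = 0; h < H2; ++h) {
        const int code = is[h + (size_t)H2 * w];
        const int di = code & 1, dj = code >> 1;
        xs[(2 * h + di) + (size_t)H * (2 * w + dj)] += ds[h + (size_t)H2 * w];
      }
    }
  }
  return dx;
}

// Transposed convolution, 2x2 kernel, stride 2 (doubles H and W).
// [[Rcpp::export]]
NumericVector cpp_upconv2_fw(NumericVector x, NumericMatrix Wm, NumericVector b) {
  int H, W, C, N; dims4(x, H, W, C, N);
  if (Wm.nrow() != C || Wm.ncol() % 4) stop("upconv weight shape mismatch");
  const int Cout = Wm.ncol() / 4;
  NumericVector y((R_xlen_t)4 * H * W * Cout * N);
  y.attr("dim") = IntegerVector::create(2 * H, 2 * W, Cout, N);
  arma::mat Wa(Wm.begin(), C, 4 * Cout, false);
  double* yp = y.begin();
  const int H2 = 2 * H, W2 = 2 * W;
  for (int n = 0; n < N; ++n) {
    arma::mat xn(const_cast<double*>(x.begin()) + (size_t)H * W * C * n,
                 H * W, C, false, true);
    arma::mat yn = xn * Wa;  // (H*W) x (4*Cout)
    double* ypn = yp + (size_t)H2 * W2 * Cout * n;
    for (int co = 0; co < Cout; ++co) {
      const double bc = b[co];
      for (int dj = 0; dj < 2; ++dj) {
        for (int di = 0; di < 2; ++di) {
          const double* src = yn.colptr(co * 4 + dj * 2 + di);
          for (int w = 0; w < W; ++w) {
            double* dst = ypn + (size_t)H2 * ((2 * w + dj) + (size_t)W2 * co);
            const double* s = src + (size_t)H * w;
            for (int h = 0; h < H; ++h) dst[2 * h + di] = s[h] + bc;
          }
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_upconv2_bw(NumericVector x, NumericMatrix Wm, NumericVector dy) {
  int H, W, C, N; dims4(x, H, W, C, N);
  const int Cout = Wm.ncol() / 4;
  const int H2 = 2 * H, W2 = 2 * W;
  arma::mat Wa(Wm.begin(), C, 4 * Cout, false);
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  arma::mat dW(C, 4 * Cout, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  arma::mat dyg(H * W, 4 * Cout);  // gathered gradient per sample
  for (int n = 0; n < N; ++n) {
    const double* dyn = dy.begin() + (size_t)H2 * W2 * Cout * n;
    for (int co = 0; co < Cout; ++co) {
      double acc = 0.0;
      for (int dj = 0; dj < 2; ++dj) {
        for (int di = 0; di < 2; ++di) {
          double* dst = dyg.colptr(co * 4 + dj * 2 + di);
          for (int w = 0; w < W; ++w) {
            const double* s = dyn + (size_t)H2 * ((2 * w + dj) + (size_t)W2 * co);
            double* d = dst + (size_t)H * w;
            for (int h = 0; h < H; ++h) { d[h] = s[2 * h + di]; acc += s[2 * h + di]; }
          }
        }
      }
      db[co] += acc;
    }
    arma::mat xn(const_cast<double*>(x.begin()) + (size_t)H * W * C * n,
                 H * W, C, false, true);
    dW += xn.t() * dyg;
    arma::mat dxn(dx.begin() + (size_t)H * W * C * n, H * W, C, false, true);
    dxn = dyg * Wa.t();
  }
  NumericMatrix dWr(C, 4 * Cout);
  std::copy(dW.begin(), dW.end(), dWr.begin());
  NumericVector dbr(Cout);
  std::copy(db.begin(), db.end(), dbr.begin());
  return List::create(_["dx"] = dx, _["dW"] = dWr, _["db"] = dbr);
}

// Parameter-free nearest-neighbour 2x upsampling and its adjoint.
// [[Rcpp::export]]
NumericVector cpp_upsample2_fw(NumericVector x) {
  int H, W, C, N; dims4(x, H, W, C, N);
  const int H2 = 2 * H, W2 = 2 * W;
  NumericVector y((R_xlen_t)H2 * W2 * C * N);
  y.attr("dim") = IntegerVector::create(H2, W2, C, N);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (R_xlen_t cn = 0; cn < (R_xlen_t)C * N; ++cn) {
    const double* xs = xp + (size_t)H * W * cn;
    double* ys = yp + (size_t)H2 * W2 * cn;
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        const double v = xs[h + (size_t)H * w];
        ys[(2 * h) + (size_t)H2 * (2 * w)] = v;
        ys[(2 * h + 1) + (size_t)H2 * (2 * w)] = v;
        ys[(2 * h) + (size_t)H2 * (2 * w + 1)] = v;
        ys[(2 * h + 1) + (size_t)H2 * (2 * w + 1)] = v;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_bw(NumericVector dy) {
  int H2, W2, C, N; dims4(dy, H2, W2, C, N);
  const int H = H2 / 2, W = W2 / 2;
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double* dyp = dy.begin();
  double* dxp = dx.begin();
  for (R_xlen_t cn = 0; cn < (R_xlen_t)C * N; ++cn) {
    const double* ds = dyp + (size_t)H2 * W2 * cn;
    double* xs = dxp + (size_t)H * W * cn;
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        xs[h + (size_t)H * w] =
          ds[(2 * h) + (size_t)H2 * (2 * w)] +
          ds[(2 * h + 1) + (size_t)H2 * (2 * w)] +
          ds[(2 * h) + (size_t)H2 * (2 * w + 1)] +
          ds[(2 * h + 1) + (size_t)H2 * (2 * w + 1)];
      }
    }
  }
  return dx;
}
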