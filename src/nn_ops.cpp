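// Low-level kernels for the conv-net core: im2col convolutions,
// 2x2 max pooling and 2x2 stride-2 transpose convolutions.
// Tensors are (H, W, C) R arrays (column-major). Conv weights are
// (k*k*Cin) x Cout matrices whose row ordering is the column-major
// flattening of an R array with dim (k, k, Cin). All kernels operate on
// zero-copy views of the R memory; outputs are allocated as R objects.

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline IntegerVector tensor_dims(const NumericVector& x) {
  if (x.hasAttribute("dim")) return x.attr("dim");
  stop("tensor lacks dim attribute");
}

// Fill `cols` ((Ho*Wo) x (k*k*C), column-major) from x; contiguous spans
// along the first image dimension are copied with memcpy, out-of-image
// (padding) cells are zeroed explicitly.
static void im2col_fill(double* cols, const double* x, int H, int W, int C,
                        int k, int stride, int pad, int Ho, int Wo) {
  const long n = (long)Ho * Wo;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (long)c * H * W;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        double* col = cols + ((long)(c * k * k + kj * k + ki)) * n;
        // valid output-row range for this kernel row offset
        // xi = i*stride + ki - pad must lie in [0, H)
        int ilo = 0, ihi = Ho;
        while (ilo < Ho && ilo * stride + ki - pad < 0) ++ilo;
        while (ihi > ilo && (ihi - 1) * stride + ki - pad >= H) --ihi;
        for (int j = 0; j < Wo; ++j) {
          double* dst = col + (long)j * Ho;
          const int xj = j * stride + kj - pad;
          if (xj < 0 || xj >= W) {
            std::memset(dst, 0, sizeof(double) * Ho);
            continue;
          }
          if (ilo > 0) std::memset(dst, 0, sizeof(double) * ilo);
          if (ihi < Ho) {
            std::memset(dst + ihi, 0, sizeof(double) * (Ho - ihi));
          }
          const double* src = xc + (long)xj * H + (ki - pad);
          if (stride == 1) {
            std::memcpy(dst + ilo, src + ilo,
                        sizeof(double) * (ihi - ilo));
          } else {
            for (int i = ilo; i < ihi; ++i) dst[i] = src[(long)i * stride];
          }
        }
      }
    }
  }
}

// Scatter-add transpose of im2col_fill: dx += positions of dcols.
static void col2im_add(double* dx, const double* dcols, int H, int W,
                       int C, int k, int stride, int pad, int Ho, int Wo) {
  const long n = (long)Ho * Wo;
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (long)c * H * W;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const double* col = dcols + ((long)(c * k * k + kj * k + ki)) * n;
        int ilo = 0, ihi = Ho;
        while (ilo < Ho && ilo * stride + ki - pad < 0) ++ilo;
        while (ihi > ilo && (ihi - 1) * stride + ki - pad >= H) --ihi;
        for (int j = 0; j < Wo; ++j) {
          const int xj = j * stride + kj - pad;
          if (xj < 0 || xj >= W) continue;
          const double* src = col + (long)j * Ho;
          double* dst = xc + (long)xj * H + (ki - pad);
          if (stride == 1) {
            for (int i = ilo; i < ihi; ++i) dst[i] += src[i];
          } else {
            for (int i = ilo; i < ihi; ++i) dst[(long)i * stride] += src[i];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
List conv_fwd_cpp(const NumericVector& x, const NumericMatrix& W,
                  const NumericVector& b, int k, int stride, int pad) {
  IntegerVector d = tensor_dims(x);
  const int H = d[0], Wd = d[1], C = d[2];
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (Wd + 2 * pad - k) / stride + 1;
  const int Co = W.ncol();
  NumericMatrix cols(no_init((R_xlen_t)Ho * Wo, k * k * C));
  im2col_fill(cols.begin(), x.begin(), H, Wd, C, k, stride, pad, Ho, Wo);
  NumericVector out(no_init((R_xlen_t)Ho * Wo * Co));
  out.attr("dim") = IntegerVector::create(Ho, Wo, Co);
  arma::mat colv(cols.begin(), (size_t)Ho * Wo, k * k * C, false);
  const arma::mat Wv(const_cast<double*>(W.begin()), k * k * C, Co, false);
  arma::mat outv(out.begin(), (size_t)Ho * Wo, Co, false);
  outv = colv * Wv;
  const arma::vec bv(const_cast<double*>(b.begin()), Co, false);
  outv.each_row() += bv.t();
  return List::create(_["out"] = out, _["cols"] = cols);
}

// [[Rcpp::export]]
List conv_bwd_cpp(const NumericVector& dout, const NumericMatrix& cols,
                  const NumericMatrix& W, int H, int Wd, int C,
                  int k, int stride, int pad) {
  IntegerVector d = tensor_dims(dout);
  const int Ho = d[0], Wo = d[1], Co = d[2];
  const size_t n = (size_t)Ho * Wo;
  const arma::mat dv(const_cast<double*>(dout.begin()), n, Co, false);
  const arma::mat colv(const_cast<double*>(cols.begin()), n, k * k * C,
                       false);
  const arma::mat Wv(const_cast<double*>(W.begin()), k * k * C, Co, false);
  NumericMatrix dW(k * k * C, Co);
  arma::mat dWv(dW.begin(), k * k * C, Co, false);
  dWv = colv.t() * dv;
  NumericVector db(Co);
  arma::vec dbv(db.begin(), Co, false);
  dbv = arma::sum(dv, 0).t();
  arma::mat dcols = dv * Wv.t();
  NumericVector dx((R_xlen_t)H * Wd * C);  // zero-initialised
  dx.attr("dim") = IntegerVector::create(H, Wd, C);
  col2im_add(dx.begin(), dcols.memptr(), H, Wd, C, k, stride, pad, Ho, Wo);
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// 2x2 max pooling, stride 2 (requires even H, W). Returns pooled tensor
// and 1-based flat winner indices for the backward pass.
// [[Rcpp::export]]
List maxpool2_fwd_cpp(const NumericVector& x) {
  IntegerVector d = tensor_dims(x);
  const int H = d[0], W = d[1], C = d[2];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector out(no_init((R_xlen_t)Ho * Wo * C));
  out.attr("dim") = IntegerVector::create(Ho, Wo, C);
  IntegerVector amax(no_init((R_xlen_t)Ho * Wo * C));
  const double* xp = x.begin();
  double* op = out.begin();
  int* ap = amax.begin();
  for (int c = 0; c < C; ++c) {
    const long xoff = (long)c * H * W;
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        double best = -HUGE_VAL;
        long bi = 0;
        for (int b = 0; b < 2; ++b) {
          for (int a = 0; a < 2; ++a) {
            const long idx = xoff + (long)(2 * j + b) * H + 2 * i + a;
            if (xp[idx] > best) { best = xp[idx]; bi = idx; }
          }
        }
        *op++ = best;
        *ap++ = (int)(bi + 1);
      }
    }
  }
  return List::create(_["out"] = out, _["argmax"] = amax);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd_cpp(const NumericVector& dout,
                               const IntegerVector& amax, int H, int W) {
  IntegerVector d = tensor_dims(dout);
  const int C = d[2];
  NumericVector dx((R_xlen_t)H * W * C);
  dx.attr("dim") = IntegerVector::create(H, W, C);
  double* xp = dx.begin();
  const double* dp = dout.begin();
  const int* ap = amax.begin();
  const R_xlen_t n = dout.size();
  for (R_xlen_t t = 0; t < n; ++t) xp[ap[t] - 1] += dp[t];
  return dx;
}

// Transpose convolution, kernel 2x2, stride 2 (exact x2 upsampling).
// W is Cin x (4*Cout); parity block t = a + 2*b (a = row offset, b = col
// offset) occupies columns [t*Cout, (t+1)*Cout).
// [[Rcpp::export]]
NumericVector tconv2_fwd_cpp(const NumericVector& x, const NumericMatrix& W,
                             const NumericVector& b) {
  IntegerVector d = tensor_dims(x);
  const int H = d[0], Wd = d[1], Cin = d[2];
  const int Co = W.ncol() / 4;
  const size_t n = (size_t)H * Wd;
  const arma::mat xm(const_cast<double*>(x.begin()), n, Cin, false);
  const arma::mat Wv(const_cast<double*>(W.begin()), Cin, 4 * Co, false);
  NumericVector out(no_init((R_xlen_t)4 * H * Wd * Co));
  out.attr("dim") = IntegerVector::create(2 * H, 2 * Wd, Co);
  double* op = out.begin();
  arma::mat ot(n, Co);
  for (int t = 0; t < 4; ++t) {
    const int a = t % 2, bb = t / 2;
    ot = xm * Wv.cols(t * Co, (t + 1) * Co - 1);
    for (int c = 0; c < Co; ++c) {
      const double bc = b[c];
      const double* sp = ot.colptr(c);
      double* oc = op + (long)c * 4 * H * Wd;
      for (int j = 0; j < Wd; ++j) {
        double* dst = oc + (long)(2 * j + bb) * 2 * H + a;
        const double* src = sp + (long)j * H;
        for (int i = 0; i < H; ++i) dst[2 * i] = src[i] + bc;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List tconv2_bwd_cpp(const NumericVector& dout, const NumericVector& x,
                    const NumericMatrix& W) {
  IntegerVector d = tensor_dims(x);
  const int H = d[0], Wd = d[1], Cin = d[2];
  const int Co = W.ncol() / 4;
  const size_t n = (size_t)H * Wd;
  const arma::mat xm(const_cast<double*>(x.begin()), n, Cin, false);
  const arma::mat Wv(const_cast<double*>(W.begin()), Cin, 4 * Co, false);
  NumericMatrix dW(Cin, 4 * Co);
  arma::mat dWv(dW.begin(), Cin, 4 * Co, false);
  NumericVector db(Co);
  NumericVector dx((R_xlen_t)H * Wd * Cin);
  dx.attr("dim") = IntegerVector::create(H, Wd, Cin);
  arma::mat dxv(dx.begin(), n, Cin, false);
  const double* dp = dout.begin();
  arma::mat dt(n, Co);
  for (int t = 0; t < 4; ++t) {
    const int a = t % 2, bb = t / 2;
    for (int c = 0; c < Co; ++c) {
      const double* sc = dp + (long)c * 4 * H * Wd;
      double* dst = dt.colptr(c);
      double acc = 0.0;
      for (int j = 0; j < Wd; ++j) {
        const double* src = sc + (long)(2 * j + bb) * 2 * H + a;
        double* dj = dst + (long)j * H;
        for (int i = 0; i < H; ++i) { dj[i] = src[2 * i]; acc += src[2 * i]; }
      }
      db[c] += acc;
    }
    dWv.cols(t * Co, (t + 1) * Co - 1) = xm.t() * dt;
    dxv += dt * Wv.cols(t * Co, (t + 1) * Co - 1).t();
  }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}
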