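#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Layout convention (column-major R arrays):
//   images / feature stacks: dim = (H, W, C, N)
//   conv kernels:            dim = (kh, kw, Cin, Cout), odd kh, kw
// Convolutions are stride-1, zero-padded "same", implemented as
// im2col + GEMM per image; pooling is 2x2 stride 2.

static inline int idx4(int h, int w, int c, int n, int H, int W, int C) {
  return h + H * (w + W * (c + C * n));
}

// Fill the im2col matrix (kh*kw*Cin rows, H*W cols) for image n.
static void im2col(const double *xp, int n, int H, int W, int C,
                   int kh, int kw, arma::mat &cols) {
  const int ph = kh / 2, pw = kw / 2;
  cols.zeros();
  for (int ci = 0; ci < C; ++ci)
    for (int dw = 0; dw < kw; ++dw)
      for (int dh = 0; dh < kh; ++dh) {
        const int row = dh + kh * (dw + kw * ci);
        for (int w = 0; w < W; ++w) {
          const int ww = w + dw - pw;
          if (ww < 0 || ww >= W) continue;
          const int h0 = std::max(0, ph - dh);
          const int h1 = std::min(H, H + ph - dh);
          const double *src = xp + idx4(h0 + dh - ph, ww, ci, n, H, W, C);
          double *dst = cols.colptr(w * H) + row + (size_t)h0 * cols.n_rows;
          for (int h = h0; h < h1; ++h) {
            *dst = *src;
            ++src;
            dst += cols.n_rows;
          }
        }
      }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector wt,
                             NumericVector bias) {
  IntegerVector xd = x.attr("dim"), wd = wt.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("channel mismatch between input and kernel");
  NumericVector out(static_cast<R_xlen_t>(H) * W * Cout * N);
  out.attr("dim") = IntegerVector::create(H, W, Cout, N);
  const arma::mat Wm(const_cast<double *>(wt.begin()), kh * kw * Cin, Cout,
                     false, true);
  const arma::rowvec bv(const_cast<double *>(bias.begin()), Cout, false,
                        true);
  arma::mat cols(kh * kw * Cin, H * W);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin(), n, H, W, C, kh, kw, cols);
    arma::mat O(out.begin() + static_cast<R_xlen_t>(n) * H * W * Cout,
                H * W, Cout, false, true);
    O = cols.t() * Wm;
    O.each_row() += bv;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector wt, NumericVector dout) {
  IntegerVector xd = x.attr("dim"), wd = wt.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  const int ph = kh / 2, pw = kw / 2;
  NumericVector dx(x.size()), dw(wt.size()), db(Cout);
  dx.attr("dim") = xd;
  dw.attr("dim") = wd;
  arma::mat dWm(dw.begin(), kh * kw * Cin, Cout, false, true);
  arma::vec dbv(db.begin(), Cout, false, true);
  const arma::mat Wm(const_cast<double *>(wt.begin()), kh * kw * Cin, Cout,
                     false, true);
  arma::mat cols(kh * kw * Cin, H * W);
  for (int n = 0; n < N; ++n) {
    const arma::mat dO(const_cast<double *>(dout.begin()) +
                           static_cast<R_xlen_t>(n) * H * W * Cout,
                       H * W, Cout, false, true);
    im2col(x.begin(), n, H, W, C, kh, kw, cols);
    dWm += cols * dO;
    dbv += arma::sum(dO, 0).t();
    arma::mat dCols = Wm * dO.t();  // (kh*kw*Cin) x (H*W)
    // col2im: scatter-add back into dx
    double *dxp = dx.begin();
    for (int ci = 0; ci < C; ++ci)
      for (int dwk = 0; dwk < kw; ++dwk)
        for (int dhk = 0; dhk < kh; ++dhk) {
          const int row = dhk + kh * (dwk + kw * ci);
          for (int w = 0; w < W; ++w) {
            const int ww = w + dwk - pw;
            if (ww < 0 || ww >= W) continue;
            const int h0 = std::max(0, ph - dhk);
            const int h1 = std::min(H, H + ph - dhk);
            double *dst = dxp + idx4(h0 + dhk - ph, ww, ci, n, H, W, C);
            const double *src =
                dCols.colptr(w * H) + row + (size_t)h0 * dCols.n_rows;
            for (int h = h0; h < h1; ++h) {
              *dst += *src;
              ++dst;
              src += dCols.n_rows;
            }
          }
        }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector out(static_cast<R_xlen_t>(Ho) * Wo * C * N);
  IntegerVector arg(out.size());
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double *xp = x.begin();
  double *op = out.begin();
  int *ap = arg.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h) {
          int best = idx4(2 * h, 2 * w, c, n, H, W, C);
          double bv = xp[best];
          for (int dw = 0; dw < 2; ++dw)
            for (int dh = 0; dh < 2; ++dh) {
              const int i = idx4(2 * h + dh, 2 * w + dw, c, n, H, W, C);
              if (xp[i] > bv) { bv = xp[i]; best = i; }
            }
          const int o = idx4(h, w, c, n, Ho, Wo, C);
          op[o] = bv;
          ap[o] = best;  // 0-based linear index into x
        }
  return List::create(_["out"] = out, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(IntegerVector arg, NumericVector dout,
                               IntegerVector xdim) {
  R_xlen_t len = 1;
  for (int k = 0; k < xdim.size(); ++k) len *= xdim[k];
  NumericVector dx(len);
  dx.attr("dim") = xdim;
  double *dxp = dx.begin();
  const double *dp = dout.begin();
  const int *ap = arg.begin();
  for (R_xlen_t i = 0; i < dout.size(); ++i) dxp[ap[i]] += dp[i];
  return dx;
}
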