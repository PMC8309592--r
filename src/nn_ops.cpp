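// Convolution and pooling kernels for the epoch decoder. Activations use
// a channels-last (H, W, B, C) layout; convolutions are im2col + GEMM per
// input channel, so row order (h, w, b) matches the R array layout and no
// transposes are needed on either side of the call.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// One channel plane (base pointer, H x W x B) -> (Hout*Wout*B) x (kh*kw),
// offset columns ordered row-fastest (di before dj), rows (h, w, b).
static arma::mat im2col_plane(const double* px, int H, int W, int B,
                              int kh, int kw) {
  const int Hout = H - kh + 1, Wout = W - kw + 1;
  arma::mat M(static_cast<arma::uword>(Hout) * Wout * B, kh * kw);
  for (int k = 0; k < kh * kw; ++k) {
    const int di = k % kh, dj = k / kh;
    double* mc = M.colptr(k);
    arma::uword r = 0;
    for (int b = 0; b < B; ++b) {
      for (int w = 0; w < Wout; ++w) {
        const double* src = px + di +
          static_cast<arma::uword>(H) * ((w + dj) + static_cast<arma::uword>(W) * b);
        std::copy(src, src + Hout, mc + r);
        r += Hout;
      }
    }
  }
  return M;
}

static arma::mat weight_mat(const NumericVector& W4, int kh, int kw,
                            int C, int F, int c) {
  arma::mat Wc(kh * kw, F);
  for (int f = 0; f < F; ++f)
    for (int dj = 0; dj < kw; ++dj)
      for (int di = 0; di < kh; ++di)
        Wc(di + kh * dj, f) =
          W4[di + static_cast<arma::uword>(kh) * (dj + static_cast<arma::uword>(kw) * (c + static_cast<arma::uword>(C) * f))];
  return Wc;
}

// [[Rcpp::export(name = "cpp_conv_fwd")]]
NumericVector cpp_conv_fwd(NumericVector X4, NumericVector W4,
                           NumericVector bias) {
  IntegerVector xd = X4.attr("dim"), wd = W4.attr("dim");
  const int H = xd[0], W = xd[1], B = xd[2], C = xd[3];
  const int kh = wd[0], kw = wd[1], F = wd[3];
  const int Hout = H - kh + 1, Wout = W - kw + 1;
  const arma::uword rows = static_cast<arma::uword>(Hout) * Wout * B;
  arma::mat Y(rows, F, arma::fill::zeros);
  const arma::uword plane = static_cast<arma::uword>(H) * W * B;
  for (int c = 0; c < C; ++c) {
    arma::mat M = im2col_plane(X4.begin() + plane * c, H, W, B, kh, kw);
    Y += M * weight_mat(W4, kh, kw, C, F, c);
  }
  for (int f = 0; f < F; ++f) Y.col(f) += bias[f];
  NumericVector out(Y.begin(), Y.end());
  out.attr("dim") = IntegerVector::create(Hout, Wout, B, F);
  return out;
}

// [[Rcpp::export(name = "cpp_conv_bwd")]]
List cpp_conv_bwd(NumericVector X4, NumericVector W4, NumericVector dY4,
                  bool compute_dx) {
  IntegerVector xd = X4.attr("dim"), wd = W4.attr("dim");
  const int H = xd[0], W = xd[1], B = xd[2], C = xd[3];
  const int kh = wd[0], kw = wd[1], F = wd[3];
  const int Hout = H - kh + 1, Wout = W - kw + 1;
  const arma::uword rows = static_cast<arma::uword>(Hout) * Wout * B;
  const arma::mat dYmat(const_cast<double*>(dY4.begin()), rows, F, false);
  const arma::uword plane = static_cast<arma::uword>(H) * W * B;

  NumericVector dW(W4.size());
  dW.attr("dim") = wd;
  NumericVector db(F);
  arma::rowvec s = arma::sum(dYmat, 0);
  for (int f = 0; f < F; ++f) db[f] = s(f);

  NumericVector dX;
  if (compute_dx) {
    dX = NumericVector(X4.size());
    dX.attr("dim") = xd;
  }
  for (int c = 0; c < C; ++c) {
    arma::mat M = im2col_plane(X4.begin() + plane * c, H, W, B, kh, kw);
    arma::mat dWc = M.t() * dYmat;   // (kh*kw) x F
    for (int f = 0; f < F; ++f)
      for (int dj = 0; dj < kw; ++dj)
        for (int di = 0; di < kh; ++di)
          dW[di + static_cast<arma::uword>(kh) * (dj + static_cast<arma::uword>(kw) * (c + static_cast<arma::uword>(C) * f))] =
            dWc(di + kh * dj, f);
    if (compute_dx) {
      arma::mat dM = dYmat * weight_mat(W4, kh, kw, C, F, c).t();
      double* dx = dX.begin() + plane * c;
      for (int k = 0; k < kh * kw; ++k) {
        const int di = k % kh, dj = k / kh;
        const double* mc = dM.colptr(k);
        arma::uword r = 0;
        for (int b = 0; b < B; ++b) {
          for (int w = 0; w < Wout; ++w) {
            double* dst = dx + di +
              static_cast<arma::uword>(H) * ((w + dj) + static_cast<arma::uword>(W) * b);
            for (int h = 0; h < Hout; ++h) dst[h] += mc[r + h];
            r += Hout;
          }
        }
      }
    }
  }
  if (compute_dx)
    return List::create(_["dW"] = dW, _["db"] = db, _["dX"] = dX);
  return List::create(_["dW"] = dW, _["db"] = db, _["dX"] = R_NilValue);
}

// 2x2 average pooling over the first two dims of (H, W, N...) where the
// trailing dims are flattened into planes; odd edges are cropped.
// [[Rcpp::export(name = "cpp_pool_fwd")]]
NumericVector cpp_pool_fwd(NumericVector X4) {
  IntegerVector xd = X4.attr("dim");
  const int H = xd[0], W = xd[1];
  int N = 1;
  for (int i = 2; i < xd.size(); ++i) N *= xd[i];
  const int Hh = H / 2, Wh = W / 2;
  NumericVector out(static_cast<R_xlen_t>(Hh) * Wh * N);
  const double* px = X4.begin();
  double* po = out.begin();
  for (int n = 0; n < N; ++n) {
    const double* p = px + static_cast<arma::uword>(H) * W * n;
    double* o = po + static_cast<arma::uword>(Hh) * Wh * n;
    for (int w = 0; w < Wh; ++w) {
      const double* c0 = p + static_cast<arma::uword>(H) * (2 * w);
      const double* c1 = c0 + H;
      double* oc = o + static_cast<arma::uword>(Hh) * w;
      for (int h = 0; h < Hh; ++h)
        oc[h] = (c0[2 * h] + c0[2 * h + 1] + c1[2 * h] + c1[2 * h + 1]) / 4.0;
    }
  }
  IntegerVector od(xd.size());
  od[0] = Hh; od[1] = Wh;
  for (int i = 2; i < xd.size(); ++i) od[i] = xd[i];
  out.attr("dim") = od;
  return out;
}

// [[Rcpp::export(name = "cpp_pool_bwd")]]
NumericVector cpp_pool_bwd(NumericVector dP4, IntegerVector Xdim) {
  IntegerVector pd = dP4.attr("dim");
  const int Hh = pd[0], Wh = pd[1];
  const int H = Xdim[0], W = Xdim[1];
  int N = 1;
  for (int i = 2; i < Xdim.size(); ++i) N *= Xdim[i];
  NumericVector dX(static_cast<R_xlen_t>(H) * W * N);
  const double* pp = dP4.begin();
  double* px = dX.begin();
  for (int n = 0; n < N; ++n) {
    const double* p = pp + static_cast<arma::uword>(Hh) * Wh * n;
    double* x = px + static_cast<arma::uword>(H) * W * n;
    for (int w = 0; w < Wh; ++w) {
      const double* pc = p + static_cast<arma::uword>(Hh) * w;
      double* c0 = x + static_cast<arma::uword>(H) * (2 * w);
      double* c1 = c0 + H;
      for (int h = 0; h < Hh; ++h) {
        const double g = pc[h] / 4.0;
        c0[2 * h] += g; c0[2 * h + 1] += g;
        c1[2 * h] += g; c1[2 * h + 1] += g;
      }
    }
  }
  dX.attr("dim") = Xdim;
  return dX;
}
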