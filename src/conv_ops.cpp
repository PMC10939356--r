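// Convolution primitives for the autodiff tape.
// Layout: images are H x W x C arma::cubes (R arrays, column-major);
// a weight matrix is Cout x (kh*kw*Cin) with the column index running
// dh fastest, then dw, then cin -- i.e. the natural flattening of an
// R array dim (kh, kw, Cin, Cout).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static mat im2col_(const cube& x, int kh, int kw, int stride) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = (H - kh) / stride + 1, Wo = (W - kw) / stride + 1;
  mat K(kh * kw * C, (uword)Ho * Wo);
  for (int c = 0; c < C; ++c)
    for (int dw = 0; dw < kw; ++dw)
      for (int dh = 0; dh < kh; ++dh) {
        const int r = dh + kh * (dw + kw * c);
        for (int wo = 0; wo < Wo; ++wo)
          for (int ho = 0; ho < Ho; ++ho)
            K(r, ho + (uword)Ho * wo) = x(ho * stride + dh, wo * stride + dw, c);
      }
  return K;
}

static void col2im_(const mat& dK, cube& dx, int kh, int kw, int stride) {
  const int H = dx.n_rows, W = dx.n_cols, C = dx.n_slices;
  const int Ho = (H - kh) / stride + 1, Wo = (W - kw) / stride + 1;
  for (int c = 0; c < C; ++c)
    for (int dw = 0; dw < kw; ++dw)
      for (int dh = 0; dh < kh; ++dh) {
        const int r = dh + kh * (dw + kw * c);
        for (int wo = 0; wo < Wo; ++wo)
          for (int ho = 0; ho < Ho; ++ho)
            dx(ho * stride + dh, wo * stride + dw, c) += dK(r, ho + (uword)Ho * wo);
      }
}

// [[Rcpp::export]]
arma::cube cpp_conv2d(const arma::cube& x, const arma::mat& wmat,
                      const arma::vec& bias, int kh, int kw, int stride) {
  const int H = x.n_rows, W = x.n_cols;
  const int Ho = (H - kh) / stride + 1, Wo = (W - kw) / stride + 1;
  const int Cout = wmat.n_rows;
  mat K = im2col_(x, kh, kw, stride);
  mat O = wmat * K;            // Cout x (Ho*Wo)
  O.each_col() += bias;
  cube out(Ho, Wo, Cout);
  for (int co = 0; co < Cout; ++co)
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho)
        out(ho, wo, co) = O(co, ho + (uword)Ho * wo);
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv2d_backward(const arma::cube& x, const arma::mat& wmat,
                               const arma::cube& gout, int kh, int kw, int stride) {
  const int Ho = gout.n_rows, Wo = gout.n_cols, Cout = gout.n_slices;
  mat Og(Cout, (uword)Ho * Wo);
  for (int co = 0; co < Cout; ++co)
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho)
        Og(co, ho + (uword)Ho * wo) = gout(ho, wo, co);
  mat K = im2col_(x, kh, kw, stride);
  mat dw = Og * K.t();
  vec db = sum(Og, 1);
  mat dK = wmat.t() * Og;
  cube dx(x.n_rows, x.n_cols, x.n_slices, fill::zeros);
  col2im_(dK, dx, kh, kw, stride);
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dw") = dw,
                            Rcpp::Named("db") = db);
}
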