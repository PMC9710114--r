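// Dilated 1-D temporal convolution kernels (forward and backward).
//
// A sequence is a T x C matrix (one row per frame).  The convolution is a
// sum over kernel taps of shifted input blocks times per-tap weight
// matrices; causal mode left-pads with zeros so frame t depends only on
// frames <= t.  These kernels carry the training loops' hot path.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat pad_input(const mat& x, int span, int pad_l) {
  mat xp(x.n_rows + span, x.n_cols, fill::zeros);
  xp.rows(pad_l, pad_l + x.n_rows - 1) = x;
  return xp;
}

// weights arrive as a (K * Cin) x Cout matrix: tap-major blocks of rows
// [[Rcpp::export]]
arma::mat conv1d_fwd_cpp(const arma::mat& x, const arma::mat& w,
                         const arma::vec& b, int kernel, int dilation,
                         bool causal) {
  const int T = x.n_rows, cin = x.n_cols, cout = w.n_cols;
  const int span = (kernel - 1) * dilation;
  const int pad_l = causal ? span : span / 2;
  mat xp = pad_input(x, span, pad_l);
  mat out(T, cout);
  out.each_row() = b.t();
  for (int k = 0; k < kernel; ++k) {
    const int off = k * dilation;
    out += xp.rows(off, off + T - 1) * w.rows(k * cin, (k + 1) * cin - 1);
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List conv1d_bwd_cpp(const arma::mat& x, const arma::mat& w,
                          const arma::mat& dy, int kernel, int dilation,
                          bool causal) {
  const int T = x.n_rows, cin = x.n_cols;
  const int span = (kernel - 1) * dilation;
  const int pad_l = causal ? span : span / 2;
  mat xp = pad_input(x, span, pad_l);
  mat dw(kernel * cin, w.n_cols);
  mat dxp(xp.n_rows, cin, fill::zeros);
  for (int k = 0; k < kernel; ++k) {
    const int off = k * dilation;
    dw.rows(k * cin, (k + 1) * cin - 1) = xp.rows(off, off + T - 1).t() * dy;
    dxp.rows(off, off + T - 1) += dy * w.rows(k * cin, (k + 1) * cin - 1).t();
  }
  return Rcpp::List::create(
      Rcpp::Named("dX") = dxp.rows(pad_l, pad_l + T - 1),
      Rcpp::Named("dW") = dw,
      Rcpp::Named("db") = sum(dy, 0).t());
}

// Per-frame layer normalization over channels, fused with the affine map.
// [[Rcpp::export]]
Rcpp::List layernorm_fwd_cpp(const arma::mat& x, const arma::vec& gamma,
                             const arma::vec& beta, double eps) {
  vec mu = mean(x, 1);
  mat xc = x.each_col() - mu;
  vec inv = 1.0 / sqrt(mean(square(xc), 1) + eps);
  mat xhat = xc.each_col() % inv;
  mat out = xhat.each_row() % gamma.t();
  out.each_row() += beta.t();
  return Rcpp::List::create(Rcpp::Named("out") = out,
                            Rcpp::Named("xhat") = xhat,
                            Rcpp::Named("inv") = inv);
}

// [[Rcpp::export]]
Rcpp::List layernorm_bwd_cpp(const arma::mat& xhat, const arma::vec& inv,
                             const arma::vec& gamma, const arma::mat& dy) {
  mat dxhat = dy.each_row() % gamma.t();
  vec m1 = mean(dxhat, 1);
  vec m2 = mean(dxhat % xhat, 1);
  mat dx = (dxhat.each_col() - m1) - (xhat.each_col() % m2);
  dx.each_col() %= inv;
  return Rcpp::List::create(
      Rcpp::Named("dX") = dx,
      Rcpp::Named("dgamma") = sum(dy % xhat, 0).t(),
      Rcpp::Named("dbeta") = sum(dy, 0).t());
}
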