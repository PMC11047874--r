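// Minimal 1-D convolution engine used by the generator/discriminator/TCN
// code.  Layout conventions:
//   signals: arma::cube (channels x time x batch)
//   conv weight: arma::mat (c_out x c_in*K), column-block k holds the taps at
//     kernel offset k for all input channels (k-major, channel-minor), which
//     matches the im2col row layout below.
// A transposed convolution with stride s is implemented as the adjoint of a
// strided convolution over the same geometry, so the up-sampling path of the
// generator exactly mirrors the down-sampling path.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline int conv_out_len(int T, int K, int s, int d, int pl, int pr) {
  int span = (K - 1) * d + 1;
  int num = T + pl + pr - span;
  if (num < 0) return 0;
  return num / s + 1;
}

// (C*K) x Tout patch matrix; out-of-range samples are zero (zero padding)
static mat im2col(const mat& x, int K, int s, int d, int pl, int Tout) {
  const int C = x.n_rows;
  const int T = x.n_cols;
  mat cols(C * K, Tout, fill::zeros);
  for (int k = 0; k < K; ++k) {
    const int off = k * d - pl;
    for (int j = 0; j < Tout; ++j) {
      const int t = j * s + off;
      if (t >= 0 && t < T)
        cols.submat(k * C, j, (k + 1) * C - 1, j) = x.col(t);
    }
  }
  return cols;
}

// adjoint of im2col: scatter-add patch columns back onto the time axis
static void col2im_add(mat& gx, const mat& cols, int K, int s, int d, int pl) {
  const int C = gx.n_rows;
  const int T = gx.n_cols;
  const int Tout = cols.n_cols;
  for (int k = 0; k < K; ++k) {
    const int off = k * d - pl;
    for (int j = 0; j < Tout; ++j) {
      const int t = j * s + off;
      if (t >= 0 && t < T)
        gx.col(t) += cols.submat(k * C, j, (k + 1) * C - 1, j);
    }
  }
}

// [[Rcpp::export(rng = false)]]
arma::cube nn_conv_fwd(const arma::cube& x, const arma::mat& W,
                       const arma::vec& b, int K, int s, int d,
                       int pl, int pr) {
  const int Tout = conv_out_len(x.n_cols, K, s, d, pl, pr);
  const int Cout = W.n_rows;
  cube y(Cout, Tout, x.n_slices);
  for (uword i = 0; i < x.n_slices; ++i) {
    mat cols = im2col(x.slice(i), K, s, d, pl, Tout);
    y.slice(i) = W * cols;
    y.slice(i).each_col() += b;
  }
  return y;
}

// [[Rcpp::export(rng = false)]]
Rcpp::List nn_conv_bwd(const arma::cube& x, const arma::mat& W,
                       const arma::cube& gy, int K, int s, int d,
                       int pl, int pr) {
  const int Tout = gy.n_cols;
  cube gx(x.n_rows, x.n_cols, x.n_slices, fill::zeros);
  mat gW(W.n_rows, W.n_cols, fill::zeros);
  vec gb(W.n_rows, fill::zeros);
  for (uword i = 0; i < x.n_slices; ++i) {
    mat cols = im2col(x.slice(i), K, s, d, pl, Tout);
    gW += gy.slice(i) * cols.t();
    gb += sum(gy.slice(i), 1);
    mat gcols = W.t() * gy.slice(i);
    col2im_add(gx.slice(i), gcols, K, s, d, pl);
  }
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gW") = gW,
                            Rcpp::Named("gb") = gb);
}

// Transposed convolution: x lives on the short (strided) grid, output on the
// long grid.  W is the weight of the adjoint convolution (long -> short):
// (c_short x c_long*K).  Output length Tout must satisfy
// conv_out_len(Tout) == T(x).
// [[Rcpp::export(rng = false)]]
arma::cube nn_tconv_fwd(const arma::cube& x, const arma::mat& W,
                        const arma::vec& b, int K, int s, int d,
                        int pl, int Tout) {
  const int Clong = W.n_cols / K;
  cube y(Clong, Tout, x.n_slices, fill::zeros);
  for (uword i = 0; i < x.n_slices; ++i) {
    mat gcols = W.t() * x.slice(i);      // (Clong*K) x Ts
    col2im_add(y.slice(i), gcols, K, s, d, pl);
    y.slice(i).each_col() += b;
  }
  return y;
}

// [[Rcpp::export(rng = false)]]
Rcpp::List nn_tconv_bwd(const arma::cube& x, const arma::mat& W,
                        const arma::cube& gy, int K, int s, int d, int pl) {
  const int Ts = x.n_cols;
  cube gx(x.n_rows, Ts, x.n_slices);
  mat gW(W.n_rows, W.n_cols, fill::zeros);
  vec gb(gy.n_rows, fill::zeros);
  for (uword i = 0; i < x.n_slices; ++i) {
    mat cols = im2col(gy.slice(i), K, s, d, pl, Ts);
    gx.slice(i) = W * cols;
    gW += x.slice(i) * cols.t();
    gb += sum(gy.slice(i), 1);
  }
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gW") = gW,
                            Rcpp::Named("gb") = gb);
}
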