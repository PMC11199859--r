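// 1D convolution ('same' zero padding, stride 1, odd kernel) on batches of
// multichannel windows, as im2col + one BLAS product. Tensors are arma
// cubes laid out channels x time x batch. The im2col matrix stays internal
// to each call; the backward pass rebuilds it from the saved input, which
// is cheaper than shuttling it through R.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline void shift_ranges(uword j, uword T, uword p,
                                uword& t0, uword& t1, uword& s0, bool& any) {
  // output positions t whose source t + j - p falls inside [0, T-1]
  long lo = (long)p - (long)j;
  long hi = (long)T - 1 + (long)p - (long)j;
  long a = lo > 0 ? lo : 0;
  long b = hi < (long)(T - 1) ? hi : (long)(T - 1);
  any = b >= a;
  if (!any) return;
  t0 = (uword)a;
  t1 = (uword)b;
  s0 = (uword)(a + (long)j - (long)p);
}

static mat build_xcol(const cube& x, uword k, uword p) {
  const uword C_in = x.n_rows, T = x.n_cols, N = x.n_slices;
  mat Xcol(C_in * k, T * N, fill::zeros);
  for (uword n = 0; n < N; ++n) {
    const mat& xs = x.slice(n);
    for (uword j = 0; j < k; ++j) {
      uword t0, t1, s0; bool any;
      shift_ranges(j, T, p, t0, t1, s0, any);
      if (!any) continue;
      Xcol.submat(j * C_in, n * T + t0, (j + 1) * C_in - 1, n * T + t1)
        = xs.cols(s0, s0 + (t1 - t0));
    }
  }
  return Xcol;
}

// [[Rcpp::export]]
arma::cube conv1d_forward(const arma::cube& x, const arma::cube& W,
                          const arma::vec& b) {
  const uword T = x.n_cols, N = x.n_slices;
  const uword C_in = x.n_rows, C_out = W.n_rows, k = W.n_slices;
  const uword p = (k - 1) / 2;
  const mat Wmat(const_cast<double*>(W.memptr()), C_out, C_in * k, false, true);
  mat out = Wmat * build_xcol(x, k, p);
  out.each_col() += b;
  return cube(out.memptr(), C_out, T, N);
}

// [[Rcpp::export]]
Rcpp::List conv1d_backward(const arma::cube& dy, const arma::cube& x,
                           const arma::cube& W) {
  const uword C_out = dy.n_rows, T = dy.n_cols, N = dy.n_slices;
  const uword C_in = W.n_cols, k = W.n_slices;
  const uword p = (k - 1) / 2;
  const mat dy_mat(const_cast<double*>(dy.memptr()), C_out, T * N, false, true);
  const mat Wmat(const_cast<double*>(W.memptr()), C_out, C_in * k, false, true);
  vec db = sum(dy_mat, 1);
  mat Xcol = build_xcol(x, k, p);
  mat dWmat = dy_mat * Xcol.t();
  cube dW(dWmat.memptr(), C_out, C_in, k);
  mat dXcol = Wmat.t() * dy_mat;
  cube dx(C_in, T, N, fill::zeros);
  for (uword n = 0; n < N; ++n) {
    mat& dxs = dx.slice(n);
    for (uword j = 0; j < k; ++j) {
      uword t0, t1, s0; bool any;
      shift_ranges(j, T, p, t0, t1, s0, any);
      if (!any) continue;
      dxs.cols(s0, s0 + (t1 - t0))
        += dXcol.submat(j * C_in, n * T + t0, (j + 1) * C_in - 1, n * T + t1);
    }
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}
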