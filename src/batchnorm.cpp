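// Channel-wise batch normalization on (channels x time x batch) cubes,
// with statistics over the time and batch axes.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using Rcpp::List;
using Rcpp::Named;

// [[Rcpp::export]]
List bn1d_forward_cpp(const arma::cube& x, const arma::vec& gamma,
                      const arma::vec& beta, const arma::vec& run_mean,
                      const arma::vec& run_var, bool training,
                      double momentum, double eps) {
  const uword C = x.n_rows, m = x.n_cols * x.n_slices;
  const mat xm(const_cast<double*>(x.memptr()), C, m, false, true);
  vec mu, v, new_mean = run_mean, new_var = run_var;
  if (training) {
    mu = mean(xm, 1);
    v = mean(square(xm.each_col() - mu), 1);
    const double corr = m > 1 ? (double)m / (m - 1) : 1.0;
    new_mean = (1 - momentum) * run_mean + momentum * mu;
    new_var = (1 - momentum) * run_var + momentum * v * corr;
  } else {
    mu = run_mean;
    v = run_var;
  }
  vec inv_std = 1.0 / sqrt(v + eps);
  mat xhat = xm.each_col() - mu;
  xhat.each_col() %= inv_std;
  mat y = xhat.each_col() % gamma;
  y.each_col() += beta;
  cube out(y.memptr(), C, x.n_cols, x.n_slices);
  return List::create(Named("out") = out, Named("xhat") = xhat,
                      Named("inv_std") = inv_std,
                      Named("mean") = new_mean, Named("var") = new_var);
}

// [[Rcpp::export]]
List bn1d_backward_cpp(const arma::cube& dy, const arma::mat& xhat,
                       const arma::vec& inv_std, const arma::vec& gamma,
                       bool training) {
  const uword C = dy.n_rows, m = dy.n_cols * dy.n_slices;
  const mat dym(const_cast<double*>(dy.memptr()), C, m, false, true);
  vec dgamma = sum(dym % xhat, 1);
  vec dbeta = sum(dym, 1);
  mat dxhat = dym.each_col() % gamma;
  mat dxm;
  if (training) {
    vec s1 = sum(dxhat, 1);
    vec s2 = sum(dxhat % xhat, 1);
    dxm = dxhat * (double)m;
    dxm.each_col() -= s1;
    dxm -= xhat.each_col() % s2;
    dxm.each_col() %= inv_std / (double)m;
  } else {
    dxm = dxhat.each_col() % inv_std;
  }
  cube dx(dxm.memptr(), C, dy.n_cols, dy.n_slices);
  return List::create(Named("dx") = dx, Named("dgamma") = dgamma,
                      Named("dbeta") = dbeta);
}
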