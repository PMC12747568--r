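// Batched scaled dot-product self-attention kernels. X is a cube whose
// slice n is the T x d sequence of window n. With proj = true the learned
// projections Q = X Wq, K = X Wk, V = X Wv are applied (scaling by
// sqrt(d)); with proj = false the projection-free form Q = K = V = X is
// used. Backward recomputes Q/K/V from X (cheap) instead of caching them.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline void softmax_rows_inplace(mat& S) {
  S.each_col() -= max(S, 1);
  S = exp(S);
  S.each_col() /= sum(S, 1);
}

// [[Rcpp::export]]
Rcpp::List self_attn_forward_cpp(const arma::cube& X, const arma::mat& Wq,
                                 const arma::mat& Wk, const arma::mat& Wv,
                                 bool proj) {
  const uword T = X.n_rows, d = X.n_cols, N = X.n_slices;
  const double s = std::sqrt((double)d);
  cube O(T, d, N), A(T, T, N);
  for (uword n = 0; n < N; ++n) {
    const mat& Xn = X.slice(n);
    mat S;
    if (proj) S = (Xn * Wq) * (Xn * Wk).t() / s;
    else S = Xn * Xn.t() / s;
    softmax_rows_inplace(S);
    O.slice(n) = proj ? mat(S * (Xn * Wv)) : mat(S * Xn);
    A.slice(n) = S;
  }
  return Rcpp::List::create(Rcpp::Named("O") = O, Rcpp::Named("A") = A);
}

// [[Rcpp::export]]
Rcpp::List self_attn_backward_cpp(const arma::cube& X, const arma::mat& Wq,
                                  const arma::mat& Wk, const arma::mat& Wv,
                                  const arma::cube& A, const arma::cube& dO,
                                  bool proj) {
  const uword T = X.n_rows, d = X.n_cols, N = X.n_slices;
  const double s = std::sqrt((double)d);
  cube dX(T, d, N, fill::zeros);
  mat dWq(d, d, fill::zeros), dWk(d, d, fill::zeros), dWv(d, d, fill::zeros);
  for (uword n = 0; n < N; ++n) {
    const mat& Xn = X.slice(n);
    const mat& An = A.slice(n);
    const mat& dOn = dO.slice(n);
    mat Q = proj ? mat(Xn * Wq) : Xn;
    mat K = proj ? mat(Xn * Wk) : Xn;
    mat V = proj ? mat(Xn * Wv) : Xn;
    mat dV = An.t() * dOn;
    mat dA = dOn * V.t();
    vec rs = sum(An % dA, 1);
    dA.each_col() -= rs;
    mat dS = (An % dA) / s;
    mat dQ = dS * K;
    mat dK = dS.t() * Q;
    if (proj) {
      dWq += Xn.t() * dQ;
      dWk += Xn.t() * dK;
      dWv += Xn.t() * dV;
      dX.slice(n) = dQ * Wq.t() + dK * Wk.t() + dV * Wv.t();
    } else {
      dX.slice(n) = dQ + dK + dV;
    }
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX, Rcpp::Named("dWq") = dWq,
                            Rcpp::Named("dWk") = dWk,
                            Rcpp::Named("dWv") = dWv);
}
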