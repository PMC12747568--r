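// LSTM forward and backward (BPTT) kernels over a batch of sequences.
// X is a cube with slice t = the N x C input matrix at timestep t (1..T).
// Gates follow the standard cell: z = [i f g o], c_t = f.c_{t-1} + i.g,
// h_t = o.tanh(c_t). The input projection X Wx is hoisted out of the
// recurrence into one large GEMM over all timesteps; only the hidden
// projection stays inside the time loop. Direction reversal is handled by
// the R caller by flipping the time axis, so these kernels are
// forward-time only.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// flatten a (N, C, T) cube into a (N*T, C) matrix, timestep-major blocks
static mat flatten_time(const cube& X) {
  const uword N = X.n_rows, C = X.n_cols, T = X.n_slices;
  mat out(N * T, C);
  for (uword t = 0; t < T; ++t) out.rows(t * N, (t + 1) * N - 1) = X.slice(t);
  return out;
}

// [[Rcpp::export]]
Rcpp::List lstm_forward_cpp(const arma::cube& X, const arma::mat& Wx,
                            const arma::mat& Wh, const arma::rowvec& b) {
  const uword N = X.n_rows, T = X.n_slices;
  const uword H = Wh.n_rows;
  cube Hs(N, H, T), Cs(N, H, T), I(N, H, T), F(N, H, T), G(N, H, T),
      O(N, H, T), TC(N, H, T);
  mat Zx = flatten_time(X) * Wx;                 // (N*T, 4H), one GEMM
  Zx.each_row() += b;
  mat h_prev(N, H, fill::zeros), c_prev(N, H, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    mat Z = Zx.rows(t * N, (t + 1) * N - 1) + h_prev * Wh;
    mat i = sigm(Z.cols(0, H - 1));
    mat f = sigm(Z.cols(H, 2 * H - 1));
    mat g = tanh(Z.cols(2 * H, 3 * H - 1));
    mat o = sigm(Z.cols(3 * H, 4 * H - 1));
    mat c = f % c_prev + i % g;
    mat tc = tanh(c);
    mat h = o % tc;
    I.slice(t) = i; F.slice(t) = f; G.slice(t) = g; O.slice(t) = o;
    Cs.slice(t) = c; TC.slice(t) = tc; Hs.slice(t) = h;
    h_prev = h; c_prev = c;
  }
  return Rcpp::List::create(
      Rcpp::Named("H") = Hs, Rcpp::Named("C") = Cs, Rcpp::Named("I") = I,
      Rcpp::Named("F") = F, Rcpp::Named("G") = G, Rcpp::Named("O") = O,
      Rcpp::Named("TC") = TC);
}

// [[Rcpp::export]]
Rcpp::List lstm_backward_cpp(const arma::cube& X, const arma::mat& Wx,
                             const arma::mat& Wh, const arma::cube& Hs,
                             const arma::cube& Cs, const arma::cube& I,
                             const arma::cube& F, const arma::cube& G,
                             const arma::cube& O, const arma::cube& TC,
                             const arma::cube& dH) {
  const uword N = X.n_rows, C = X.n_cols, T = X.n_slices;
  const uword Hn = Wh.n_rows;
  mat dWh(Hn, 4 * Hn, fill::zeros);
  rowvec db(4 * Hn, fill::zeros);
  mat dZ_all(N * T, 4 * Hn);
  mat dh_next(N, Hn, fill::zeros), dc_next(N, Hn, fill::zeros);
  for (uword tt = T; tt-- > 0;) {
    mat dh = dH.slice(tt) + dh_next;
    const mat& i = I.slice(tt); const mat& f = F.slice(tt);
    const mat& g = G.slice(tt); const mat& o = O.slice(tt);
    const mat& tc = TC.slice(tt);
    mat c_prev = (tt == 0) ? mat(N, Hn, fill::zeros) : Cs.slice(tt - 1);
    mat h_prev = (tt == 0) ? mat(N, Hn, fill::zeros) : Hs.slice(tt - 1);
    mat dc = dc_next + dh % o % (1.0 - tc % tc);
    mat dZ(N, 4 * Hn);
    dZ.cols(0, Hn - 1) = (dc % g) % i % (1.0 - i);
    dZ.cols(Hn, 2 * Hn - 1) = (dc % c_prev) % f % (1.0 - f);
    dZ.cols(2 * Hn, 3 * Hn - 1) = (dc % i) % (1.0 - g % g);
    dZ.cols(3 * Hn, 4 * Hn - 1) = (dh % tc) % o % (1.0 - o);
    dZ_all.rows(tt * N, (tt + 1) * N - 1) = dZ;
    dWh += h_prev.t() * dZ;
    db += sum(dZ, 0);
    dh_next = dZ * Wh.t();
    dc_next = dc % f;
  }
  mat dX_flat = dZ_all * Wx.t();                 // (N*T, C), one GEMM
  mat dWx = flatten_time(X).t() * dZ_all;        // (C, 4H), one GEMM
  cube dX(N, C, T);
  for (uword t = 0; t < T; ++t)
    dX.slice(t) = dX_flat.rows(t * N, (t + 1) * N - 1);
  return Rcpp::List::create(Rcpp::Named("dX") = dX, Rcpp::Named("dWx") = dWx,
                            Rcpp::Named("dWh") = dWh, Rcpp::Named("db") = db);
}
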