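// 1-D cross-correlation kernels with "same" zero padding, batched over the
// third cube dimension. These are the only compute-heavy primitives of the
// CNN decoders; everything else (pooling, activations, dense heads, the
// optimizers) is plain R. Layout: activations are (time, maps, batch) cubes,
// weights are (kernel, in_maps, out_maps) cubes.
//
// y[t, o] = b[o] + sum_i sum_u x[t + u - pad, i] * w[u, i, o],  pad = (k-1)/2
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// [[Rcpp::export]]
arma::cube cc_conv1d_fw(const arma::cube& X, const arma::cube& W,
                        const arma::vec& b) {
  const uword T = X.n_rows, Cin = X.n_cols, N = X.n_slices;
  const uword k = W.n_rows, Cout = W.n_slices;
  const int pad = ((int)k - 1) / 2;
  cube Y(T, Cout, N, fill::zeros);
  for (uword n = 0; n < N; ++n) {
    const mat& Xn = X.slice(n);
    mat& Yn = Y.slice(n);
    for (uword o = 0; o < Cout; ++o) {
      vec acc(T, fill::zeros);
      for (uword i = 0; i < Cin; ++i) {
        const vec& x = Xn.unsafe_col(i);
        for (uword u = 0; u < k; ++u) {
          const double w = W(u, i, o);
          if (w == 0.0) continue;
          const int off = (int)u - pad;  // x index = t + off
          const int lo = std::max(0, -off);
          const int hi = std::min((int)T - 1, (int)T - 1 - off);
          if (lo > hi) continue;
          acc.subvec(lo, hi) += w * x.subvec(lo + off, hi + off);
        }
      }
      Yn.col(o) = acc + b(o);
    }
  }
  return Y;
}

// [[Rcpp::export]]
Rcpp::List cc_conv1d_bw(const arma::cube& X, const arma::cube& W,
                        const arma::cube& G, const bool need_dx) {
  const uword T = X.n_rows, Cin = X.n_cols, N = X.n_slices;
  const uword k = W.n_rows, Cout = W.n_slices;
  const int pad = ((int)k - 1) / 2;
  cube dX;
  if (need_dx) dX.zeros(T, Cin, N);
  cube dW(k, Cin, Cout, fill::zeros);
  vec db(Cout, fill::zeros);
  for (uword n = 0; n < N; ++n) {
    const mat& Xn = X.slice(n);
    const mat& Gn = G.slice(n);
    for (uword o = 0; o < Cout; ++o) {
      const vec& g = Gn.unsafe_col(o);
      db(o) += accu(g);
      for (uword i = 0; i < Cin; ++i) {
        const vec& x = Xn.unsafe_col(i);
        for (uword u = 0; u < k; ++u) {
          const int off = (int)u - pad;
          const int lo = std::max(0, -off);
          const int hi = std::min((int)T - 1, (int)T - 1 - off);
          if (lo > hi) continue;
          dW(u, i, o) += dot(g.subvec(lo, hi), x.subvec(lo + off, hi + off));
          if (need_dx) {
            const double w = W(u, i, o);
            if (w != 0.0)
              dX.slice(n).col(i).subvec(lo + off, hi + off) +=
                  w * g.subvec(lo, hi);
          }
        }
      }
    }
  }
  if (need_dx)
    return Rcpp::List::create(Rcpp::Named("dX") = dX, Rcpp::Named("dW") = dW,
                              Rcpp::Named("db") = db);
  return Rcpp::List::create(Rcpp::Named("dW") = dW, Rcpp::Named("db") = db);
}

// Depthwise temporal convolution: one kernel per map, no cross-map mixing.
// X: (T, M, N); W: (k, M). y[t, m] = sum_u x[t + u - pad, m] * w[u, m]
// [[Rcpp::export]]
arma::cube cc_dwconv1d_fw(const arma::cube& X, const arma::mat& W) {
  const uword T = X.n_rows, M = X.n_cols, N = X.n_slices;
  const uword k = W.n_rows;
  const int pad = ((int)k - 1) / 2;
  cube Y(T, M, N, fill::zeros);
  for (uword n = 0; n < N; ++n) {
    const mat& Xn = X.slice(n);
    mat& Yn = Y.slice(n);
    for (uword m = 0; m < M; ++m) {
      const vec& x = Xn.unsafe_col(m);
      vec acc(T, fill::zeros);
      for (uword u = 0; u < k; ++u) {
        const double w = W(u, m);
        if (w == 0.0) continue;
        const int off = (int)u - pad;
        const int lo = std::max(0, -off);
        const int hi = std::min((int)T - 1, (int)T - 1 - off);
        if (lo > hi) continue;
        acc.subvec(lo, hi) += w * x.subvec(lo + off, hi + off);
      }
      Yn.col(m) = acc;
    }
  }
  return Y;
}

// [[Rcpp::export]]
Rcpp::List cc_dwconv1d_bw(const arma::cube& X, const arma::mat& W,
                          const arma::cube& G) {
  const uword T = X.n_rows, M = X.n_cols, N = X.n_slices;
  const uword k = W.n_rows;
  const int pad = ((int)k - 1) / 2;
  cube dX(T, M, N, fill::zeros);
  mat dW(k, M, fill::zeros);
  for (uword n = 0; n < N; ++n) {
    const mat& Xn = X.slice(n);
    const mat& Gn = G.slice(n);
    for (uword m = 0; m < M; ++m) {
      const vec& x = Xn.unsafe_col(m);
      const vec& g = Gn.unsafe_col(m);
      for (uword u = 0; u < k; ++u) {
        const int off = (int)u - pad;
        const int lo = std::max(0, -off);
        const int hi = std::min((int)T - 1, (int)T - 1 - off);
        if (lo > hi) continue;
        dW(u, m) += dot(g.subvec(lo, hi), x.subvec(lo + off, hi + off));
        const double w = W(u, m);
        if (w != 0.0)
          dX.slice(n).col(m).subvec(lo + off, hi + off) += w * g.subvec(lo, hi);
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX, Rcpp::Named("dW") = dW);
}

// Fast path for the electrode-shared temporal convolution (single input
// map): X is a (T, S) matrix whose columns are independent series (channel
// within trial), W is (k, F). Forward returns a (T, S, F) cube.
// [[Rcpp::export]]
arma::cube cc_tconv1d_fw(const arma::mat& X, const arma::mat& W,
                         const arma::vec& b) {
  const uword T = X.n_rows, S = X.n_cols;
  const uword k = W.n_rows, F = W.n_cols;
  const int pad = ((int)k - 1) / 2;
  cube Y(T, S, F);
  for (uword f = 0; f < F; ++f) {
    mat acc(T, S, fill::zeros);
    for (uword u = 0; u < k; ++u) {
      const double w = W(u, f);
      if (w == 0.0) continue;
      const int off = (int)u - pad;
      const int lo = std::max(0, -off);
      const int hi = std::min((int)T - 1, (int)T - 1 - off);
      if (lo > hi) continue;
      acc.rows(lo, hi) += w * X.rows(lo + off, hi + off);
    }
    Y.slice(f) = acc + b(f);
  }
  return Y;
}

// [[Rcpp::export]]
Rcpp::List cc_tconv1d_bw(const arma::mat& X, const arma::mat& W,
                         const arma::cube& G, const bool need_dx) {
  const uword T = X.n_rows, S = X.n_cols;
  const uword k = W.n_rows, F = W.n_cols;
  const int pad = ((int)k - 1) / 2;
  mat dW(k, F, fill::zeros);
  vec db(F, fill::zeros);
  mat dX;
  if (need_dx) dX.zeros(T, S);
  for (uword f = 0; f < F; ++f) {
    const mat& g = G.slice(f);
    db(f) = accu(g);
    for (uword u = 0; u < k; ++u) {
      const int off = (int)u - pad;
      const int lo = std::max(0, -off);
      const int hi = std::min((int)T - 1, (int)T - 1 - off);
      if (lo > hi) continue;
      dW(u, f) = accu(g.rows(lo, hi) % X.rows(lo + off, hi + off));
      if (need_dx) {
        const double w = W(u, f);
        if (w != 0.0) dX.rows(lo + off, hi + off) += w * g.rows(lo, hi);
      }
    }
  }
  if (need_dx)
    return Rcpp::List::create(Rcpp::Named("dX") = dX, Rcpp::Named("dW") = dW,
                              Rcpp::Named("db") = db);
  return Rcpp::List::create(Rcpp::Named("dW") = dW, Rcpp::Named("db") = db);
}
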