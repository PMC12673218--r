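// Fused forward/backward for the EEGNet-style decoder. Activations are kept
// in memory layouts where the innermost (column-major fastest) index runs
// over maps/channels and batch, and time runs over columns, so every
// temporal-convolution step touches contiguous memory:
//   Xs   : (C*N, T)        input, channel fastest within trial
//   A1   : (C*N, T, F1)    temporal conv maps
//   a2   : (F2, N*T)  ==  (F2*N, T) reinterpreted
//   P1   : (F2*N, T1)      pooled + dropout
//   dw   : (F2*N, T1)      depthwise separable stage
//   a3   : (F3, N*T1) ==  (F3*N, T1)
//   P2   : (F3*N, T2)
// The dense weights W4 are indexed (f + F3*t, class), feature fastest.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline void elu_inplace(mat& x) {
  for (uword i = 0; i < x.n_elem; ++i) {
    if (x[i] < 0) x[i] = std::exp(x[i]) - 1.0;
  }
}

// [[Rcpp::export]]
Rcpp::List eegnet_fw_cpp(const arma::mat& Xs, const int C, const int N,
                         const arma::mat& W1, const arma::vec& b1,
                         const arma::mat& W2, const arma::vec& b2,
                         const int D, const arma::mat& W3d,
                         const arma::mat& W3p, const arma::vec& b3,
                         const arma::mat& W4, const arma::vec& b4,
                         const int p1, const int p2,
                         const arma::mat& drop1, const arma::mat& drop2) {
  const int T = Xs.n_cols;
  const int k1 = W1.n_rows, F1 = W1.n_cols;
  const int F2 = W2.n_cols, F3 = W3p.n_cols;
  const int k3 = W3d.n_rows;
  const int T1 = T / p1, T2 = T1 / p2;
  const int ncls = W4.n_cols;
  const int pad1 = (k1 - 1) / 2, pad3 = (k3 - 1) / 2;

  // temporal conv shared over channels
  cube A1(C * N, T, F1);
  for (int f = 0; f < F1; ++f) {
    mat& acc = A1.slice(f);
    acc.fill(b1(f));
    for (int u = 0; u < k1; ++u) {
      const double w = W1(u, f);
      if (w == 0.0) continue;
      const int off = u - pad1;
      const int lo = std::max(0, -off);
      const int hi = std::min(T - 1, T - 1 - off);
      if (lo > hi) continue;
      acc.cols(lo, hi) += w * Xs.cols(lo + off, hi + off);
    }
  }

  // depthwise spatial conv across channels: (F2, N*T)
  mat out2pre(F2, (size_t)N * T);
  for (int f = 0; f < F1; ++f) {
    const mat Afv(const_cast<double*>(A1.slice(f).memptr()), C,
                  (size_t)N * T, false, true);
    out2pre.rows(f * D, f * D + D - 1) =
        W2.cols(f * D, f * D + D - 1).t() * Afv;
  }
  out2pre.each_col() += b2;
  mat a2 = out2pre;
  elu_inplace(a2);

  // average pool along time, then dropout: (F2*N, T1)
  const mat a2t(a2.memptr(), (size_t)F2 * N, T, false, true);
  mat P1((size_t)F2 * N, T1);
  for (int j = 0; j < T1; ++j) {
    P1.col(j) = a2t.col(j * p1);
    for (int u = 1; u < p1; ++u) P1.col(j) += a2t.col(j * p1 + u);
  }
  P1 /= p1;
  if (drop1.n_elem > 1) P1 %= drop1;

  // depthwise temporal conv, per-map kernels
  vec wu((size_t)F2 * N);
  mat dw(size(P1), fill::zeros);
  for (int u = 0; u < k3; ++u) {
    const int off = u - pad3;
    const int lo = std::max(0, -off);
    const int hi = std::min(T1 - 1, T1 - 1 - off);
    if (lo > hi) continue;
    for (uword r = 0; r < wu.n_elem; ++r) wu(r) = W3d(u, r % F2);
    dw.cols(lo, hi) += P1.cols(lo + off, hi + off).each_col() % wu;
  }

  // pointwise mix: (F3, N*T1)
  const mat dwv(dw.memptr(), F2, (size_t)N * T1, false, true);
  mat out3pre = W3p.t() * dwv;
  out3pre.each_col() += b3;
  mat a3 = out3pre;
  elu_inplace(a3);

  const mat a3t(a3.memptr(), (size_t)F3 * N, T1, false, true);
  mat P2((size_t)F3 * N, T2);
  for (int j = 0; j < T2; ++j) {
    P2.col(j) = a3t.col(j * p2);
    for (int u = 1; u < p2; ++u) P2.col(j) += a3t.col(j * p2 + u);
  }
  P2 /= p2;
  if (drop2.n_elem > 1) P2 %= drop2;

  // dense head
  mat logits(ncls, N, fill::zeros);
  for (int t = 0; t < T2; ++t) {
    const mat P2t(const_cast<double*>(P2.colptr(t)), F3, N, false, true);
    logits += W4.rows(t * F3, t * F3 + F3 - 1).t() * P2t;
  }
  logits.each_col() += b4;
  mat probs = logits;
  probs.each_row() -= max(probs, 0);
  probs = exp(probs);
  probs.each_row() /= sum(probs, 0);

  return Rcpp::List::create(
      Rcpp::Named("logits") = logits, Rcpp::Named("probs") = probs,
      Rcpp::Named("A1") = A1, Rcpp::Named("out2pre") = out2pre,
      Rcpp::Named("a2") = a2, Rcpp::Named("P1") = P1, Rcpp::Named("dw") = dw,
      Rcpp::Named("out3pre") = out3pre, Rcpp::Named("a3") = a3,
      Rcpp::Named("P2") = P2);
}

static inline mat elu_grad_mat(const mat& pre) {
  mat g(size(pre));
  for (uword i = 0; i < pre.n_elem; ++i) {
    g[i] = pre[i] > 0 ? 1.0 : std::exp(pre[i]);
  }
  return g;
}

// [[Rcpp::export]]
Rcpp::List eegnet_bw_cpp(const arma::mat& Xs, const int C, const int N,
                         const arma::mat& W1, const arma::mat& W2,
                         const int D, const arma::mat& W3d,
                         const arma::mat& W3p, const arma::mat& W4,
                         const int p1, const int p2,
                         const arma::mat& drop1, const arma::mat& drop2,
                         const arma::cube& A1, const arma::mat& out2pre,
                         const arma::mat& P1, const arma::mat& dw,
                         const arma::mat& out3pre, const arma::mat& P2,
                         const arma::mat& dlogits, const bool need_dx,
                         const bool grad_conv1, const bool grad_conv2,
                         const bool grad_conv3) {
  const int T = Xs.n_cols;
  const int k1 = W1.n_rows, F1 = W1.n_cols;
  const int F2 = W2.n_cols, F3 = W3p.n_cols;
  const int k3 = W3d.n_rows;
  const int T1 = T / p1, T2 = T1 / p2;
  const int pad1 = (k1 - 1) / 2, pad3 = (k3 - 1) / 2;

  mat dW4(size(W4), fill::zeros);
  vec db4 = sum(dlogits, 1);
  mat dP2(size(P2));
  for (int t = 0; t < T2; ++t) {
    const mat P2t(const_cast<double*>(P2.colptr(t)), F3, N, false, true);
    dW4.rows(t * F3, t * F3 + F3 - 1) = P2t * dlogits.t();
    mat dP2t(dP2.colptr(t), F3, N, false, true);
    dP2t = W4.rows(t * F3, t * F3 + F3 - 1) * dlogits;
  }
  if (drop2.n_elem > 1) dP2 %= drop2;

  mat da3((size_t)F3 * N, T1, fill::zeros);
  for (int j = 0; j < T2; ++j) {
    for (int u = 0; u < p2; ++u) da3.col(j * p2 + u) = dP2.col(j) / p2;
  }

  mat dout3 = da3;
  {
    const mat g = elu_grad_mat(out3pre);
    const mat gt(const_cast<double*>(g.memptr()), (size_t)F3 * N, T1, false,
                 true);
    dout3 %= gt;
  }
  const mat dout3v(dout3.memptr(), F3, (size_t)N * T1, false, true);
  const mat dwv(const_cast<double*>(dw.memptr()), F2, (size_t)N * T1, false,
                true);
  mat dW3p = dwv * dout3v.t();
  vec db3 = sum(dout3v, 1);
  mat ddwv = W3p * dout3v;                       // (F2, N*T1)
  mat ddw(ddwv.memptr(), (size_t)F2 * N, T1, false, true);

  mat dP1(size(P1), fill::zeros);
  mat dW3d(size(W3d), fill::zeros);
  vec wu((size_t)F2 * N);
  for (int u = 0; u < k3; ++u) {
    const int off = u - pad3;
    const int lo = std::max(0, -off);
    const int hi = std::min(T1 - 1, T1 - 1 - off);
    if (lo > hi) continue;
    for (uword r = 0; r < wu.n_elem; ++r) wu(r) = W3d(u, r % F2);
    dP1.cols(lo + off, hi + off) += ddw.cols(lo, hi).each_col() % wu;
    const vec rs = sum(ddw.cols(lo, hi) % P1.cols(lo + off, hi + off), 1);
    for (uword r = 0; r < rs.n_elem; ++r) dW3d(u, r % F2) += rs(r);
  }
  if (drop1.n_elem > 1) dP1 %= drop1;

  mat da2((size_t)F2 * N, T, fill::zeros);
  for (int j = 0; j < T1; ++j) {
    for (int u = 0; u < p1; ++u) da2.col(j * p1 + u) = dP1.col(j) / p1;
  }
  mat dout2 = da2;
  {
    const mat g = elu_grad_mat(out2pre);
    const mat gt(const_cast<double*>(g.memptr()), (size_t)F2 * N, T, false,
                 true);
    dout2 %= gt;
  }
  const mat dout2v(dout2.memptr(), F2, (size_t)N * T, false, true);
  vec db2 = sum(dout2v, 1);
  mat dW2(size(W2), fill::zeros);
  cube dA1(size(A1));
  for (int f = 0; f < F1; ++f) {
    const mat Afv(const_cast<double*>(A1.slice(f).memptr()), C,
                  (size_t)N * T, false, true);
    const mat df = dout2v.rows(f * D, f * D + D - 1);  // (D, N*T)
    dW2.cols(f * D, f * D + D - 1) = Afv * df.t();
    mat dAfv(dA1.slice(f).memptr(), C, (size_t)N * T, false, true);
    dAfv = W2.cols(f * D, f * D + D - 1) * df;
  }

  mat dW1(size(W1), fill::zeros);
  vec db1(F1);
  mat dXs;
  if (need_dx) dXs.zeros(size(Xs));
  for (int f = 0; f < F1; ++f) {
    const mat& g = dA1.slice(f);
    db1(f) = accu(g);
    for (int u = 0; u < k1; ++u) {
      const int off = u - pad1;
      const int lo = std::max(0, -off);
      const int hi = std::min(T - 1, T - 1 - off);
      if (lo > hi) continue;
      dW1(u, f) = accu(g.cols(lo, hi) % Xs.cols(lo + off, hi + off));
      if (need_dx) {
        const double w = W1(u, f);
        if (w != 0.0) dXs.cols(lo + off, hi + off) += w * g.cols(lo, hi);
      }
    }
  }

  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("dW1") = dW1, Rcpp::Named("db1") = db1,
      Rcpp::Named("dW2") = dW2, Rcpp::Named("db2") = db2,
      Rcpp::Named("dW3d") = dW3d, Rcpp::Named("dW3p") = dW3p,
      Rcpp::Named("db3") = db3, Rcpp::Named("dW4") = dW4,
      Rcpp::Named("db4") = db4);
  if (need_dx) out["dXs"] = dXs;
  if (grad_conv1) out["dA1"] = dA1;
  if (grad_conv2) out["da2"] = da2;
  if (grad_conv3) out["da3"] = da3;
  return out;
}
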