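// Batched multi-head attention core. Sequences are padded to equal length
// and laid out sequence-major: rows of Q/K/V for sequence b occupy the
// contiguous block [b*L, (b+1)*L). Attention probabilities are stored
// key-major (Lk x Lq slices, one per sequence/head) so the softmax runs
// down contiguous columns; the R wrapper transposes when capturing maps.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// [[Rcpp::export]]
Rcpp::List mha_core_fwd(const arma::mat& Q, const arma::mat& K,
                        const arma::mat& V, int B, int Lq, int Lk, int H,
                        const arma::imat& key_valid, bool causal) {
  const int d = Q.n_cols, dk = d / H;
  const double scale = 1.0 / std::sqrt((double)dk);
  mat O(Q.n_rows, d, fill::zeros);
  cube P(Lk, Lq, (size_t)B * H);
  for (int b = 0; b < B; ++b) {
    const int q0 = b * Lq, k0 = b * Lk;
    bool all_valid = true;
    for (int j = 0; j < Lk; ++j) {
      if (!key_valid(b, j)) { all_valid = false; break; }
    }
    for (int h = 0; h < H; ++h) {
      const int c0 = h * dk;
      mat& St = P.slice((size_t)b * H + h);
      St = K.submat(k0, c0, k0 + Lk - 1, c0 + dk - 1) *
           Q.submat(q0, c0, q0 + Lq - 1, c0 + dk - 1).t() * scale;
      if (!all_valid) {
        for (int j = 0; j < Lk; ++j) {
          if (!key_valid(b, j)) St.row(j).fill(-datum::inf);
        }
      }
      // softmax down each column (keys for one query are contiguous)
      for (int q = 0; q < Lq; ++q) {
        double* col = St.colptr(q);
        const int jmax = causal ? std::min(q + 1, Lk) : Lk;
        for (int j = jmax; j < Lk; ++j) col[j] = 0.0;
        double m = -datum::inf;
        for (int j = 0; j < jmax; ++j) {
          if (col[j] > m) m = col[j];
        }
        double s = 0.0;
        for (int j = 0; j < jmax; ++j) {
          col[j] = (col[j] == -datum::inf) ? 0.0 : std::exp(col[j] - m);
          s += col[j];
        }
        const double inv = 1.0 / s;
        for (int j = 0; j < jmax; ++j) col[j] *= inv;
      }
      O.submat(q0, c0, q0 + Lq - 1, c0 + dk - 1) =
        St.t() * V.submat(k0, c0, k0 + Lk - 1, c0 + dk - 1);
    }
  }
  return Rcpp::List::create(Rcpp::Named("O") = O, Rcpp::Named("P") = P);
}

// [[Rcpp::export]]
Rcpp::List mha_core_bwd(const arma::mat& dO, const arma::mat& Q,
                        const arma::mat& K, const arma::mat& V,
                        const arma::cube& P, int B, int Lq, int Lk, int H) {
  const int d = Q.n_cols, dk = d / H;
  const double scale = 1.0 / std::sqrt((double)dk);
  mat dQ(Q.n_rows, d, fill::zeros), dK(K.n_rows, d, fill::zeros),
      dV(V.n_rows, d, fill::zeros);
  for (int b = 0; b < B; ++b) {
    const int q0 = b * Lq, k0 = b * Lk;
    for (int h = 0; h < H; ++h) {
      const int c0 = h * dk;
      const mat& Pt = P.slice((size_t)b * H + h);  // Lk x Lq
      mat dOs = dO.submat(q0, c0, q0 + Lq - 1, c0 + dk - 1);
      dV.submat(k0, c0, k0 + Lk - 1, c0 + dk - 1) = Pt * dOs;
      mat dPt = V.submat(k0, c0, k0 + Lk - 1, c0 + dk - 1) * dOs.t();
      rowvec rs = sum(dPt % Pt, 0);  // per-query correction term
      mat dSt = Pt % (dPt.each_row() - rs);
      dQ.submat(q0, c0, q0 + Lq - 1, c0 + dk - 1) =
        dSt.t() * K.submat(k0, c0, k0 + Lk - 1, c0 + dk - 1) * scale;
      dK.submat(k0, c0, k0 + Lk - 1, c0 + dk - 1) =
        dSt * Q.submat(q0, c0, q0 + Lq - 1, c0 + dk - 1) * scale;
    }
  }
  return Rcpp::List::create(Rcpp::Named("dQ") = dQ, Rcpp::Named("dK") = dK,
                            Rcpp::Named("dV") = dV);
}
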