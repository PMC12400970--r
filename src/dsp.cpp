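// Spectral signal-processing kernels: zero-phase FFT filtering with
// reflection padding, and 1/f^beta spectral shaping of white noise.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Zero-phase filter of each column of X (T x m): reflection-pad by Pl/Pr,
// FFT, multiply by the real gain H (length T+Pl+Pr), inverse FFT, crop.
// Processed in internal column chunks to bound working memory.
// [[Rcpp::export]]
arma::mat fft_filter(const arma::mat& X, const arma::vec& H, int Pl,
                     int Pr) {
  int T = X.n_rows, m = X.n_cols, L = T + Pl + Pr;
  if ((int)H.n_elem != L) stop("gain length mismatch");
  arma::cx_vec Hc(H, arma::vec(L, arma::fill::zeros));
  arma::mat out(T, m);
  int chunk = std::max(1, (int)(8e6 / L));
  arma::mat Xp(L, std::min(chunk, m));
  for (int start = 0; start < m; start += chunk) {
    int mc = std::min(chunk, m - start);
    if ((int)Xp.n_cols != mc) Xp.set_size(L, mc);
    for (int j = 0; j < mc; ++j) {
      const double* x = X.colptr(start + j);
      double* p = Xp.colptr(j);
      for (int i = 0; i < Pl; ++i) p[i] = x[Pl - i];
      std::memcpy(p + Pl, x, sizeof(double) * T);
      for (int i = 0; i < Pr; ++i) p[Pl + T + i] = x[T - 2 - i];
    }
    arma::cx_mat F = arma::fft(Xp);
    F.each_col() %= Hc;
    arma::mat Y = arma::real(arma::ifft(F));
    out.cols(start, start + mc - 1) = Y.rows(Pl, Pl + T - 1);
  }
  return out;
}

// maximum absolute amplitude per trial of an [N, C, T] epoch array
// [[Rcpp::export]]
arma::vec trial_absmax(const arma::cube& X) {
  // cube arrives as [N, C, T]: rows = trials
  arma::vec mx(X.n_rows, arma::fill::zeros);
  const double* p = X.memptr();
  arma::uword n = X.n_rows, total = X.n_elem;
  for (arma::uword i = 0; i < total; ++i) {
    double a = std::abs(p[i]);
    arma::uword tr = i % n;
    if (a > mx(tr)) mx(tr) = a;
  }
  return mx;
}

// Multiply the spectrum of each column of W by the real amplitude profile
// s (two-sided, symmetric) and return the real inverse transform.
// [[Rcpp::export]]
arma::mat fft_shape(const arma::mat& W, const arma::vec& s) {
  if (W.n_rows != s.n_elem) stop("profile length mismatch");
  arma::cx_mat F = arma::fft(W);
  F.each_col() %= arma::cx_vec(s, arma::vec(s.n_elem, arma::fill::zeros));
  return arma::real(arma::ifft(F));
}
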