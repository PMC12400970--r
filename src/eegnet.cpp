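// Compact convolutional EEG classifier: temporal convolution, depthwise
// spatial convolution, pointwise convolution (block 1), then one or more
// separable (depthwise temporal + pointwise) blocks, each with batch
// normalization, ELU activation, temporal average pooling and channel-wise
// dropout, followed by a dense layer producing one logit per class.
//
// Activations are stored time-major: cube(T, maps, batch). The R layer owns
// parameter initialization, the optimizer, dropout mask generation and
// running batch-norm statistics; this file implements the forward pass, the
// analytic backward pass, and the feature/gradient extraction used by
// Grad-CAM.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double elu(double x) { return x > 0 ? x : std::expm1(x); }

// lag matrix of one trace: Xcol(t, l) = x(t + l - pad), zero padded
static void fill_lag_matrix(const double* x, arma::mat& Xcol, int T, int L,
                            int pad) {
  for (int l = 0; l < L; ++l) {
    int off = l - pad;
    double* col = Xcol.colptr(l);
    std::memset(col, 0, sizeof(double) * T);
    int t0 = std::max(0, -off), t1 = std::min(T, T - off);
    if (t1 > t0)
      std::memcpy(col + t0, x + t0 + off, sizeof(double) * (t1 - t0));
  }
}

// temporal convolution of every channel with every temporal kernel, via
// one GEMM per channel; A1 is (T x F1*C), column f*C+c
static void conv1_forward(const arma::mat& xs, const arma::mat& Wt,
                          arma::mat& A1) {
  int T = xs.n_rows, C = xs.n_cols, L = Wt.n_cols, F1 = Wt.n_rows;
  int pad = L / 2;
  arma::mat Xcol(T, L), blk;
  for (int c = 0; c < C; ++c) {
    fill_lag_matrix(xs.colptr(c), Xcol, T, L, pad);
    blk = Xcol * Wt.t();
    for (int f = 0; f < F1; ++f)
      std::memcpy(A1.colptr(f * C + c), blk.colptr(f), sizeof(double) * T);
  }
}

// temporal same-convolution of each column of x (T x M) with one kernel per
// output assignment; used via the helpers below
static void conv_col_accum(const double* x, double* out, int T, double wv,
                           int off) {
  int t0 = std::max(0, -off);
  int t1 = std::min(T, T - off);
  for (int t = t0; t < t1; ++t) out[t] += wv * x[t + off];
}

struct Cfg {
  int C, T, K, F1, L, D, F2;
  std::vector<int> pools;   // length n_blocks
  std::vector<int> Lsep;    // kernel length per separable block
  std::vector<int> Tlen;    // Tlen[0]=T, Tlen[b+1] after pool b
  int n_sep;
};

static Cfg parse_cfg(const List& cfg) {
  Cfg c;
  c.C = cfg["n_channels"]; c.T = cfg["n_samples"]; c.K = cfg["n_classes"];
  c.F1 = cfg["F1"]; c.L = cfg["temporal_kernel_len"];
  c.D = cfg["D"]; c.F2 = cfg["F2"];
  IntegerVector pools = cfg["pool_sizes"];
  IntegerVector lsep = cfg["sep_kernel_len"];
  for (int i = 0; i < pools.size(); ++i) c.pools.push_back(pools[i]);
  for (int i = 0; i < lsep.size(); ++i) c.Lsep.push_back(lsep[i]);
  c.n_sep = pools.size() - 1;
  c.Tlen.push_back(c.T);
  for (size_t b = 0; b < c.pools.size(); ++b)
    c.Tlen.push_back(c.Tlen[b] / c.pools[b]);
  return c;
}

// average pooling along rows: in (Tin x M) -> out (Tout x M)
static arma::mat pool_fwd(const arma::mat& in, int p) {
  int Tout = in.n_rows / p;
  arma::mat out(Tout, in.n_cols, arma::fill::zeros);
  for (arma::uword j = 0; j < in.n_cols; ++j)
    for (int t = 0; t < Tout; ++t) {
      double s = 0;
      for (int u = 0; u < p; ++u) s += in(t * p + u, j);
      out(t, j) = s / p;
    }
  return out;
}

static arma::mat pool_bwd(const arma::mat& dout, int p, int Tin) {
  arma::mat din(Tin, dout.n_cols, arma::fill::zeros);
  for (arma::uword j = 0; j < dout.n_cols; ++j)
    for (arma::uword t = 0; t < dout.n_rows; ++t) {
      double g = dout(t, j) / p;
      for (int u = 0; u < p; ++u) din(t * p + u, j) = g;
    }
  return din;
}

// depthwise temporal conv, same padding: out(t,j) = sum_l W(j,l) in(t+l-pad,j)
static arma::mat dwconv_fwd(const arma::mat& in, const arma::mat& W) {
  int T = in.n_rows, L = W.n_cols, pad = L / 2;
  arma::mat out(T, in.n_cols, arma::fill::zeros);
  for (arma::uword j = 0; j < in.n_cols; ++j)
    for (int l = 0; l < L; ++l)
      conv_col_accum(in.colptr(j), out.colptr(j), T, W(j, l), l - pad);
  return out;
}

static void dwconv_bwd(const arma::mat& in, const arma::mat& W,
                       const arma::mat& dout, arma::mat& din,
                       arma::mat& dW) {
  int T = in.n_rows, L = W.n_cols, pad = L / 2;
  din.zeros(T, in.n_cols);
  for (arma::uword j = 0; j < in.n_cols; ++j) {
    for (int l = 0; l < L; ++l) {
      int off = l - pad;
      int t0 = std::max(0, -off), t1 = std::min(T, T - off);
      const double* dptr = dout.colptr(j);
      const double* iptr = in.colptr(j);
      double acc = 0;
      for (int t = t0; t < t1; ++t) acc += dptr[t] * iptr[t + off];
      dW(j, l) += acc;
      // din(t+off) += W(j,l) * dout(t)
      double wv = W(j, l);
      double* dn = din.colptr(j);
      for (int t = t0; t < t1; ++t) dn[t + off] += wv * dptr[t];
    }
  }
}

// ---------------------------------------------------------------------------
// forward/backward state per batch
struct SepCache {
  arma::cube H;   // block input  (Tb x F2 x B)
  arma::cube Q;   // after depthwise conv
  arma::cube U;   // after pointwise conv (pre-BN)
  arma::cube E;   // after BN + ELU
  arma::vec mu, inv;
};

// batch-norm statistics over all slices, per column (map)
static void bn_stats(const arma::cube& pre, arma::vec& mu, arma::vec& var) {
  int M = pre.n_cols;
  double n = (double)pre.n_rows * pre.n_slices;
  mu.zeros(M); var.zeros(M);
  for (arma::uword s = 0; s < pre.n_slices; ++s) {
    mu += arma::sum(pre.slice(s), 0).t();
    var += arma::sum(arma::square(pre.slice(s)), 0).t();
  }
  mu /= n;
  var = var / n - arma::square(mu);
  var.transform([](double v) { return v < 0 ? 0 : v; });
}

static void bn_elu_fwd(const arma::cube& pre, arma::cube& out,
                       const arma::vec& g, const arma::vec& b,
                       const arma::vec& mu, const arma::vec& inv) {
  out.set_size(arma::size(pre));
  for (arma::uword s = 0; s < pre.n_slices; ++s)
    for (arma::uword j = 0; j < pre.n_cols; ++j) {
      const double* p = pre.slice(s).colptr(j);
      double* o = out.slice(s).colptr(j);
      double gj = g(j), bj = b(j), mj = mu(j), ij = inv(j);
      for (arma::uword t = 0; t < pre.n_rows; ++t)
        o[t] = elu(gj * (p[t] - mj) * ij + bj);
    }
}

// backward through ELU + batch BN; dE is modified in place into d(pre)
static void bn_elu_bwd(const arma::cube& pre, const arma::cube& E,
                       arma::cube& dE, const arma::vec& g,
                       const arma::vec& mu, const arma::vec& inv,
                       arma::vec& dg, arma::vec& db) {
  int M = pre.n_cols;
  double n = (double)pre.n_rows * pre.n_slices;
  // ELU backward: dY = dE * (E > 0 ? 1 : E + 1)
  for (arma::uword s = 0; s < E.n_slices; ++s) {
    arma::mat& dm = dE.slice(s);
    const arma::mat& em = E.slice(s);
    for (arma::uword j = 0; j < em.n_cols; ++j) {
      double* d = dm.colptr(j);
      const double* e = em.colptr(j);
      for (arma::uword t = 0; t < em.n_rows; ++t)
        if (e[t] <= 0) d[t] *= (e[t] + 1.0);
    }
  }
  // BN backward, batch statistics
  arma::vec sum_dxhat(M, arma::fill::zeros),
      sum_dxhat_xhat(M, arma::fill::zeros);
  dg.zeros(M); db.zeros(M);
  for (arma::uword s = 0; s < pre.n_slices; ++s)
    for (int j = 0; j < M; ++j) {
      const double* p = pre.slice(s).colptr(j);
      const double* d = dE.slice(s).colptr(j);
      double mj = mu(j), ij = inv(j), sd = 0, sdx = 0, sdg = 0;
      for (arma::uword t = 0; t < pre.n_rows; ++t) {
        double xh = (p[t] - mj) * ij;
        sd += d[t];
        sdx += d[t] * xh;
        sdg += d[t] * xh;
      }
      db(j) += sd;
      dg(j) += sdg;
      sum_dxhat(j) += sd;         // times gamma applied below
      sum_dxhat_xhat(j) += sdx;
    }
  for (arma::uword s = 0; s < pre.n_slices; ++s)
    for (int j = 0; j < M; ++j) {
      double* d = dE.slice(s).colptr(j);
      const double* p = pre.slice(s).colptr(j);
      double mj = mu(j), ij = inv(j), gj = g(j);
      double m1 = g(j) * sum_dxhat(j) / n;
      double m2 = g(j) * sum_dxhat_xhat(j) / n;
      for (arma::uword t = 0; t < pre.n_rows; ++t) {
        double xh = (p[t] - mj) * ij;
        d[t] = ij * (gj * d[t] - m1 - xh * m2);
      }
    }
}

// [[Rcpp::export]]
List nn_train_batch(const arma::cube& X, const arma::ivec& y, List w,
                    List cfg_, const arma::vec& class_w, List dropmasks,
                    double bn_eps) {
  Cfg cfg = parse_cfg(cfg_);
  int B = X.n_slices, Tn = cfg.T, C = cfg.C, F1 = cfg.F1, D = cfg.D,
      F2 = cfg.F2, K = cfg.K, L = cfg.L;
  int pad = L / 2;

  arma::mat Wt = w["Wt"], Wdw = w["Wdw"], Wpw1 = w["Wpw1"], Wd = w["Wd"];
  arma::vec g1 = w["g1"], b1 = w["b1"], bd = w["bd"];
  List sep = w["sep"];

  // ---- forward: block 1 ----
  arma::cube A1(Tn, F1 * C, B);
  for (int n = 0; n < B; ++n)
    conv1_forward(X.slice(n), Wt, A1.slice(n));
  arma::cube S(Tn, F1 * D, B), P(Tn, F2, B);
  for (int n = 0; n < B; ++n) {
    for (int f = 0; f < F1; ++f)
      S.slice(n).cols(f * D, (f + 1) * D - 1) =
          A1.slice(n).cols(f * C, (f + 1) * C - 1) *
          Wdw.rows(f * D, (f + 1) * D - 1).t();
    P.slice(n) = S.slice(n) * Wpw1.t();
  }
  arma::vec mu1, var1;
  bn_stats(P, mu1, var1);
  arma::vec inv1 = 1.0 / arma::sqrt(var1 + bn_eps);
  arma::cube E1;
  bn_elu_fwd(P, E1, g1, b1, mu1, inv1);

  int T1 = cfg.Tlen[1];
  arma::mat mask1 = dropmasks[0];
  arma::cube H1(T1, F2, B);
  for (int n = 0; n < B; ++n) {
    arma::mat h = pool_fwd(E1.slice(n), cfg.pools[0]);
    for (int j = 0; j < F2; ++j) h.col(j) *= mask1(j, n);
    H1.slice(n) = h;
  }

  // ---- forward: separable blocks ----
  std::vector<SepCache> sc(cfg.n_sep);
  arma::cube Hin = H1;
  std::vector<arma::vec> mus(cfg.n_sep), invs(cfg.n_sep), vars(cfg.n_sep);
  for (int b = 0; b < cfg.n_sep; ++b) {
    List wb = sep[b];
    arma::mat Wdt = wb["Wdt"], Wpw = wb["Wpw"];
    arma::vec gb = wb["g"], bb = wb["b"];
    int Tb = cfg.Tlen[b + 1], Tb1 = cfg.Tlen[b + 2];
    sc[b].H = Hin;
    sc[b].Q.set_size(Tb, F2, B);
    sc[b].U.set_size(Tb, F2, B);
    for (int n = 0; n < B; ++n) {
      sc[b].Q.slice(n) = dwconv_fwd(Hin.slice(n), Wdt);
      sc[b].U.slice(n) = sc[b].Q.slice(n) * Wpw.t();
    }
    bn_stats(sc[b].U, mus[b], vars[b]);
    invs[b] = 1.0 / arma::sqrt(vars[b] + bn_eps);
    sc[b].mu = mus[b];
    sc[b].inv = invs[b];
    bn_elu_fwd(sc[b].U, sc[b].E, gb, bb, mus[b], invs[b]);
    arma::mat maskb = dropmasks[b + 1];
    arma::cube Hout(Tb1, F2, B);
    for (int n = 0; n < B; ++n) {
      arma::mat h = pool_fwd(sc[b].E.slice(n), cfg.pools[b + 1]);
      for (int j = 0; j < F2; ++j) h.col(j) *= maskb(j, n);
      Hout.slice(n) = h;
    }
    Hin = Hout;
  }

  // ---- dense + loss ----
  int Tlast = cfg.Tlen.back();
  arma::mat Hmat(Tlast * F2, B);
  for (int n = 0; n < B; ++n)
    Hmat.col(n) = arma::vectorise(Hin.slice(n));
  arma::mat Z = Wd * Hmat;
  Z.each_col() += bd;

  arma::mat Pr(K, B);
  double loss = 0, wsum = 0;
  for (int n = 0; n < B; ++n) {
    arma::vec z = Z.col(n);
    double zm = z.max();
    arma::vec e = arma::exp(z - zm);
    arma::vec p = e / arma::accu(e);
    Pr.col(n) = p;
    double cw = class_w(y(n));
    loss += -cw * std::log(std::max(p(y(n)), 1e-300));
    wsum += cw;
  }
  loss /= wsum;

  // ---- backward ----
  arma::mat dZ = Pr;
  for (int n = 0; n < B; ++n) {
    dZ(y(n), n) -= 1.0;
    dZ.col(n) *= class_w(y(n)) / wsum;
  }
  arma::mat dWd = dZ * Hmat.t();
  arma::vec dbd = arma::sum(dZ, 1);
  arma::mat dHmat = Wd.t() * dZ;

  arma::cube dHin(Tlast, F2, B);
  for (int n = 0; n < B; ++n)
    dHin.slice(n) = arma::reshape(dHmat.col(n), Tlast, F2);

  List dsep(cfg.n_sep);
  for (int b = cfg.n_sep - 1; b >= 0; --b) {
    List wb = sep[b];
    arma::mat Wdt = wb["Wdt"], Wpw = wb["Wpw"];
    arma::vec gb = wb["g"];
    int Tb = cfg.Tlen[b + 1];
    arma::mat maskb = dropmasks[b + 1];
    arma::cube dE(Tb, F2, B);
    for (int n = 0; n < B; ++n) {
      arma::mat dh = dHin.slice(n);
      for (int j = 0; j < F2; ++j) dh.col(j) *= maskb(j, n);
      dE.slice(n) = pool_bwd(dh, cfg.pools[b + 1], Tb);
    }
    arma::vec dg, db;
    bn_elu_bwd(sc[b].U, sc[b].E, dE, gb, sc[b].mu, sc[b].inv, dg, db);
    // dE now holds dU
    arma::mat dWpw(F2, F2, arma::fill::zeros),
        dWdt(F2, Wdt.n_cols, arma::fill::zeros);
    arma::cube dH(Tb, F2, B);
    for (int n = 0; n < B; ++n) {
      dWpw += dE.slice(n).t() * sc[b].Q.slice(n);
      arma::mat dQ = dE.slice(n) * Wpw;
      arma::mat din;
      dwconv_bwd(sc[b].H.slice(n), Wdt, dQ, din, dWdt);
      dH.slice(n) = din;
    }
    dsep[b] = List::create(_["Wdt"] = dWdt, _["Wpw"] = dWpw, _["g"] = dg,
                           _["b"] = db);
    dHin = dH;
  }

  // block 1 backward
  arma::cube dE1(Tn, F2, B);
  for (int n = 0; n < B; ++n) {
    arma::mat dh = dHin.slice(n);
    for (int j = 0; j < F2; ++j) dh.col(j) *= mask1(j, n);
    dE1.slice(n) = pool_bwd(dh, cfg.pools[0], Tn);
  }
  arma::vec dg1, db1;
  bn_elu_bwd(P, E1, dE1, g1, mu1, inv1, dg1, db1);
  // dE1 now holds dP
  arma::mat dWpw1(F2, F1 * D, arma::fill::zeros);
  arma::mat dWdw(F1 * D, C, arma::fill::zeros);
  arma::mat dWt(F1, L, arma::fill::zeros);
  arma::mat dA1(Tn, F1 * C), Xcol(Tn, L), dblk(Tn, F1);
  for (int n = 0; n < B; ++n) {
    dWpw1 += dE1.slice(n).t() * S.slice(n);
    arma::mat dS = dE1.slice(n) * Wpw1;
    const arma::mat& xs = X.slice(n);
    for (int f = 0; f < F1; ++f) {
      arma::mat dSf = dS.cols(f * D, (f + 1) * D - 1);
      arma::mat A1f = A1.slice(n).cols(f * C, (f + 1) * C - 1);
      dWdw.rows(f * D, (f + 1) * D - 1) += dSf.t() * A1f;
      dA1.cols(f * C, (f + 1) * C - 1) =
          dSf * Wdw.rows(f * D, (f + 1) * D - 1);
    }
    for (int c = 0; c < C; ++c) {
      fill_lag_matrix(xs.colptr(c), Xcol, Tn, L, pad);
      for (int f = 0; f < F1; ++f)
        std::memcpy(dblk.colptr(f), dA1.colptr(f * C + c),
                    sizeof(double) * Tn);
      dWt += dblk.t() * Xcol;
    }
  }

  List grads = List::create(
      _["Wt"] = dWt, _["Wdw"] = dWdw, _["Wpw1"] = dWpw1, _["g1"] = dg1,
      _["b1"] = db1, _["sep"] = dsep, _["Wd"] = dWd, _["bd"] = dbd);
  List bn1 = List::create(_["mu"] = mu1, _["var"] = var1);
  List bnsep(cfg.n_sep);
  for (int b = 0; b < cfg.n_sep; ++b)
    bnsep[b] = List::create(_["mu"] = mus[b], _["var"] = vars[b]);
  return List::create(_["loss"] = loss, _["logits"] = Z, _["grads"] = grads,
                      _["bn1"] = bn1, _["bnsep"] = bnsep);
}

// forward pass with running batch-norm statistics (inference); optionally
// returns the post-activation feature maps of the first separable block
// (the network's second convolutional block), used by Grad-CAM
// [[Rcpp::export]]
List nn_infer(const arma::cube& X, List w, List cfg_, List bn_state,
              double bn_eps, bool want_features) {
  Cfg cfg = parse_cfg(cfg_);
  int B = X.n_slices, Tn = cfg.T, C = cfg.C, F1 = cfg.F1, D = cfg.D,
      F2 = cfg.F2, L = cfg.L;
  int pad = L / 2;
  arma::mat Wt = w["Wt"], Wdw = w["Wdw"], Wpw1 = w["Wpw1"], Wd = w["Wd"];
  arma::vec g1 = w["g1"], b1 = w["b1"], bd = w["bd"];
  List sep = w["sep"];
  List bn1 = bn_state["bn1"];
  arma::vec rm1 = bn1["mu"], rv1 = bn1["var"];
  arma::vec inv1 = 1.0 / arma::sqrt(rv1 + bn_eps);
  List bnsep = bn_state["bnsep"];

  arma::cube A2;  // features of the second convolutional block
  arma::mat logits(cfg.K, B);

  for (int n = 0; n < B; ++n) {
    const arma::mat& xs = X.slice(n);
    arma::mat A1(Tn, F1 * C);
    conv1_forward(xs, Wt, A1);
    arma::mat S(Tn, F1 * D);
    for (int f = 0; f < F1; ++f)
      S.cols(f * D, (f + 1) * D - 1) =
          A1.cols(f * C, (f + 1) * C - 1) *
          Wdw.rows(f * D, (f + 1) * D - 1).t();
    arma::mat P = S * Wpw1.t();
    for (int j = 0; j < F2; ++j) {
      double* p = P.colptr(j);
      for (int t = 0; t < Tn; ++t)
        p[t] = elu(g1(j) * (p[t] - rm1(j)) * inv1(j) + b1(j));
    }
    arma::mat H = pool_fwd(P, cfg.pools[0]);
    for (int b = 0; b < cfg.n_sep; ++b) {
      List wb = sep[b];
      arma::mat Wdt = wb["Wdt"], Wpw = wb["Wpw"];
      arma::vec gb = wb["g"], bb = wb["b"];
      List bnb = bnsep[b];
      arma::vec rm = bnb["mu"], rv = bnb["var"];
      arma::vec inv = 1.0 / arma::sqrt(rv + bn_eps);
      arma::mat Q = dwconv_fwd(H, Wdt);
      arma::mat U = Q * Wpw.t();
      for (int j = 0; j < F2; ++j) {
        double* u = U.colptr(j);
        for (arma::uword t = 0; t < U.n_rows; ++t)
          u[t] = elu(gb(j) * (u[t] - rm(j)) * inv(j) + bb(j));
      }
      if (b == 0 && want_features) {
        if (A2.n_slices == 0) A2.set_size(U.n_rows, F2, B);
        A2.slice(n) = U;
      }
      H = pool_fwd(U, cfg.pools[b + 1]);
    }
    logits.col(n) = Wd * arma::vectorise(H) + bd;
  }
  if (want_features)
    return List::create(_["logits"] = logits, _["features"] = A2);
  return List::create(_["logits"] = logits);
}

// Gradient of one logit per trial with respect to the second convolutional
// block's post-activation feature maps, in inference mode. Returns both the
// features and the gradients (T1 x F2 x B).
// [[Rcpp::export]]
List nn_feature_grad(const arma::cube& X, List w, List cfg_, List bn_state,
                     double bn_eps, const arma::ivec& classes) {
  Cfg cfg = parse_cfg(cfg_);
  int B = X.n_slices, Tn = cfg.T, C = cfg.C, F1 = cfg.F1, D = cfg.D,
      F2 = cfg.F2, L = cfg.L;
  int pad = L / 2;
  arma::mat Wt = w["Wt"], Wdw = w["Wdw"], Wpw1 = w["Wpw1"], Wd = w["Wd"];
  arma::vec g1 = w["g1"], b1 = w["b1"], bd = w["bd"];
  List sep = w["sep"];
  List bn1 = bn_state["bn1"];
  arma::vec rm1 = bn1["mu"], rv1 = bn1["var"];
  arma::vec inv1 = 1.0 / arma::sqrt(rv1 + bn_eps);
  List bnsep = bn_state["bnsep"];

  int T1 = cfg.Tlen[2];  // length of block-2 feature maps (pre-pool: Tlen[1])
  int Tfeat = cfg.Tlen[1];
  arma::cube A2(Tfeat, F2, B), G(Tfeat, F2, B);
  (void)T1;

  for (int n = 0; n < B; ++n) {
    const arma::mat& xs = X.slice(n);
    arma::mat A1(Tn, F1 * C);
    conv1_forward(xs, Wt, A1);
    arma::mat S(Tn, F1 * D);
    for (int f = 0; f < F1; ++f)
      S.cols(f * D, (f + 1) * D - 1) =
          A1.cols(f * C, (f + 1) * C - 1) *
          Wdw.rows(f * D, (f + 1) * D - 1).t();
    arma::mat P = S * Wpw1.t();
    for (int j = 0; j < F2; ++j) {
      double* p = P.colptr(j);
      for (int t = 0; t < Tn; ++t)
        p[t] = elu(g1(j) * (p[t] - rm1(j)) * inv1(j) + b1(j));
    }
    arma::mat H = pool_fwd(P, cfg.pools[0]);

    // forward through separable blocks, caching per-block tensors
    std::vector<arma::mat> Hs(cfg.n_sep), Qs(cfg.n_sep), Es(cfg.n_sep);
    std::vector<arma::vec> invb(cfg.n_sep), gvb(cfg.n_sep);
    for (int b = 0; b < cfg.n_sep; ++b) {
      List wb = sep[b];
      arma::mat Wdt = wb["Wdt"], Wpw = wb["Wpw"];
      arma::vec gb = wb["g"], bb = wb["b"];
      List bnb = bnsep[b];
      arma::vec rm = bnb["mu"], rv = bnb["var"];
      arma::vec inv = 1.0 / arma::sqrt(rv + bn_eps);
      invb[b] = inv; gvb[b] = gb;
      Hs[b] = H;
      Qs[b] = dwconv_fwd(H, Wdt);
      arma::mat U = Qs[b] * Wpw.t();
      Es[b] = U;
      for (int j = 0; j < F2; ++j) {
        double* u = Es[b].colptr(j);
        for (arma::uword t = 0; t < U.n_rows; ++t)
          u[t] = elu(gb(j) * (u[t] - rm(j)) * inv(j) + bb(j));
      }
      H = pool_fwd(Es[b], cfg.pools[b + 1]);
    }
    A2.slice(n) = Es[0];

    // backward from the selected logit down to Es[0]
    int Tlast = cfg.Tlen.back();
    arma::vec dh = Wd.row(classes(n)).t();
    arma::mat dH = arma::reshape(dh, Tlast, F2);
    for (int b = cfg.n_sep - 1; b >= 1; --b) {
      List wb = sep[b];
      arma::mat Wdt = wb["Wdt"], Wpw = wb["Wpw"];
      arma::mat dE = pool_bwd(dH, cfg.pools[b + 1], Es[b].n_rows);
      // ELU + inference-BN backward
      for (int j = 0; j < F2; ++j) {
        double* d = dE.colptr(j);
        const double* e = Es[b].colptr(j);
        double scale = gvb[b](j) * invb[b](j);
        for (arma::uword t = 0; t < dE.n_rows; ++t) {
          if (e[t] <= 0) d[t] *= (e[t] + 1.0);
          d[t] *= scale;
        }
      }
      arma::mat dQ = dE * Wpw;
      arma::mat din, dWdt_dummy(F2, Wdt.n_cols, arma::fill::zeros);
      dwconv_bwd(Hs[b], Wdt, dQ, din, dWdt_dummy);
      dH = din;
    }
    G.slice(n) = pool_bwd(dH, cfg.pools[1], Tfeat);
  }
  return List::create(_["features"] = A2, _["grads"] = G);
}
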