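// Batched forward/backward engine for the GAT + Transformer seizure
// detector. The plain-R functions in R/gat.R and R/transformer.R define the
// model; this file computes the same forward pass over batches of window
// sequences, plus analytic gradients of the focal loss, for training speed.
// Conventions (must stay in lock-step with the R reference):
//   - node features h: M x F, Z = h * W (W: F x Fh per head),
//     e_ij = LeakyReLU(a1.Zi + a2.Zj) on edges, masked row softmax,
//     layer out = act(mean over heads of alpha_q * Z_q)
//   - slices flattened column-major, token = E^T vec, class token row 0,
//     fixed sinusoidal positions added
//   - pre-norm blocks: H' = MSA(LN(H)) + H; H = MLP(LN(H')) + H'
//   - head: LayerNorm, linear to 2 logits, softmax; index 1 = seizure
// Single-threaded and deterministic given the dropout seed. Hot paths are
// arranged as a few large GEMMs per batch; the small per-window attention
// work uses explicit loops to avoid temporary allocations.

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::cube;
using arma::uword;

static inline double elu1(double x) { return x > 0 ? x : std::exp(x) - 1; }
static inline double elu1g(double x) { return x > 0 ? 1.0 : std::exp(x); }
// GAT output nonlinearity: 0 = elu (default), 1 = relu, 2 = identity
static inline double gact(double x, int a) {
  return a == 0 ? elu1(x) : (a == 1 ? (x > 0 ? x : 0.0) : x);
}
static inline double gactg(double x, int a) {
  return a == 0 ? elu1g(x) : (a == 1 ? (x > 0 ? 1.0 : 0.0) : 1.0);
}
static inline double gelu1(double x) {
  return 0.5 * x * (1.0 + std::erf(x / std::sqrt(2.0)));
}
static inline double gelu1g(double x) {
  const double phi = std::exp(-0.5 * x * x) / std::sqrt(2.0 * M_PI);
  return 0.5 * (1.0 + std::erf(x / std::sqrt(2.0))) + x * phi;
}

struct Dropout {
  std::mt19937_64 rng;
  std::uniform_real_distribution<double> unif;
  double rate;
  bool on;
  Dropout(uint64_t seed, double rate_, bool on_)
    : rng(seed), unif(0.0, 1.0), rate(rate_), on(on_ && rate_ > 0) {}
  void mask(mat& m) { // inverted-dropout mask (ones when inactive)
    if (!on) { m.ones(); return; }
    const double keep = 1.0 - rate;
    double* p = m.memptr();
    const uword n = m.n_elem;
    for (uword i = 0; i < n; ++i)
      p[i] = unif(rng) < keep ? 1.0 / keep : 0.0;
  }
};

// ---------------------------------------------------------------------------
// GAT layer over a stack of windows

struct GatCache {
  mat Z;        // (W*M) x (Fh*Q)
  cube alpha;   // M x M x (W*Q)
  mat S1, S2;   // (W*M) x Q attention projections
  mat pre;      // (W*M) x Fh pre-activation head average
  mat drop;     // dropout mask on the layer output
};

static mat gat_layer_fwd(const mat& Xs, const cube& A,
                         const std::vector<uword>& wins, uword M,
                         const mat& W, const mat& a1, const mat& a2,
                         double slope, int act, Dropout& dropo, GatCache& cc) {
  const uword Q = a1.n_cols, Fh = a1.n_rows, Wn = wins.size();
  cc.Z = Xs * W;
  // one GEMM for all attention projections: column q of S1 is Z_q * a1_q
  mat A1sel(Fh * Q, Q, arma::fill::zeros), A2sel(Fh * Q, Q, arma::fill::zeros);
  for (uword q = 0; q < Q; ++q) {
    A1sel.submat(q * Fh, q, q * Fh + Fh - 1, q) = a1.col(q);
    A2sel.submat(q * Fh, q, q * Fh + Fh - 1, q) = a2.col(q);
  }
  cc.S1 = cc.Z * A1sel;
  cc.S2 = cc.Z * A2sel;
  cc.alpha.zeros(M, M, Wn * Q);
  mat acc(Wn * M, Fh);
  mat Alcat(M, M * Q), Zcat(M * Q, Fh);
  std::vector<double> mx(M), rs(M);
  std::vector<unsigned> eidx, ei, ej;
  for (uword w = 0; w < Wn; ++w) {
    // masked softmax touches edges only; the edge list is shared by all heads
    const double* Aw = A.slice(wins[w]).memptr();
    eidx.clear(); ei.clear(); ej.clear();
    for (uword j = 0; j < M; ++j)
      for (uword i = 0; i < M; ++i)
        if (Aw[j * M + i] != 0) {
          eidx.push_back(j * M + i);
          ei.push_back(i);
          ej.push_back(j);
        }
    const uword ne = eidx.size();
    for (uword q = 0; q < Q; ++q) {
      mat& al = cc.alpha.slice(w * Q + q);
      double* alp = al.memptr();
      const double* s1 = cc.S1.colptr(q) + w * M;
      const double* s2 = cc.S2.colptr(q) + w * M;
      std::fill(mx.begin(), mx.end(), -arma::datum::inf);
      std::fill(rs.begin(), rs.end(), 0.0);
      for (uword e = 0; e < ne; ++e) {
        double v = s1[ei[e]] + s2[ej[e]];
        v = v > 0 ? v : slope * v;
        alp[eidx[e]] = v;
        if (v > mx[ei[e]]) mx[ei[e]] = v;
      }
      for (uword e = 0; e < ne; ++e) {
        const double v = std::exp(alp[eidx[e]] - mx[ei[e]]);
        alp[eidx[e]] = v;
        rs[ei[e]] += v;
      }
      for (uword e = 0; e < ne; ++e)
        alp[eidx[e]] /= rs[ei[e]];
      Alcat.cols(q * M, q * M + M - 1) = al;
      Zcat.rows(q * M, q * M + M - 1) =
        cc.Z.submat(w * M, q * Fh, w * M + M - 1, q * Fh + Fh - 1);
    }
    acc.rows(w * M, w * M + M - 1) = Alcat * Zcat;
  }
  acc /= (double)Q;
  cc.pre = acc;
  mat out = acc;
  out.transform([act](double x) { return gact(x, act); });
  cc.drop.set_size(out.n_rows, out.n_cols);
  dropo.mask(cc.drop);
  return out % cc.drop;
}

static mat gat_layer_bwd(const mat& dOut, const mat& Xs, const cube& A,
                         const std::vector<uword>& wins, uword M,
                         const mat& W, const mat& a1, const mat& a2,
                         double slope, int act, const GatCache& cc,
                         mat& dW, mat& da1, mat& da2, bool want_dx) {
  const uword Q = a1.n_cols, Fh = a1.n_rows, Wn = wins.size();
  mat dpre = dOut % cc.drop;
  {
    double* dp = dpre.memptr();
    const double* pr = cc.pre.memptr();
    const double invQ = 1.0 / (double)Q;
    for (uword i = 0; i < dpre.n_elem; ++i)
      dp[i] *= gactg(pr[i], act) * invQ;
  }
  mat dZ(cc.Z.n_rows, cc.Z.n_cols);
  da1.zeros(Fh, Q);
  da2.zeros(Fh, Q);
  mat Alcat(M, M * Q), Zcat(M * Q, Fh);
  vec ds1(M), ds2(M), rs(M);
  std::vector<unsigned> eidx, ei, ej;
  for (uword w = 0; w < Wn; ++w) {
    const double* Aw = A.slice(wins[w]).memptr();
    eidx.clear(); ei.clear(); ej.clear();
    for (uword j = 0; j < M; ++j)
      for (uword i = 0; i < M; ++i)
        if (Aw[j * M + i] != 0) {
          eidx.push_back(j * M + i);
          ei.push_back(i);
          ej.push_back(j);
        }
    const uword ne = eidx.size();
    for (uword q = 0; q < Q; ++q) {
      Alcat.cols(q * M, q * M + M - 1) = cc.alpha.slice(w * Q + q);
      Zcat.rows(q * M, q * M + M - 1) =
        cc.Z.submat(w * M, q * Fh, w * M + M - 1, q * Fh + Fh - 1);
    }
    mat dH = dpre.rows(w * M, w * M + M - 1);  // M x Fh
    mat dAlcat = dH * Zcat.t();                // M x (M*Q)
    mat dZcat = Alcat.t() * dH;                // (M*Q) x Fh
    for (uword q = 0; q < Q; ++q) {
      const mat& al = cc.alpha.slice(w * Q + q);
      const double* alp = al.memptr();
      const double* dalp = dAlcat.colptr(q * M); // M x M sub-block
      const double* s1 = cc.S1.colptr(q) + w * M;
      const double* s2 = cc.S2.colptr(q) + w * M;
      // softmax rows then LeakyReLU on the additive scores e_ij = s1_i+s2_j
      rs.zeros();
      for (uword e = 0; e < ne; ++e)
        rs(ei[e]) += alp[eidx[e]] * dalp[eidx[e]];
      ds1.zeros();
      ds2.zeros();
      for (uword e = 0; e < ne; ++e) {
        const uword i = ei[e], j = ej[e];
        double g = alp[eidx[e]] * (dalp[eidx[e]] - rs(i));
        g *= (s1[i] + s2[j]) > 0 ? 1.0 : slope;
        ds1(i) += g;
        ds2(j) += g;
      }
      // dZ_q = (alpha^T dH) + ds1 a1^T + ds2 a2^T; da += Z^T ds
      for (uword f = 0; f < Fh; ++f) {
        const double a1f = a1(f, q), a2f = a2(f, q);
        double* dzc = dZ.colptr(q * Fh + f) + w * M;
        const double* zc = cc.Z.colptr(q * Fh + f) + w * M;
        const double* dzcat = dZcat.colptr(f) + q * M;
        double g1 = 0, g2 = 0;
        for (uword i = 0; i < M; ++i) {
          dzc[i] = dzcat[i] + ds1(i) * a1f + ds2(i) * a2f;
          g1 += zc[i] * ds1(i);
          g2 += zc[i] * ds2(i);
        }
        da1(f, q) += g1;
        da2(f, q) += g2;
      }
    }
  }
  dW = Xs.t() * dZ;
  if (want_dx) return dZ * W.t();
  return mat();
}

// ---------------------------------------------------------------------------
// Transformer encoder, batched over samples: token matrices of all B
// sequences are stacked into (B*(N+1)) x D so LayerNorm/projection/MLP run
// as single GEMMs; only the tiny attention products loop per sample.

struct LnCache { mat xhat; vec inv; };

static mat ln_fwd(const mat& X, const vec& g, const vec& b, LnCache& c) {
  const uword n = X.n_rows, D = X.n_cols;
  c.xhat.set_size(n, D);
  c.inv.set_size(n);
  mat Y(n, D);
  for (uword i = 0; i < n; ++i) {
    double s = 0, s2 = 0;
    for (uword j = 0; j < D; ++j) { double x = X(i, j); s += x; s2 += x * x; }
    const double m = s / D;
    const double v = s2 / D - m * m;
    const double is = 1.0 / std::sqrt(v + 1e-5);
    c.inv(i) = is;
    for (uword j = 0; j < D; ++j) {
      const double xh = (X(i, j) - m) * is;
      c.xhat(i, j) = xh;
      Y(i, j) = xh * g(j) + b(j);
    }
  }
  return Y;
}

static mat ln_bwd(const mat& dY, const LnCache& c, const vec& g,
                  vec& dg, vec& db) {
  const uword n = dY.n_rows, D = dY.n_cols;
  mat dX(n, D);
  for (uword i = 0; i < n; ++i) {
    double m1 = 0, m2 = 0;
    for (uword j = 0; j < D; ++j) {
      const double dxh = dY(i, j) * g(j);
      m1 += dxh;
      m2 += dxh * c.xhat(i, j);
      dg(j) += dY(i, j) * c.xhat(i, j);
      db(j) += dY(i, j);
    }
    m1 /= D;
    m2 /= D;
    for (uword j = 0; j < D; ++j)
      dX(i, j) = c.inv(i) * (dY(i, j) * g(j) - m1 - c.xhat(i, j) * m2);
  }
  return dX;
}

struct BlockParams {
  vec ln1g, ln1b, bqkv, bo, ln2g, ln2b, b1, b2;
  mat Wqkv, Wo, W1, W2;
};

struct BlockCache {
  LnCache ln1, ln2;
  mat Y, QKV, O, H1, A, G, dropG;
  cube P; // n x n x (B*heads) attention probabilities
};

struct BlockGrads {
  vec ln1g, ln1b, bqkv, bo, ln2g, ln2b, b1, b2;
  mat Wqkv, Wo, W1, W2;
  void init(const BlockParams& p) {
    ln1g.zeros(p.ln1g.n_elem); ln1b.zeros(p.ln1b.n_elem);
    bqkv.zeros(p.bqkv.n_elem); bo.zeros(p.bo.n_elem);
    ln2g.zeros(p.ln2g.n_elem); ln2b.zeros(p.ln2b.n_elem);
    b1.zeros(p.b1.n_elem); b2.zeros(p.b2.n_elem);
    Wqkv.zeros(p.Wqkv.n_rows, p.Wqkv.n_cols);
    Wo.zeros(p.Wo.n_rows, p.Wo.n_cols);
    W1.zeros(p.W1.n_rows, p.W1.n_cols);
    W2.zeros(p.W2.n_rows, p.W2.n_cols);
  }
};

// Hall: (B*n) x D stacked token matrices, n = N+1 rows per sample
static mat block_fwd(const mat& Hall, const BlockParams& p, uword heads,
                     uword B, uword n, Dropout& dropo, BlockCache& c) {
  const uword D = Hall.n_cols, dh = D / heads;
  const double sc = 1.0 / std::sqrt((double)dh);
  c.Y = ln_fwd(Hall, p.ln1g, p.ln1b, c.ln1);
  c.QKV = c.Y * p.Wqkv;
  c.QKV.each_row() += p.bqkv.t();
  c.P.set_size(n, n, B * heads);
  c.O.set_size(Hall.n_rows, D);
  for (uword b = 0; b < B; ++b) {
    const uword r0 = b * n, r1 = r0 + n - 1;
    for (uword h = 0; h < heads; ++h) {
      mat Qh = c.QKV.submat(r0, h * dh, r1, h * dh + dh - 1);
      mat Kh = c.QKV.submat(r0, D + h * dh, r1, D + h * dh + dh - 1);
      mat Vh = c.QKV.submat(r0, 2 * D + h * dh, r1, 2 * D + h * dh + dh - 1);
      mat S = Qh * Kh.t() * sc;
      for (uword i = 0; i < n; ++i) {
        double mx = S.row(i).max();
        double Zs = 0;
        for (uword j = 0; j < n; ++j) {
          S(i, j) = std::exp(S(i, j) - mx);
          Zs += S(i, j);
        }
        S.row(i) /= Zs;
      }
      c.P.slice(b * heads + h) = S;
      c.O.submat(r0, h * dh, r1, h * dh + dh - 1) = S * Vh;
    }
  }
  mat attn = c.O * p.Wo;
  attn.each_row() += p.bo.t();
  c.H1 = Hall + attn;
  mat Y2 = ln_fwd(c.H1, p.ln2g, p.ln2b, c.ln2);
  c.A = Y2 * p.W1;
  c.A.each_row() += p.b1.t();
  c.G = c.A;
  c.G.transform([](double x) { return gelu1(x); });
  c.dropG.set_size(c.G.n_rows, c.G.n_cols);
  dropo.mask(c.dropG);
  c.G %= c.dropG;
  mat out = c.H1 + c.G * p.W2;
  out.each_row() += p.b2.t();
  return out;
}

static mat block_bwd(const mat& dOut, const BlockParams& p, uword heads,
                     uword B, uword n, const BlockCache& c, BlockGrads& g) {
  const uword D = dOut.n_cols, dh = D / heads;
  const double sc = 1.0 / std::sqrt((double)dh);
  // MLP branch
  g.b2 += arma::sum(dOut, 0).t();
  g.W2 += c.G.t() * dOut;
  mat dG = (dOut * p.W2.t()) % c.dropG;
  {
    double* d = dG.memptr();
    const double* a = c.A.memptr();
    for (uword i = 0; i < dG.n_elem; ++i) d[i] *= gelu1g(a[i]);
  }
  g.b1 += arma::sum(dG, 0).t();
  mat Y2 = c.ln2.xhat;
  Y2.each_row() %= p.ln2g.t();
  Y2.each_row() += p.ln2b.t();
  g.W1 += Y2.t() * dG;
  mat dY2 = dG * p.W1.t();
  mat dH1 = dOut + ln_bwd(dY2, c.ln2, p.ln2g, g.ln2g, g.ln2b);
  // MSA branch
  g.bo += arma::sum(dH1, 0).t();
  g.Wo += c.O.t() * dH1;
  mat dO = dH1 * p.Wo.t();
  mat dQKV(dOut.n_rows, 3 * D);
  for (uword b = 0; b < B; ++b) {
    const uword r0 = b * n, r1 = r0 + n - 1;
    for (uword h = 0; h < heads; ++h) {
      mat Qh = c.QKV.submat(r0, h * dh, r1, h * dh + dh - 1);
      mat Kh = c.QKV.submat(r0, D + h * dh, r1, D + h * dh + dh - 1);
      mat Vh = c.QKV.submat(r0, 2 * D + h * dh, r1, 2 * D + h * dh + dh - 1);
      mat dOh = dO.submat(r0, h * dh, r1, h * dh + dh - 1);
      const mat& P = c.P.slice(b * heads + h);
      mat dP = dOh * Vh.t();
      vec rs = arma::sum(P % dP, 1);
      mat tmp = dP;
      tmp.each_col() -= rs;
      mat dS = P % tmp;
      dQKV.submat(r0, h * dh, r1, h * dh + dh - 1) = dS * Kh * sc;
      dQKV.submat(r0, D + h * dh, r1, D + h * dh + dh - 1) = dS.t() * Qh * sc;
      dQKV.submat(r0, 2 * D + h * dh, r1, 2 * D + h * dh + dh - 1) =
        P.t() * dOh;
    }
  }
  g.bqkv += arma::sum(dQKV, 0).t();
  g.Wqkv += c.Y.t() * dQKV;
  mat dY = dQKV * p.Wqkv.t();
  return dH1 + ln_bwd(dY, c.ln1, p.ln1g, g.ln1g, g.ln1b);
}

// ---------------------------------------------------------------------------
// Full model

enum Mode { COMBINED, GAT_ONLY, TRANSFORMER_ONLY };

// [[Rcpp::export(name = ".engine_run")]]
List engine_run(List params, const arma::cube& Xbank, const arma::cube& Abank,
                const arma::umat& seq_idx, const arma::vec& mu,
                const arma::vec& sdv, const arma::ivec& y, List cfg) {
  const std::string mode_s = as<std::string>(cfg["mode"]);
  const Mode mode = mode_s == "combined" ? COMBINED :
    (mode_s == "gat_only" ? GAT_ONLY : TRANSFORMER_ONLY);
  const bool training = as<bool>(cfg["training"]);
  const bool want_grads = as<bool>(cfg["compute_grads"]);
  const double slope = as<double>(cfg["negative_slope"]);
  const double f_alpha = as<double>(cfg["focal_alpha"]);
  const double f_gamma = as<double>(cfg["focal_gamma"]);
  const double drop_rate = as<double>(cfg["dropout"]);
  const int act = as<int>(cfg["act"]);
  const uword heads_t = as<uword>(cfg["n_heads_t"]);
  Dropout dropo(as<double>(cfg["dropout_seed"]), drop_rate, training);

  const uword B = seq_idx.n_rows, N = seq_idx.n_cols;
  const uword M = Xbank.n_rows, F = Xbank.n_cols;
  const uword Wn = B * N;
  std::vector<uword> wins(Wn);
  for (uword b = 0; b < B; ++b)
    for (uword nn = 0; nn < N; ++nn)
      wins[b * N + nn] = seq_idx(b, nn) - 1; // R is 1-based

  // stack z-scored windows: rows [w*M, w*M+M) hold window w
  mat Xs(Wn * M, F);
  {
    vec inv_sd = 1.0 / sdv;
    for (uword w = 0; w < Wn; ++w) {
      const mat& src = Xbank.slice(wins[w]);
      for (uword f = 0; f < F; ++f) {
        double* dst = Xs.colptr(f) + w * M;
        const double* s = src.colptr(f);
        for (uword i = 0; i < M; ++i)
          dst[i] = (s[i] - mu(i)) * inv_sd(i);
      }
    }
  }

  // GAT encoder
  mat gW1, ga1_1, ga2_1, gW2, ga1_2, ga2_2, X1, X2;
  GatCache gc1, gc2;
  const bool use_gat = mode != TRANSFORMER_ONLY;
  if (use_gat) {
    gW1 = as<mat>(params["gW1"]);
    ga1_1 = as<mat>(params["ga1_1"]);
    ga2_1 = as<mat>(params["ga2_1"]);
    gW2 = as<mat>(params["gW2"]);
    ga1_2 = as<mat>(params["ga1_2"]);
    ga2_2 = as<mat>(params["ga2_2"]);
    X1 = gat_layer_fwd(Xs, Abank, wins, M, gW1, ga1_1, ga2_1, slope, act,
                       dropo, gc1);
    X2 = gat_layer_fwd(X1, Abank, wins, M, gW2, ga1_2, ga2_2, slope, act,
                       dropo, gc2);
  }

  vec p(B), loss_i(B);
  mat headW = as<mat>(params["headW"]);
  vec headb = as<vec>(params["headb"]);
  vec dz1(B); // gradient of mean loss w.r.t. seizure logit, per sample

  // --- gat_only: mean-pool nodes and windows, linear head ---
  if (mode == GAT_ONLY) {
    const uword F2 = X2.n_cols;
    mat pooled(B, F2);
    for (uword b = 0; b < B; ++b)
      pooled.row(b) = arma::mean(X2.rows(b * N * M, (b + 1) * N * M - 1), 0);
    mat Zl = pooled * headW;
    Zl.each_row() += headb.t();
    for (uword b = 0; b < B; ++b) {
      double mx = std::max(Zl(b, 0), Zl(b, 1));
      double e0 = std::exp(Zl(b, 0) - mx), e1 = std::exp(Zl(b, 1) - mx);
      p(b) = e1 / (e0 + e1);
    }
  }

  // --- transformer path (combined and transformer_only) ---
  mat E, Epos, Vmat, Hall, dropH, Hc;
  vec cls, lnfg, lnfb;
  std::vector<BlockParams> bp;
  std::vector<BlockCache> bcache;
  LnCache lnf_cache;
  uword L = 0, D = 0;
  const uword ntok = N + 1;
  if (mode != GAT_ONLY) {
    E = as<mat>(params["E"]);
    cls = as<vec>(params["cls"]);
    lnfg = as<vec>(params["lnfg"]);
    lnfb = as<vec>(params["lnfb"]);
    Epos = as<mat>(cfg["Epos"]);
    L = as<uword>(cfg["L"]);
    D = E.n_cols;
    bp.resize(L);
    bcache.resize(L);
    for (uword l = 0; l < L; ++l) {
      std::string pre = "b" + std::to_string(l) + "_";
      BlockParams& q = bp[l];
      q.ln1g = as<vec>(params[pre + "ln1g"]); q.ln1b = as<vec>(params[pre + "ln1b"]);
      q.Wqkv = as<mat>(params[pre + "Wqkv"]); q.bqkv = as<vec>(params[pre + "bqkv"]);
      q.Wo = as<mat>(params[pre + "Wo"]);     q.bo = as<vec>(params[pre + "bo"]);
      q.ln2g = as<vec>(params[pre + "ln2g"]); q.ln2b = as<vec>(params[pre + "ln2b"]);
      q.W1 = as<mat>(params[pre + "W1"]);     q.b1 = as<vec>(params[pre + "b1"]);
      q.W2 = as<mat>(params[pre + "W2"]);     q.b2 = as<vec>(params[pre + "b2"]);
    }
    // token inputs: flattened feature maps (col-major), stored transposed
    // (one contiguous column per window) to keep writes sequential
    const mat& src = use_gat ? X2 : Xs;
    const uword fdim = src.n_cols, in_dim = fdim * M;
    Vmat.set_size(in_dim, Wn);
    for (uword w = 0; w < Wn; ++w) {
      double* dst = Vmat.colptr(w);
      for (uword f = 0; f < fdim; ++f) {
        const double* s = src.colptr(f) + w * M;
        for (uword i = 0; i < M; ++i)
          dst[f * M + i] = s[i];
      }
    }
    mat Tok = Vmat.t() * E; // Wn x D
    Hall.set_size(B * ntok, D);
    for (uword b = 0; b < B; ++b) {
      for (uword j = 0; j < D; ++j)
        Hall(b * ntok, j) = cls(j) + Epos(0, j);
      for (uword nn = 0; nn < N; ++nn)
        for (uword j = 0; j < D; ++j)
          Hall(b * ntok + nn + 1, j) = Tok(b * N + nn, j) + Epos(nn + 1, j);
    }
    dropH.set_size(Hall.n_rows, D);
    dropo.mask(dropH);
    Hall %= dropH;
    mat H = Hall;
    for (uword l = 0; l < L; ++l)
      H = block_fwd(H, bp[l], heads_t, B, ntok, dropo, bcache[l]);
    // class-token rows through the final LayerNorm and linear head
    mat Hcls(B, D);
    for (uword b = 0; b < B; ++b) Hcls.row(b) = H.row(b * ntok);
    Hc = ln_fwd(Hcls, lnfg, lnfb, lnf_cache);
    mat Zl = Hc * headW;
    Zl.each_row() += headb.t();
    for (uword b = 0; b < B; ++b) {
      double mx = std::max(Zl(b, 0), Zl(b, 1));
      double e0 = std::exp(Zl(b, 0) - mx), e1 = std::exp(Zl(b, 1) - mx);
      p(b) = e1 / (e0 + e1);
    }
  }

  // focal loss and its gradient w.r.t. the seizure logit
  for (uword b = 0; b < B; ++b) {
    double pc = std::min(std::max(p(b), 1e-7), 1.0 - 1e-7);
    double dLdp;
    if (y(b) == 1) {
      loss_i(b) = -f_alpha * std::pow(1 - pc, f_gamma) * std::log(pc);
      dLdp = f_alpha * f_gamma * std::pow(1 - pc, f_gamma - 1) * std::log(pc)
           - f_alpha * std::pow(1 - pc, f_gamma) / pc;
    } else {
      loss_i(b) = -(1 - f_alpha) * std::pow(pc, f_gamma) * std::log(1 - pc);
      dLdp = -(1 - f_alpha) * f_gamma * std::pow(pc, f_gamma - 1) * std::log(1 - pc)
           + (1 - f_alpha) * std::pow(pc, f_gamma) / (1 - pc);
    }
    dz1(b) = dLdp * pc * (1 - pc) / (double)B;
  }
  const double loss = arma::mean(loss_i);

  List out = List::create(Named("loss") = loss,
                          Named("p") = NumericVector(p.begin(), p.end()));
  if (!want_grads) return out;

  // ------------------------------------------------------------------ backward
  List grads;
  mat dX2; // gradient into the GAT output stack
  mat dheadW(headW.n_rows, 2, arma::fill::zeros);
  vec dheadb(2, arma::fill::zeros);

  if (mode == GAT_ONLY) {
    const uword F2 = X2.n_cols;
    dX2.zeros(Wn * M, F2);
    for (uword b = 0; b < B; ++b) {
      arma::rowvec dz(2);
      dz(1) = dz1(b); dz(0) = -dz1(b);
      arma::rowvec pooled =
        arma::mean(X2.rows(b * N * M, (b + 1) * N * M - 1), 0);
      dheadW += pooled.t() * dz;
      dheadb += dz.t();
      arma::rowvec dpool = (headW * dz.t()).t() / (double)(N * M);
      dX2.rows(b * N * M, (b + 1) * N * M - 1).each_row() += dpool;
    }
  } else {
    vec dcls(D, arma::fill::zeros), dlnfg(D, arma::fill::zeros),
        dlnfb(D, arma::fill::zeros);
    std::vector<BlockGrads> bg(L);
    for (uword l = 0; l < L; ++l) bg[l].init(bp[l]);
    mat dZl(B, 2);
    for (uword b = 0; b < B; ++b) { dZl(b, 1) = dz1(b); dZl(b, 0) = -dz1(b); }
    dheadW += Hc.t() * dZl;
    dheadb += arma::sum(dZl, 0).t();
    mat dHc = ln_bwd(dZl * headW.t(), lnf_cache, lnfg, dlnfg, dlnfb);
    mat dH(B * ntok, D, arma::fill::zeros);
    for (uword b = 0; b < B; ++b) dH.row(b * ntok) = dHc.row(b);
    for (uword l = L; l-- > 0;)
      dH = block_bwd(dH, bp[l], heads_t, B, ntok, bcache[l], bg[l]);
    dH %= dropH;
    mat dTok(Wn, D);
    for (uword b = 0; b < B; ++b) {
      dcls += dH.row(b * ntok).t();
      for (uword nn = 0; nn < N; ++nn)
        dTok.row(b * N + nn) = dH.row(b * ntok + nn + 1);
    }
    grads["E"] = wrap(mat(Vmat * dTok));
    grads["cls"] = wrap(dcls);
    grads["lnfg"] = wrap(dlnfg);
    grads["lnfb"] = wrap(dlnfb);
    for (uword l = 0; l < L; ++l) {
      std::string pre = "b" + std::to_string(l) + "_";
      grads[pre + "ln1g"] = wrap(bg[l].ln1g); grads[pre + "ln1b"] = wrap(bg[l].ln1b);
      grads[pre + "Wqkv"] = wrap(bg[l].Wqkv); grads[pre + "bqkv"] = wrap(bg[l].bqkv);
      grads[pre + "Wo"] = wrap(bg[l].Wo);     grads[pre + "bo"] = wrap(bg[l].bo);
      grads[pre + "ln2g"] = wrap(bg[l].ln2g); grads[pre + "ln2b"] = wrap(bg[l].ln2b);
      grads[pre + "W1"] = wrap(bg[l].W1);     grads[pre + "b1"] = wrap(bg[l].b1);
      grads[pre + "W2"] = wrap(bg[l].W2);     grads[pre + "b2"] = wrap(bg[l].b2);
    }
    if (use_gat) {
      // unflatten token gradients back onto the GAT output stack
      mat dVmat = E * dTok.t(); // in_dim x Wn, contiguous per window
      const uword F2 = X2.n_cols;
      dX2.set_size(Wn * M, F2);
      for (uword w = 0; w < Wn; ++w) {
        const double* s = dVmat.colptr(w);
        for (uword f = 0; f < F2; ++f) {
          double* d = dX2.colptr(f) + w * M;
          for (uword i = 0; i < M; ++i)
            d[i] = s[f * M + i];
        }
      }
    }
  }
  grads["headW"] = wrap(dheadW);
  grads["headb"] = wrap(dheadb);

  if (use_gat) {
    mat dgW2, dga1_2, dga2_2, dgW1, dga1_1, dga2_1;
    mat dX1 = gat_layer_bwd(dX2, X1, Abank, wins, M, gW2, ga1_2, ga2_2, slope,
                            act, gc2, dgW2, dga1_2, dga2_2, true);
    gat_layer_bwd(dX1, Xs, Abank, wins, M, gW1, ga1_1, ga2_1, slope,
                  act, gc1, dgW1, dga1_1, dga2_1, false);
    grads["gW1"] = wrap(dgW1);
    grads["ga1_1"] = wrap(dga1_1);
    grads["ga2_1"] = wrap(dga2_1);
    grads["gW2"] = wrap(dgW2);
    grads["ga1_2"] = wrap(dga1_2);
    grads["ga2_2"] = wrap(dga2_2);
  }
  out["grads"] = grads;
  return out;
}
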