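// Core numerics for the BSLMM sampler.
//
// Everything works in the kinship eigenbasis: with K = U diag(delta) U',
// yt = U'y, onest = U'1 and xt_j = U'x_j, the model covariance
// tau^{-1} (sigma_b2 K + I) becomes diagonal with weights
// d_i = 1/(sigma_b2 delta_i + 1).  The sparse effects beta_gamma
// (prior N(0, sigma_a2/tau)), the intercept mu (flat prior) and the
// residual precision tau (improper Gamma limit, p(tau) ~ 1/tau) are
// integrated out analytically, giving for a configuration gamma with
// q = |gamma| columns X (here already transformed and d-weighted through
// the inner products below):
//
//   log P(y | gamma, sigma_a2, sigma_b2)
//     = c0 + 1/2 sum_i log d_i - 1/2 log(s11) - 1/2 log det(A)
//       - (q/2) log sigma_a2 - (n-1)/2 log S
//
// with s11 = <1,1>_d, A = Gram_c + sigma_a2^{-1} I where Gram_c is the
// d-weighted Gram matrix of the gamma columns projected orthogonally to
// the intercept, S the GLS residual sum of squares after solving for
// beta, and c0 = -(n-1)/2 log(2 pi) + lgamma((n-1)/2) + (n-1)/2 log 2.
// The expression is fully normalized, so it can be compared directly
// against quadrature over (beta, mu, log tau) with the same priors.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double LOG2PI = 1.837877066409345483560659472811;

// ---------------------------------------------------------------------------
// d-weighted summary statistics
// ---------------------------------------------------------------------------

struct DStats {
  arma::vec d;
  double sumlogd, s11, oy, yy;
};

static void compute_dstats(DStats &ds, const arma::vec &delta,
                           const arma::vec &yt, const arma::vec &onest,
                           double sigma_b2) {
  ds.d = 1.0 / (sigma_b2 * delta + 1.0);
  ds.sumlogd = arma::accu(arma::log(ds.d));
  ds.s11 = arma::dot(ds.d, arma::square(onest));
  ds.oy  = arma::dot(ds.d % onest, yt);
  ds.yy  = arma::dot(ds.d, arma::square(yt));
}

// Weighted per-configuration statistics for the included columns.
struct GammaStats {
  std::vector<int> gidx;   // 0-based marker indices (column order)
  arma::vec Xy, Xo;        // <x_j, y>_d, <x_j, 1>_d
  arma::mat Gram;          // <x_j, x_k>_d
};

static void rebuild_gamma_stats(GammaStats &gs, const arma::mat &UtX,
                                const DStats &ds, const arma::vec &yt,
                                const arma::vec &onest,
                                const arma::mat *Xt_pre = nullptr) {
  const int q = (int) gs.gidx.size();
  if (q == 0) {
    gs.Xy.set_size(0); gs.Xo.set_size(0); gs.Gram.set_size(0, 0);
    return;
  }
  arma::mat Xc;
  const arma::mat *X = Xt_pre;
  if (!X) {
    arma::uvec cols(q);
    for (int k = 0; k < q; ++k) cols[k] = (arma::uword) gs.gidx[k];
    Xc = UtX.cols(cols);
    X = &Xc;
  }
  arma::vec sd = arma::sqrt(ds.d);
  arma::mat Xw = X->each_col() % sd;
  gs.Gram = Xw.t() * Xw;
  gs.Xy = X->t() * (ds.d % yt);
  gs.Xo = X->t() * (ds.d % onest);
}

// Append marker j with precomputed cross terms against the current columns.
static void stats_add_with_cross(GammaStats &gs, const arma::vec &cross,
                                 double gjj, double xy, double xo, int j) {
  const int q = (int) gs.gidx.size();
  gs.Gram.resize(q + 1, q + 1);
  for (int k = 0; k < q; ++k) { gs.Gram(k, q) = cross[k]; gs.Gram(q, k) = cross[k]; }
  gs.Gram(q, q) = gjj;
  gs.Xy.resize(q + 1); gs.Xy[q] = xy;
  gs.Xo.resize(q + 1); gs.Xo[q] = xo;
  gs.gidx.push_back(j);
}

// Append marker j to the configuration, under weights ds.d (gathers the
// existing columns from UtX; used on the compound-move replay path).
static void stats_add(GammaStats &gs, const arma::mat &UtX, const DStats &ds,
                      const arma::vec &yt, const arma::vec &onest, int j) {
  const int q = (int) gs.gidx.size();
  arma::vec v = ds.d % UtX.col(j);
  arma::vec cross(q);
  for (int k = 0; k < q; ++k) cross[k] = arma::dot(UtX.col(gs.gidx[k]), v);
  stats_add_with_cross(gs, cross, arma::dot(UtX.col(j), v),
                       arma::dot(v, yt), arma::dot(v, onest), j);
}

// Remove the column at position pos.
static void stats_remove(GammaStats &gs, int pos) {
  gs.Gram.shed_row(pos); gs.Gram.shed_col(pos);
  gs.Xy.shed_row(pos); gs.Xo.shed_row(pos);
  gs.gidx.erase(gs.gidx.begin() + pos);
}

// ---------------------------------------------------------------------------
// marginal likelihood
// ---------------------------------------------------------------------------

struct LogMLOut {
  double logml;
  bool ok;
};

static LogMLOut logml_stats(int n, const DStats &ds, const GammaStats &gs,
                            double sigma_a2) {
  LogMLOut out; out.ok = true;
  const double c0 = -0.5 * (n - 1) * LOG2PI + std::lgamma(0.5 * (n - 1)) +
                    0.5 * (n - 1) * std::log(2.0);
  const double yPy = ds.yy - ds.oy * ds.oy / ds.s11;
  const int q = (int) gs.gidx.size();
  if (q == 0 || sigma_a2 <= 0.0) {
    if (yPy <= 0.0) { out.ok = false; out.logml = -HUGE_VAL; return out; }
    out.logml = c0 + 0.5 * ds.sumlogd - 0.5 * std::log(ds.s11) -
                0.5 * (n - 1) * std::log(yPy);
    return out;
  }
  arma::mat A = gs.Gram - (gs.Xo * gs.Xo.t()) / ds.s11;
  A.diag() += 1.0 / sigma_a2;
  arma::vec b = gs.Xy - gs.Xo * (ds.oy / ds.s11);
  arma::mat R;
  if (!arma::chol(R, A)) { out.ok = false; out.logml = -HUGE_VAL; return out; }
  arma::vec z = arma::solve(arma::trimatl(R.t()), b);
  double S = yPy - arma::dot(z, z);
  if (!(S > 0.0)) { out.ok = false; out.logml = -HUGE_VAL; return out; }
  double logdetA = 2.0 * arma::accu(arma::log(R.diag()));
  out.logml = c0 + 0.5 * ds.sumlogd - 0.5 * std::log(ds.s11) - 0.5 * logdetA -
              0.5 * q * std::log(sigma_a2) - 0.5 * (n - 1) * std::log(S);
  return out;
}

// [[Rcpp::export]]
double cpp_logml(const arma::vec &yt, const arma::vec &onest,
                 const arma::vec &delta, const arma::mat &Xt,
                 double sigma_a2, double sigma_b2) {
  const int n = (int) yt.n_elem;
  DStats ds; compute_dstats(ds, delta, yt, onest, sigma_b2);
  GammaStats gs;
  const int q = (int) Xt.n_cols;
  gs.gidx.resize(q);
  for (int k = 0; k < q; ++k) gs.gidx[k] = k;
  if (q > 0) {
    arma::vec sd = arma::sqrt(ds.d);
    arma::mat Xw = Xt.each_col() % sd;
    gs.Gram = Xw.t() * Xw;
    gs.Xy = Xt.t() * (ds.d % yt);
    gs.Xo = Xt.t() * (ds.d % onest);
  }
  LogMLOut out = logml_stats(n, ds, gs, sigma_a2);
  if (!out.ok) stop("marginal likelihood evaluation failed (singular system or non-positive residual); try a smaller model or larger sigma_a2");
  return out.logml;
}

// ---------------------------------------------------------------------------
// conditional draws of (tau, mu, beta, u) given (gamma, hyper, y)
// ---------------------------------------------------------------------------

struct EffectDraw {
  double tau, mu, pve, pge;
  arma::vec beta;   // length q (empty if none)
  arma::vec gt;     // transformed sparse component X_t beta
  arma::vec ut;     // transformed random effects
};

static void sample_effects_stats(EffectDraw &out, int n, const DStats &ds,
                                 const GammaStats &gs, const arma::mat &UtX,
                                 const arma::vec &yt, const arma::vec &onest,
                                 const arma::vec &delta, double sigma_a2,
                                 double sigma_b2, const arma::mat *Xt_direct) {
  int q = (int) gs.gidx.size();
  if (sigma_a2 <= 0.0) q = 0;
  arma::mat M(q + 1, q + 1);
  arma::vec rhs(q + 1);
  M(0, 0) = ds.s11; rhs[0] = ds.oy;
  if (q > 0) {
    M.submat(1, 1, q, q) = gs.Gram;
    M.submat(1, 1, q, q).diag() += 1.0 / sigma_a2;
    M.submat(1, 0, q, 0) = gs.Xo;
    M.submat(0, 1, 0, q) = gs.Xo.t();
    rhs.subvec(1, q) = gs.Xy;
  }
  arma::mat R;
  if (!arma::chol(R, M)) stop("conditional effect sampling: Cholesky failure");
  arma::vec that = arma::solve(arma::trimatu(R),
                               arma::solve(arma::trimatl(R.t()), rhs));
  double S = ds.yy - arma::dot(rhs, that);
  if (S <= 0.0) S = std::numeric_limits<double>::min();
  out.tau = ::Rf_rgamma(0.5 * (n - 1), 2.0 / S);
  arma::vec zdraw(q + 1);
  for (int k = 0; k <= q; ++k) zdraw[k] = ::norm_rand();
  arma::vec theta = that + arma::solve(arma::trimatu(R), zdraw) / std::sqrt(out.tau);
  out.mu = theta[0];
  out.gt.zeros(n);
  if (q > 0) {
    out.beta = theta.subvec(1, q);
    if (Xt_direct) {
      out.gt = (*Xt_direct) * out.beta;
    } else {
      arma::uvec cols(q);
      for (int k = 0; k < q; ++k) cols[k] = (arma::uword) gs.gidx[k];
      out.gt = UtX.cols(cols) * out.beta;
    }
  } else {
    out.beta.set_size(0);
  }
  // u | rest: coordinatewise in the eigenbasis
  out.ut.zeros(n);
  if (sigma_b2 > 0.0) {
    arma::vec rt = yt - onest * out.mu - out.gt;
    for (int i = 0; i < n; ++i) {
      double a = sigma_b2 * delta[i] * ds.d[i];
      out.ut[i] = a * rt[i] + ::norm_rand() * std::sqrt(a / out.tau);
    }
  }
  // PVE / PGE of this draw; V(x) = |x|^2/n - mean(x)^2, computable in the
  // transformed basis because U is orthonormal and 1'x = onest' xt.
  arma::vec tot = out.gt + out.ut;
  double mtot = arma::dot(onest, tot) / n;
  double Vtot = arma::dot(tot, tot) / n - mtot * mtot;
  if (Vtot < 0) Vtot = 0;
  double mg = arma::dot(onest, out.gt) / n;
  double Vg = arma::dot(out.gt, out.gt) / n - mg * mg;
  if (Vg < 0) Vg = 0;
  out.pve = Vtot / (Vtot + 1.0 / out.tau);
  out.pge = (Vtot > 0) ? Vg / Vtot : 0.0;
  if (out.pge > 1.0) out.pge = 1.0;
  if (out.pge < 0.0) out.pge = 0.0;
}

// [[Rcpp::export]]
List cpp_sample_effects(const arma::vec &yt, const arma::vec &onest,
                        const arma::vec &delta, const arma::mat &Xt,
                        double sigma_a2, double sigma_b2, int ndraws) {
  const int n = (int) yt.n_elem;
  const int q = (int) Xt.n_cols;
  DStats ds; compute_dstats(ds, delta, yt, onest, sigma_b2);
  GammaStats gs;
  gs.gidx.resize(q);
  for (int k = 0; k < q; ++k) gs.gidx[k] = k;
  if (q > 0) {
    arma::vec sd = arma::sqrt(ds.d);
    arma::mat Xw = Xt.each_col() % sd;
    gs.Gram = Xw.t() * Xw;
    gs.Xy = Xt.t() * (ds.d % yt);
    gs.Xo = Xt.t() * (ds.d % onest);
  }
  arma::vec tau(ndraws), mu(ndraws), pve(ndraws), pge(ndraws);
  arma::mat beta(ndraws, q), ut(ndraws, n), gt(ndraws, n);
  EffectDraw drw;
  for (int it = 0; it < ndraws; ++it) {
    sample_effects_stats(drw, n, ds, gs, Xt, yt, onest, delta, sigma_a2,
                         sigma_b2, &Xt);
    tau[it] = drw.tau; mu[it] = drw.mu; pve[it] = drw.pve; pge[it] = drw.pge;
    if (q > 0 && drw.beta.n_elem == (arma::uword) q) beta.row(it) = drw.beta.t();
    else if (q > 0) beta.row(it).zeros();
    ut.row(it) = drw.ut.t();
    gt.row(it) = drw.gt.t();
  }
  return List::create(_["tau"] = tau, _["mu"] = mu, _["beta"] = beta,
                      _["ut"] = ut, _["gt"] = gt, _["pve"] = pve,
                      _["pge"] = pge);
}

// ---------------------------------------------------------------------------
// rank-based gamma proposals
// ---------------------------------------------------------------------------

struct ProposalCfg {
  double p_add, p_remove, p_swap;
  double kappa;        // geometric decay per rank
  double unif_mix;     // weight of the uniform component of the add kernel
  double long_range_prob;
  int compound_max;
  int qcap;
};

struct GammaState {
  std::vector<int> gidx;
  std::vector<char> incl;  // length p
};

// Move-type probabilities given current q (p = number of markers).
static void move_type_probs(const ProposalCfg &cfg, int q, int p,
                            double &pa, double &pr, double &ps) {
  bool can_add = q < p;
  bool can_rem = q > 0;
  bool can_swap = can_add && can_rem;
  double wa = can_add ? cfg.p_add : 0.0;
  double wr = can_rem ? cfg.p_remove : 0.0;
  double ws = can_swap ? cfg.p_swap : 0.0;
  double tot = wa + wr + ws;
  pa = wa / tot; pr = wr / tot; ps = ws / tot;
}

// Normalizer of the geometric component over excluded markers.
static double geom_z_excluded(const GammaState &st,
                              const std::vector<double> &geomw,
                              const std::vector<int> &rank_order) {
  double z = 0.0;
  const int p = (int) rank_order.size();
  for (int k = 0; k < p; ++k) {
    int j = rank_order[k];
    if (!st.incl[j]) z += geomw[k];
  }
  return z;
}

// log P(select j to add | state); m = number excluded.
static double log_add_select_prob(const GammaState &st, int j,
                                  const ProposalCfg &cfg,
                                  const std::vector<double> &geomw,
                                  const std::vector<int> &rank_order,
                                  const std::vector<int> &rank_of) {
  const int p = (int) rank_order.size();
  const int m = p - (int) st.gidx.size();
  double zex = geom_z_excluded(st, geomw, rank_order);
  double pr;
  if (zex > 0.0)
    pr = cfg.unif_mix / m + (1.0 - cfg.unif_mix) * geomw[rank_of[j]] / zex;
  else
    pr = 1.0 / m;
  return std::log(pr);
}

// Draw a marker to add. Uses R's RNG.
static int draw_add_marker(const GammaState &st, const ProposalCfg &cfg,
                           const std::vector<double> &geomw,
                           const std::vector<int> &rank_order) {
  const int p = (int) rank_order.size();
  double zex = geom_z_excluded(st, geomw, rank_order);
  bool use_unif = (zex <= 0.0) || (::unif_rand() < cfg.unif_mix);
  if (use_unif) {
    for (;;) {
      int j = (int) std::floor(::unif_rand() * p);
      if (j >= p) j = p - 1;
      if (!st.incl[j]) return j;
    }
  }
  double target = ::unif_rand() * zex;
  double acc = 0.0;
  int last = -1;
  for (int k = 0; k < p; ++k) {
    int j = rank_order[k];
    if (st.incl[j]) continue;
    last = j;
    acc += geomw[k];
    if (acc >= target) return j;
  }
  return last;  // fp guard
}

enum StepType { STEP_ADD = 0, STEP_REMOVE = 1, STEP_SWAP = 2 };

struct Step {
  StepType type;
  int add_j;    // marker added (ADD, SWAP)
  int rem_pos;  // position removed in gidx at time of step (REMOVE, SWAP)
  int rem_j;    // marker removed
};

// Perform one elementary move on st (in place), returning the step taken and
// accumulating the log proposal-density ratio (reverse minus forward).
static bool single_gamma_move(GammaState &st, const ProposalCfg &cfg,
                              const std::vector<double> &geomw,
                              const std::vector<int> &rank_order,
                              const std::vector<int> &rank_of,
                              Step &step, double &logratio) {
  const int p = (int) rank_order.size();
  int q = (int) st.gidx.size();
  double pa, pr, ps;
  move_type_probs(cfg, q, p, pa, pr, ps);
  double u = ::unif_rand();
  if (u < pa) {
    // ADD
    int j = draw_add_marker(st, cfg, geomw, rank_order);
    double lfwd = std::log(pa) + log_add_select_prob(st, j, cfg, geomw, rank_order, rank_of);
    st.incl[j] = 1; st.gidx.push_back(j);
    double pa2, pr2, ps2;
    move_type_probs(cfg, q + 1, p, pa2, pr2, ps2);
    double lrev = std::log(pr2) - std::log((double) (q + 1));
    logratio += lrev - lfwd;
    step.type = STEP_ADD; step.add_j = j; step.rem_pos = -1; step.rem_j = -1;
    return true;
  } else if (u < pa + pr) {
    // REMOVE
    int pos = (int) std::floor(::unif_rand() * q);
    if (pos >= q) pos = q - 1;
    int j = st.gidx[pos];
    double lfwd = std::log(pr) - std::log((double) q);
    st.incl[j] = 0; st.gidx.erase(st.gidx.begin() + pos);
    double pa2, pr2, ps2;
    move_type_probs(cfg, q - 1, p, pa2, pr2, ps2);
    double lrev = std::log(pa2) + log_add_select_prob(st, j, cfg, geomw, rank_order, rank_of);
    logratio += lrev - lfwd;
    step.type = STEP_REMOVE; step.add_j = -1; step.rem_pos = pos; step.rem_j = j;
    return true;
  } else {
    // SWAP: remove uniform i, add j from the add kernel of the current state
    int pos = (int) std::floor(::unif_rand() * q);
    if (pos >= q) pos = q - 1;
    int i = st.gidx[pos];
    int j = draw_add_marker(st, cfg, geomw, rank_order);
    double lfwd = std::log(ps) - std::log((double) q) +
                  log_add_select_prob(st, j, cfg, geomw, rank_order, rank_of);
    st.incl[i] = 0; st.gidx.erase(st.gidx.begin() + pos);
    st.incl[j] = 1; st.gidx.push_back(j);
    // reverse swap: pick j (uniform over q), then add i
    double lrev = std::log(ps) - std::log((double) q) +
                  log_add_select_prob(st, i, cfg, geomw, rank_order, rank_of);
    logratio += lrev - lfwd;
    step.type = STEP_SWAP; step.add_j = j; step.rem_pos = pos; step.rem_j = i;
    return true;
  }
}

// Full gamma proposal, possibly compound. Returns false if the proposal must
// be auto-rejected (q exceeded the soft cap at some point).
static bool propose_gamma_state(GammaState &st, const ProposalCfg &cfg,
                                const std::vector<double> &geomw,
                                const std::vector<int> &rank_order,
                                const std::vector<int> &rank_of,
                                std::vector<Step> &steps, double &logratio,
                                bool &compound) {
  steps.clear();
  logratio = 0.0;
  int L = 1;
  compound = false;
  if (cfg.long_range_prob > 0.0 && ::unif_rand() < cfg.long_range_prob) {
    L = 2 + (int) std::floor(::unif_rand() * (cfg.compound_max - 1));
    if (L > cfg.compound_max) L = cfg.compound_max;
    compound = true;
  }
  bool ok = true;
  for (int s = 0; s < L; ++s) {
    Step stp;
    single_gamma_move(st, cfg, geomw, rank_order, rank_of, stp, logratio);
    steps.push_back(stp);
    if ((int) st.gidx.size() > cfg.qcap) ok = false;  // soft cap: auto-reject
  }
  return ok;
}

static ProposalCfg cfg_from_list(const List &cfg, int p, int n) {
  ProposalCfg c;
  c.p_add = as<double>(cfg["p_add"]);
  c.p_remove = as<double>(cfg["p_remove"]);
  c.p_swap = as<double>(cfg["p_swap"]);
  c.kappa = as<double>(cfg["geometric_rank_param"]);
  c.unif_mix = as<double>(cfg["unif_mix"]);
  c.long_range_prob = as<double>(cfg["long_range_prob"]);
  c.compound_max = as<int>(cfg["compound_max"]);
  int qcap = as<int>(cfg["qcap"]);
  int qmax = std::min(n - 2, qcap);
  if (qmax > p) qmax = p;
  c.qcap = qmax;
  return c;
}

static void make_rank_tables(const std::vector<int> &rank_order, double kappa,
                             std::vector<int> &rank_of,
                             std::vector<double> &geomw) {
  const int p = (int) rank_order.size();
  rank_of.assign(p, 0);
  geomw.assign(p, 0.0);
  double w = 1.0;
  for (int k = 0; k < p; ++k) {
    rank_of[rank_order[k]] = k;
    geomw[k] = w;
    w *= kappa;
  }
}

// [[Rcpp::export]]
List cpp_propose_gamma(const IntegerVector &gamma1, int p,
                       const IntegerVector &rank_order1, const List &cfg,
                       int n) {
  std::vector<int> rank_order(p);
  for (int k = 0; k < p; ++k) rank_order[k] = rank_order1[k] - 1;
  ProposalCfg c = cfg_from_list(cfg, p, n);
  std::vector<int> rank_of; std::vector<double> geomw;
  make_rank_tables(rank_order, c.kappa, rank_of, geomw);
  GammaState st;
  st.incl.assign(p, 0);
  for (int k = 0; k < gamma1.size(); ++k) {
    st.gidx.push_back(gamma1[k] - 1);
    st.incl[gamma1[k] - 1] = 1;
  }
  std::vector<Step> steps; double logratio; bool compound;
  bool ok = propose_gamma_state(st, c, geomw, rank_order, rank_of, steps,
                                logratio, compound);
  IntegerVector out(st.gidx.size());
  for (size_t k = 0; k < st.gidx.size(); ++k) out[k] = st.gidx[k] + 1;
  return List::create(_["gamma"] = out, _["log_ratio"] = logratio,
                      _["valid"] = ok, _["compound"] = compound,
                      _["n_steps"] = (int) steps.size());
}

// log-density of proposing `to` from `from` in a single elementary move
// (type inferred from the set difference). Used by detailed-balance tests.
// [[Rcpp::export]]
double cpp_gamma_logdensity(const IntegerVector &from1,
                            const IntegerVector &to1, int p,
                            const IntegerVector &rank_order1, const List &cfg,
                            int n) {
  std::vector<int> rank_order(p);
  for (int k = 0; k < p; ++k) rank_order[k] = rank_order1[k] - 1;
  ProposalCfg c = cfg_from_list(cfg, p, n);
  std::vector<int> rank_of; std::vector<double> geomw;
  make_rank_tables(rank_order, c.kappa, rank_of, geomw);
  GammaState st;
  st.incl.assign(p, 0);
  for (int k = 0; k < from1.size(); ++k) {
    st.gidx.push_back(from1[k] - 1);
    st.incl[from1[k] - 1] = 1;
  }
  std::vector<char> into(p, 0);
  for (int k = 0; k < to1.size(); ++k) into[to1[k] - 1] = 1;
  std::vector<int> added, removed;
  for (int j = 0; j < p; ++j) {
    if (into[j] && !st.incl[j]) added.push_back(j);
    if (!into[j] && st.incl[j]) removed.push_back(j);
  }
  int q = (int) st.gidx.size();
  double pa, pr, ps;
  move_type_probs(c, q, p, pa, pr, ps);
  if (added.size() == 1 && removed.empty()) {
    return std::log(pa) + log_add_select_prob(st, added[0], c, geomw,
                                              rank_order, rank_of);
  } else if (removed.size() == 1 && added.empty()) {
    return std::log(pr) - std::log((double) q);
  } else if (added.size() == 1 && removed.size() == 1) {
    return std::log(ps) - std::log((double) q) +
           log_add_select_prob(st, added[0], c, geomw, rank_order, rank_of);
  }
  return R_NegInf;  // not reachable in one elementary move
}

// ---------------------------------------------------------------------------
// the sampler
// ---------------------------------------------------------------------------

static double reflect_into(double x, double lo, double hi) {
  const double w = hi - lo;
  if (w <= 0) return lo;
  double s = (x - lo) / (2.0 * w);
  double t = (s - std::floor(s)) * 2.0 * w;
  return (t <= w) ? lo + t : hi - (t - w);
}

// gamma prior: q log(pi) + (p-q) log(1-pi)
static double log_prior_gamma(int q, int p, double logpi) {
  double pi = std::exp(logpi);
  if (pi >= 1.0) return (q == p) ? 0.0 : -HUGE_VAL;
  return q * logpi + (p - q) * std::log1p(-pi);
}

// [[Rcpp::export]]
List cpp_bslmm_mcmc(const arma::vec &yt, const arma::vec &onest,
                    const arma::vec &delta, const arma::mat &UtX,
                    double s_a, double s_b,
                    const IntegerVector &rank_order1,
                    const IntegerVector &init_gamma1,
                    double h0, double rho0, double logpi0,
                    const List &cfg) {
  const int n = (int) yt.n_elem;
  const int p = (int) UtX.n_cols;

  // chain config
  const int n_iter = as<int>(cfg["n_iter"]);
  const int burn_in = as<int>(cfg["burn_in"]);
  const int thin = as<int>(cfg["thin"]);
  const double hyper_prob_cfg = as<double>(cfg["hyper_move_prob"]);
  const double hstep = as<double>(cfg["h_step"]);
  const double rstep = as<double>(cfg["rho_step"]);
  const double pistep = as<double>(cfg["logpi_step"]);
  const bool fix_h = as<bool>(cfg["fix_h"]);
  const bool fix_rho = as<bool>(cfg["fix_rho"]);
  const bool fix_logpi = as<bool>(cfg["fix_logpi"]);
  const bool fix_gamma = as<bool>(cfg["fix_gamma"]);
  const bool eb_mode = as<bool>(cfg["eb_mode"]);
  const double sigma_b2_fixed = as<double>(cfg["sigma_b2_fixed"]);
  const bool record_effects = as<bool>(cfg["record_effects"]);
  const double logpi_min = std::log(1.0 / p);

  ProposalCfg pcfg = cfg_from_list(cfg, p, n);
  std::vector<int> rank_order(p);
  for (int k = 0; k < p; ++k) rank_order[k] = rank_order1[k] - 1;
  std::vector<int> rank_of; std::vector<double> geomw;
  make_rank_tables(rank_order, pcfg.kappa, rank_of, geomw);

  double hyper_prob = hyper_prob_cfg;
  if (fix_gamma) hyper_prob = 1.0;
  if (fix_h && fix_rho && fix_logpi && !eb_mode) hyper_prob = 0.0;

  // hyper -> variances
  auto derive_variances = [&](double h, double rho, double logpi,
                              double &sa2, double &sb2) {
    double G = h / (1.0 - h);
    double pi = std::exp(logpi);
    sa2 = (rho > 0.0) ? rho * G / (p * pi * s_a) : 0.0;
    sb2 = (rho < 1.0) ? (1.0 - rho) * G / s_b : 0.0;
    if (eb_mode) sb2 = sigma_b2_fixed;
  };

  // state
  double h = h0, rho = rho0, logpi = logpi0;
  double sigma_a2, sigma_b2;
  derive_variances(h, rho, logpi, sigma_a2, sigma_b2);

  GammaState gstate;
  gstate.incl.assign(p, 0);
  for (int k = 0; k < init_gamma1.size(); ++k) {
    gstate.gidx.push_back(init_gamma1[k] - 1);
    gstate.incl[init_gamma1[k] - 1] = 1;
  }

  DStats ds; compute_dstats(ds, delta, yt, onest, sigma_b2);
  GammaStats gs;
  gs.gidx = gstate.gidx;
  rebuild_gamma_stats(gs, UtX, ds, yt, onest);
  // contiguous copy of the included (transformed, unweighted) columns,
  // kept in step with gs.gidx; weight-independent, so hyper moves reuse it
  arma::mat Xt(n, (arma::uword) gs.gidx.size());
  for (size_t k = 0; k < gs.gidx.size(); ++k) Xt.col(k) = UtX.col(gs.gidx[k]);

  LogMLOut ml = logml_stats(n, ds, gs, sigma_a2);
  if (!ml.ok) stop("non-finite marginal likelihood at initialization");
  double cur_logml = ml.logml;
  double cur_lpg = log_prior_gamma((int) gs.gidx.size(), p, logpi);

  // recording
  const int n_keep = (n_iter + thin - 1) / thin;
  arma::vec rec_h(n_keep), rec_rho(n_keep), rec_logpi(n_keep),
      rec_pve(n_keep), rec_pge(n_keep), rec_mu(n_keep), rec_tau(n_keep),
      rec_sa2(n_keep), rec_sb2(n_keep);
  arma::ivec rec_q(n_keep);
  arma::vec incl_count(p, arma::fill::zeros), beta_sum(p, arma::fill::zeros),
      beta_abs_sum(p, arma::fill::zeros);
  std::vector<int> eff_draw_id; std::vector<int> eff_marker;
  std::vector<double> eff_beta;

  long acc_gamma = 0, try_gamma = 0, acc_hyper = 0, try_hyper = 0,
       acc_comp = 0, try_comp = 0, n_capped = 0;

  GammaState cand;
  GammaStats cgs;
  DStats cds;
  EffectDraw drw;
  int kept = 0;
  const long total_iter = (long) burn_in + n_iter;

  for (long iter = 0; iter < total_iter; ++iter) {
    bool do_hyper = (::unif_rand() < hyper_prob);
    if (do_hyper) {
      ++try_hyper;
      // a share of hyper moves updates log pi alone: sigma_b2 is unchanged
      // there, so no reweighting of the Gram matrix is needed (cheap move)
      double pi_only_prob = fix_logpi ? 0.0
          : ((fix_h && (fix_rho || eb_mode)) ? 1.0 : (1.0 / 3.0));
      bool pi_only = (::unif_rand() < pi_only_prob);
      double h_p = h, rho_p = rho, logpi_p = logpi;
      if (!fix_h && !pi_only)
        h_p = reflect_into(h + hstep * (2.0 * ::unif_rand() - 1.0), 0.0, 1.0);
      if (!fix_rho && !eb_mode && !pi_only)
        rho_p = reflect_into(rho + rstep * (2.0 * ::unif_rand() - 1.0), 0.0, 1.0);
      if (!fix_logpi)
        logpi_p = reflect_into(logpi + pistep * (2.0 * ::unif_rand() - 1.0),
                               logpi_min, 0.0);
      bool valid = (h_p > 0.0 && h_p < 1.0);
      if (eb_mode && valid) {
        // sigma_b2 pinned: rho is the derived coordinate
        double G = h_p / (1.0 - h_p);
        rho_p = 1.0 - sigma_b2_fixed * s_b / G;
        if (rho_p < 0.0 || rho_p > 1.0) valid = false;
      }
      if (valid) {
        double sa2_p, sb2_p;
        derive_variances(h_p, rho_p, logpi_p, sa2_p, sb2_p);
        const DStats *dsp = &ds;
        const GammaStats *gsp = &gs;
        bool reweighted = false;
        if (sb2_p != sigma_b2) {
          compute_dstats(cds, delta, yt, onest, sb2_p);
          cgs.gidx = gs.gidx;
          rebuild_gamma_stats(cgs, UtX, cds, yt, onest, &Xt);
          dsp = &cds; gsp = &cgs; reweighted = true;
        }
        LogMLOut mlp = logml_stats(n, *dsp, *gsp, sa2_p);
        double lpg_p = log_prior_gamma((int) gs.gidx.size(), p, logpi_p);
        if (mlp.ok) {
          double lalpha = (mlp.logml + lpg_p) - (cur_logml + cur_lpg);
          if (lalpha >= 0.0 || ::unif_rand() < std::exp(lalpha)) {
            h = h_p; rho = rho_p; logpi = logpi_p;
            sigma_a2 = sa2_p; sigma_b2 = sb2_p;
            if (reweighted) { ds = cds; gs = cgs; }
            cur_logml = mlp.logml; cur_lpg = lpg_p;
            ++acc_hyper;
          }
        }
      }
    } else {
      // gamma move
      cand = gstate;
      std::vector<Step> steps; double logratio; bool compound;
      bool ok = propose_gamma_state(cand, pcfg, geomw, rank_order, rank_of,
                                    steps, logratio, compound);
      if (compound) ++try_comp; else ++try_gamma;
      if (!ok) {
        ++n_capped;
      } else {
        // replay steps onto the stats; single moves use the contiguous
        // design for one BLAS cross-product, compound moves fall back to
        // gathered columns at each intermediate state
        cgs = gs;
        if (steps.size() == 1) {
          const Step &stp = steps[0];
          if (stp.type == STEP_REMOVE) {
            stats_remove(cgs, stp.rem_pos);
          } else {
            arma::vec v = ds.d % UtX.col(stp.add_j);
            arma::vec cross = Xt.t() * v;
            double gjj = arma::dot(UtX.col(stp.add_j), v);
            double xy = arma::dot(v, yt), xo = arma::dot(v, onest);
            if (stp.type == STEP_SWAP) {
              stats_remove(cgs, stp.rem_pos);
              cross.shed_row(stp.rem_pos);
            }
            stats_add_with_cross(cgs, cross, gjj, xy, xo, stp.add_j);
          }
        } else {
          for (const Step &stp : steps) {
            if (stp.type == STEP_ADD) {
              stats_add(cgs, UtX, ds, yt, onest, stp.add_j);
            } else if (stp.type == STEP_REMOVE) {
              stats_remove(cgs, stp.rem_pos);
            } else {
              stats_remove(cgs, stp.rem_pos);
              stats_add(cgs, UtX, ds, yt, onest, stp.add_j);
            }
          }
        }
        LogMLOut mlp = logml_stats(n, ds, cgs, sigma_a2);
        double lpg_p = log_prior_gamma((int) cgs.gidx.size(), p, logpi);
        if (mlp.ok) {
          double lalpha = (mlp.logml + lpg_p) - (cur_logml + cur_lpg) + logratio;
          if (lalpha >= 0.0 || ::unif_rand() < std::exp(lalpha)) {
            gstate = cand;
            gs = cgs;
            cur_logml = mlp.logml; cur_lpg = lpg_p;
            if (compound) ++acc_comp; else ++acc_gamma;
            // keep the contiguous design in step with gs.gidx
            if (steps.size() == 1) {
              const Step &stp = steps[0];
              if (stp.type == STEP_REMOVE) {
                Xt.shed_col(stp.rem_pos);
              } else if (stp.type == STEP_ADD) {
                Xt.insert_cols(Xt.n_cols, 1);
                Xt.col(Xt.n_cols - 1) = UtX.col(stp.add_j);
              } else {
                Xt.shed_col(stp.rem_pos);
                Xt.insert_cols(Xt.n_cols, 1);
                Xt.col(Xt.n_cols - 1) = UtX.col(stp.add_j);
              }
            } else {
              Xt.set_size(n, (arma::uword) gs.gidx.size());
              for (size_t k = 0; k < gs.gidx.size(); ++k)
                Xt.col(k) = UtX.col(gs.gidx[k]);
            }
          }
        }
      }
    }

    // record
    if (iter >= burn_in && ((iter - burn_in) % thin == 0)) {
      sample_effects_stats(drw, n, ds, gs, UtX, yt, onest, delta, sigma_a2,
                           sigma_b2, &Xt);
      rec_h[kept] = h; rec_rho[kept] = rho; rec_logpi[kept] = logpi;
      rec_pve[kept] = drw.pve; rec_pge[kept] = drw.pge;
      rec_mu[kept] = drw.mu; rec_tau[kept] = drw.tau;
      rec_sa2[kept] = sigma_a2; rec_sb2[kept] = sigma_b2;
      rec_q[kept] = (int) gs.gidx.size();
      if (sigma_a2 > 0.0) {
        for (size_t k = 0; k < gs.gidx.size(); ++k) {
          int j = gs.gidx[k];
          incl_count[j] += 1.0;
          double b = drw.beta[k];
          beta_sum[j] += b;
          beta_abs_sum[j] += std::fabs(b);
          if (record_effects) {
            eff_draw_id.push_back(kept + 1);
            eff_marker.push_back(j + 1);
            eff_beta.push_back(b);
          }
        }
      }
      ++kept;
    }
    if ((iter & 0x3FF) == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
      _["h"] = rec_h.head(kept), _["rho"] = rec_rho.head(kept),
      _["log_pi"] = rec_logpi.head(kept), _["q"] = rec_q.head(kept),
      _["pve"] = rec_pve.head(kept), _["pge"] = rec_pge.head(kept),
      _["mu"] = rec_mu.head(kept), _["tau"] = rec_tau.head(kept),
      _["sigma_a2"] = rec_sa2.head(kept), _["sigma_b2"] = rec_sb2.head(kept),
      _["inclusion_count"] = incl_count, _["beta_sum"] = beta_sum,
      _["beta_abs_sum"] = beta_abs_sum, _["n_kept"] = kept,
      _["accept"] = List::create(
          _["gamma"] = (try_gamma > 0) ? (double) acc_gamma / try_gamma : NA_REAL,
          _["compound"] = (try_comp > 0) ? (double) acc_comp / try_comp : NA_REAL,
          _["hyper"] = (try_hyper > 0) ? (double) acc_hyper / try_hyper : NA_REAL),
      _["n_capped"] = (double) n_capped,
      _["final_gamma"] = wrap([&]() {
        IntegerVector g(gs.gidx.size());
        for (size_t k = 0; k < gs.gidx.size(); ++k) g[k] = gs.gidx[k] + 1;
        return g;
      }()),
      _["effect_draws"] = record_effects
          ? (SEXP) List::create(_["draw"] = wrap(eff_draw_id),
                                _["marker"] = wrap(eff_marker),
                                _["beta"] = wrap(eff_beta))
          : (SEXP) R_NilValue);
}
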