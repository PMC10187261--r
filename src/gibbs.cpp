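// Multi-chain Gibbs sampler for the noisy OR-NOR regulation model.
//
// Latent variables per chain: x (TF activity, 0/1), theta (TF activity
// probability, sampled on a fixed grid), s (per-edge mode of regulation,
// 0=I, 1=NA, 2=A) and h (true gene state, -1/0/+1). The observed evidence y
// enters through the observation matrix P(Y|H). Convergence is monitored by
// the Gelman-Rubin potential scale reduction factor computed on the
// post-burn-in portion of every variable's chain.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <random>
#include <string>
#include <vector>

using namespace Rcpp;

namespace {

struct Model {
  int n_tf, n_gene, n_edge;
  std::vector<int> e_tf, e_gene, e_ann;   // per edge; ann: 0=I, 2=A
  std::vector<int> g_ptr, g_edge;         // gene -> incoming edge ids (CSR)
  std::vector<int> t_ptr, t_edge;         // tf -> outgoing edge ids (CSR)
  std::vector<int> y;                     // per gene, -1/0/1
  std::vector<double> zeta;               // per gene
  double q[3];
  double p0;
  double obs[3][3];                       // [y+1][h+1]
  std::vector<double> sprior;             // n_edge x 3 (I, NA, A), row-major
  std::vector<double> grid, gprior;       // theta grid and prior weights
  bool resample_s;
};

struct Chain {
  std::vector<int> x;        // n_tf
  std::vector<double> tv;    // n_tf, theta values (grid points)
  std::vector<int> s;        // n_edge, 0/1/2
  std::vector<int> h;        // n_gene, -1/0/1
  std::mt19937_64 rng;
  double unif() {
    return std::uniform_real_distribution<double>(0.0, 1.0)(rng);
  }
  int draw_cat(const double* w, int k) {
    double tot = 0.0;
    for (int i = 0; i < k; ++i) tot += w[i];
    double u = unif() * tot, c = 0.0;
    for (int i = 0; i < k; ++i) {
      c += w[i];
      if (u <= c) return i;
    }
    return k - 1;
  }
};

struct Ctx {
  double DA, DI;
  int nact;
};

// Contribution of one parent edge with given state to a gene's context.
inline void edge_factor(const Model& M, int j, int xv, double th, int sv,
                        Ctx& c) {
  if (!xv || sv == 1) return;  // inactive TF or "not applicable" edge
  double u = 1.0 - M.zeta[j] * (1.0 - th);  // firing probability
  if (sv == 2) c.DA *= 1.0 - u; else c.DI *= 1.0 - u;
  c.nact += 1;
}

inline Ctx gene_ctx(const Model& M, const Chain& C, int j, int skip_edge) {
  Ctx c{1.0, 1.0, 0};
  for (int k = M.g_ptr[j]; k < M.g_ptr[j + 1]; ++k) {
    int e = M.g_edge[k];
    if (e == skip_edge) continue;
    int i = M.e_tf[e];
    edge_factor(M, j, C.x[i], C.tv[i], C.s[e], c);
  }
  return c;
}

// Outcome distribution (down, zero, up) for gene j given its context.
inline void h_probs(const Model& M, int j, const Ctx& c, double* p) {
  double xi = 1.0 - M.zeta[j];
  double w = (c.nact == 0) ? 1.0 : std::pow(xi, (double)c.nact);
  double pl = 1.0 - w;
  p[0] = pl * (1.0 - c.DI) + w * M.q[0];
  p[1] = pl * (c.DA * c.DI) + w * M.q[1];
  p[2] = pl * ((1.0 - c.DA) * c.DI) + w * M.q[2];
  for (int i = 0; i < 3; ++i) if (p[i] < 0.0) p[i] = 0.0;
}

const double TINY = 1e-300;

// Conditional P(x_i = 1 | Markov blanket).
double cond_x(const Model& M, const Chain& C, int i) {
  double lo = std::log(M.p0) - std::log1p(-M.p0);
  for (int k = M.t_ptr[i]; k < M.t_ptr[i + 1]; ++k) {
    int e = M.t_edge[k], j = M.e_gene[e];
    Ctx base = gene_ctx(M, C, j, e);
    Ctx c1 = base;
    edge_factor(M, j, 1, C.tv[i], C.s[e], c1);
    double p1[3], p0v[3];
    h_probs(M, j, c1, p1);
    h_probs(M, j, base, p0v);
    int hj = C.h[j] + 1;
    lo += std::log(std::max(p1[hj], TINY)) - std::log(std::max(p0v[hj], TINY));
  }
  return 1.0 / (1.0 + std::exp(-lo));
}

// Multiply the grid weights w (over theta_i values, x_i = 1 assumed) by the
// outcome likelihood of one child gene; returns the theta-free likelihood of
// the same gene under x_i = 0.
inline double child_grid_factor(const Model& M, const Chain& C, int i, int e,
                                std::vector<double>& w) {
  int j = M.e_gene[e], G = (int)M.grid.size();
  Ctx base = gene_ctx(M, C, j, e);
  int hj = C.h[j] + 1;
  double p0v[3];
  h_probs(M, j, base, p0v);
  double l0 = std::max(p0v[hj], TINY);
  int sv = C.s[e];
  if (sv == 1) return 1.0;  // NA edge: identical likelihood for x = 0/1
  double xi = 1.0 - M.zeta[j];
  int nact = base.nact + 1;
  double mw = std::pow(xi, (double)nact);
  double pl = 1.0 - mw;
  for (int t = 0; t < G; ++t) {
    double u = 1.0 - M.zeta[j] * (1.0 - M.grid[t]);
    double DA = base.DA, DI = base.DI;
    if (sv == 2) DA *= 1.0 - u; else DI *= 1.0 - u;
    double p;
    if (hj == 0)      p = pl * (1.0 - DI) + mw * M.q[0];
    else if (hj == 1) p = pl * (DA * DI) + mw * M.q[1];
    else              p = pl * ((1.0 - DA) * DI) + mw * M.q[2];
    w[t] *= std::max(p, TINY);
  }
  return l0;
}

// Joint grid weights (theta | x_i = 1, rest) and the two marginal likelihoods
// needed for the blocked (x_i, theta_i) update. On return, w holds
// gprior[t] * prod_children P(h_j | x_i=1, theta=grid[t]) and lik0 the
// matching product under x_i = 0, both on a common scale.
void xtheta_weights(const Model& M, const Chain& C, int i,
                    std::vector<double>& w, double& lik0) {
  int G = (int)M.grid.size();
  w.assign(M.gprior.begin(), M.gprior.end());
  lik0 = 1.0;
  int done = 0;
  for (int k = M.t_ptr[i]; k < M.t_ptr[i + 1]; ++k) {
    int e = M.t_edge[k];
    double l0 = child_grid_factor(M, C, i, e, w);
    if (l0 == 1.0 && C.s[e] == 1) continue;  // NA edge skipped on both sides
    lik0 *= l0;
    if (++done % 8 == 0) {  // joint rescale preserves the w / lik0 ratio
      double mx = lik0;
      for (int t = 0; t < G; ++t) if (w[t] > mx) mx = w[t];
      if (mx > 0.0) {
        for (int t = 0; t < G; ++t) w[t] /= mx;
        lik0 /= mx;
      }
    }
  }
}

// Blocked update: draw x_i with theta_i summed out over its grid, then draw
// theta_i from its conditional given the new x_i. Collapsing theta removes
// the metastability of single-site updates (an active TF with a high current
// theta would otherwise almost never switch off).
void update_xtheta(const Model& M, Chain& C, int i, std::vector<double>& w) {
  double lik0;
  xtheta_weights(M, C, i, w, lik0);
  int G = (int)M.grid.size();
  double s1 = 0.0;
  for (int t = 0; t < G; ++t) s1 += w[t];
  double num = M.p0 * s1, den = num + (1.0 - M.p0) * lik0;
  double po = (den > 0.0) ? num / den : M.p0;
  C.x[i] = (C.unif() < po) ? 1 : 0;
  if (C.x[i] == 1 && s1 > 0.0)
    C.tv[i] = M.grid[C.draw_cat(w.data(), G)];
  else
    C.tv[i] = M.grid[C.draw_cat(M.gprior.data(), G)];
}

// Marginalised conditional P(x_i = 1 | blanket \ theta_i), for validation.
double cond_x_marginal(const Model& M, const Chain& C, int i,
                       std::vector<double>& w) {
  double lik0;
  xtheta_weights(M, C, i, w, lik0);
  double s1 = 0.0;
  for (size_t t = 0; t < w.size(); ++t) s1 += w[t];
  double num = M.p0 * s1, den = num + (1.0 - M.p0) * lik0;
  return (den > 0.0) ? num / den : M.p0;
}

// Grid weights of the theta_i conditional given x_i (normalised).
void cond_theta(const Model& M, const Chain& C, int i, std::vector<double>& w) {
  int G = (int)M.grid.size();
  if (C.x[i] == 1) {
    double lik0;
    xtheta_weights(M, C, i, w, lik0);
  } else {
    w.assign(M.gprior.begin(), M.gprior.end());
  }
  double tot = 0.0;
  for (int t = 0; t < G; ++t) tot += w[t];
  if (tot <= 0.0) { w.assign(G, 1.0 / G); return; }
  for (int t = 0; t < G; ++t) w[t] /= tot;
}

// Weights of the s_e conditional over (I, NA, A) (normalised).
void cond_s(const Model& M, const Chain& C, int e, double* w) {
  int i = M.e_tf[e], j = M.e_gene[e];
  Ctx base = gene_ctx(M, C, j, e);
  int hj = C.h[j] + 1;
  double tot = 0.0;
  for (int sv = 0; sv < 3; ++sv) {
    Ctx c = base;
    edge_factor(M, j, C.x[i], C.tv[i], sv, c);
    double p[3];
    h_probs(M, j, c, p);
    w[sv] = M.sprior[e * 3 + sv] * std::max(p[hj], TINY);
    tot += w[sv];
  }
  for (int sv = 0; sv < 3; ++sv) w[sv] /= tot;
}

// Weights of the h_j conditional over (-1, 0, +1) (normalised).
void cond_h(const Model& M, const Chain& C, int j, double* w) {
  Ctx c = gene_ctx(M, C, j, -1);
  double p[3];
  h_probs(M, j, c, p);
  int yi = M.y[j] + 1;
  double tot = 0.0;
  for (int hv = 0; hv < 3; ++hv) {
    w[hv] = M.obs[yi][hv] * p[hv];
    tot += w[hv];
  }
  if (tot <= 0.0) { w[0] = w[1] = w[2] = 1.0 / 3.0; return; }
  for (int hv = 0; hv < 3; ++hv) w[hv] /= tot;
}

void sweep(const Model& M, Chain& C, std::vector<double>& tbuf) {
  for (int i = 0; i < M.n_tf; ++i)
    update_xtheta(M, C, i, tbuf);
  if (M.resample_s) {
    double w[3];
    for (int e = 0; e < M.n_edge; ++e) {
      cond_s(M, C, e, w);
      C.s[e] = C.draw_cat(w, 3);
    }
  }
  double w[3];
  for (int j = 0; j < M.n_gene; ++j) {
    cond_h(M, C, j, w);
    C.h[j] = C.draw_cat(w, 3) - 1;
  }
}

Model make_model(int n_tf, int n_gene, const IntegerVector& edge_tf,
                 const IntegerVector& edge_gene, const IntegerVector& edge_ann,
                 const IntegerVector& y, const NumericVector& zeta,
                 const NumericVector& q, double p0, const NumericMatrix& obs,
                 const NumericMatrix& s_prior, const NumericVector& theta_grid,
                 const NumericVector& theta_prior, bool resample_s) {
  Model M;
  M.n_tf = n_tf;
  M.n_gene = n_gene;
  M.n_edge = edge_tf.size();
  M.e_tf.assign(edge_tf.begin(), edge_tf.end());
  M.e_gene.assign(edge_gene.begin(), edge_gene.end());
  M.e_ann.assign(edge_ann.begin(), edge_ann.end());
  M.y.assign(y.begin(), y.end());
  M.zeta.assign(zeta.begin(), zeta.end());
  for (int i = 0; i < 3; ++i) M.q[i] = q[i];
  M.p0 = p0;
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b) M.obs[a][b] = obs(a, b);
  M.sprior.resize((size_t)M.n_edge * 3);
  for (int e = 0; e < M.n_edge; ++e)
    for (int svv = 0; svv < 3; ++svv) M.sprior[e * 3 + svv] = s_prior(e, svv);
  M.grid.assign(theta_grid.begin(), theta_grid.end());
  M.gprior.assign(theta_prior.begin(), theta_prior.end());
  M.resample_s = resample_s;

  // CSR indices
  M.g_ptr.assign(n_gene + 1, 0);
  M.t_ptr.assign(n_tf + 1, 0);
  for (int e = 0; e < M.n_edge; ++e) {
    ++M.g_ptr[M.e_gene[e] + 1];
    ++M.t_ptr[M.e_tf[e] + 1];
  }
  for (int j = 0; j < n_gene; ++j) M.g_ptr[j + 1] += M.g_ptr[j];
  for (int i = 0; i < n_tf; ++i) M.t_ptr[i + 1] += M.t_ptr[i];
  M.g_edge.resize(M.n_edge);
  M.t_edge.resize(M.n_edge);
  std::vector<int> gpos(M.g_ptr.begin(), M.g_ptr.end() - 1);
  std::vector<int> tpos(M.t_ptr.begin(), M.t_ptr.end() - 1);
  for (int e = 0; e < M.n_edge; ++e) {
    M.g_edge[gpos[M.e_gene[e]]++] = e;
    M.t_edge[tpos[M.e_tf[e]]++] = e;
  }
  return M;
}

Chain init_chain(const Model& M, uint64_t seed) {
  Chain C;
  C.rng.seed(seed);
  C.x.resize(M.n_tf);
  C.tv.resize(M.n_tf);
  C.s.resize(M.n_edge);
  C.h.resize(M.n_gene);
  for (int i = 0; i < M.n_tf; ++i) C.x[i] = (C.unif() < M.p0) ? 1 : 0;
  for (int i = 0; i < M.n_tf; ++i)
    C.tv[i] = M.grid[C.draw_cat(M.gprior.data(), (int)M.gprior.size())];
  for (int e = 0; e < M.n_edge; ++e) {
    if (M.resample_s)
      C.s[e] = C.draw_cat(M.sprior.data() + e * 3, 3);
    else
      C.s[e] = M.e_ann[e];
  }
  double qv[3] = {M.q[0], M.q[1], M.q[2]};
  for (int j = 0; j < M.n_gene; ++j) C.h[j] = C.draw_cat(qv, 3) - 1;
  return C;
}

// Per-chain trace and running moments for every monitored variable.
// Variable layout: [x: n_tf][theta: n_tf][s: n_edge][h: n_gene].
struct ChainStats {
  int n_var;
  long n = 0;   // recorded sweeps
  long hb = 0;  // sweeps folded into the burn-in segment
  std::vector<double> sa, ssa, sb, ssb;           // all / burn sums
  std::vector<int8_t> tx, ts, th;                 // traces
  std::vector<float> tt;
  std::vector<long long> s_cnt_a, s_cnt_b;        // per-edge category counts
  std::vector<long long> h_cnt_a, h_cnt_b;        // per-gene category counts

  void init(const Model& M) {
    n_var = 2 * M.n_tf + M.n_edge + M.n_gene;
    sa.assign(n_var, 0.0); ssa.assign(n_var, 0.0);
    sb.assign(n_var, 0.0); ssb.assign(n_var, 0.0);
    s_cnt_a.assign((size_t)M.n_edge * 3, 0);
    s_cnt_b.assign((size_t)M.n_edge * 3, 0);
    h_cnt_a.assign((size_t)M.n_gene * 3, 0);
    h_cnt_b.assign((size_t)M.n_gene * 3, 0);
  }

  void record(const Model& M, const Chain& C) {
    int nt = M.n_tf, ne = M.n_edge, ng = M.n_gene;
    for (int i = 0; i < nt; ++i) {
      double v = C.x[i];
      sa[i] += v; ssa[i] += v * v;
      tx.push_back((int8_t)C.x[i]);
    }
    for (int i = 0; i < nt; ++i) {
      double v = C.tv[i];
      sa[nt + i] += v; ssa[nt + i] += v * v;
      tt.push_back((float)v);
    }
    for (int e = 0; e < ne; ++e) {
      double v = C.s[e] - 1;  // numeric coding -1/0/+1
      sa[2 * nt + e] += v; ssa[2 * nt + e] += v * v;
      ts.push_back((int8_t)C.s[e]);
      ++s_cnt_a[(size_t)e * 3 + C.s[e]];
    }
    for (int j = 0; j < ng; ++j) {
      double v = C.h[j];
      sa[2 * nt + ne + j] += v; ssa[2 * nt + ne + j] += v * v;
      th.push_back((int8_t)C.h[j]);
      ++h_cnt_a[(size_t)j * 3 + (C.h[j] + 1)];
    }
    ++n;
  }

  // Fold sweeps into the burn-in segment until it holds floor(n * bf) sweeps.
  void advance_burn(const Model& M, double bf) {
    long tgt = (long)std::floor(n * bf);
    int nt = M.n_tf, ne = M.n_edge, ng = M.n_gene;
    while (hb < tgt) {
      long r = hb;
      for (int i = 0; i < nt; ++i) {
        double v = tx[(size_t)r * nt + i];
        sb[i] += v; ssb[i] += v * v;
      }
      for (int i = 0; i < nt; ++i) {
        double v = tt[(size_t)r * nt + i];
        sb[nt + i] += v; ssb[nt + i] += v * v;
      }
      for (int e = 0; e < ne; ++e) {
        int sv = ts[(size_t)r * ne + e];
        double v = sv - 1;
        sb[2 * nt + e] += v; ssb[2 * nt + e] += v * v;
        ++s_cnt_b[(size_t)e * 3 + sv];
      }
      for (int j = 0; j < ng; ++j) {
        double v = th[(size_t)r * ng + j];
        sb[2 * nt + ne + j] += v; ssb[2 * nt + ne + j] += v * v;
        ++h_cnt_b[(size_t)j * 3 + (th[(size_t)r * ng + j] + 1)];
      }
      ++hb;
    }
  }
};

// Gelman-Rubin PSRF over the post-burn-in segments of m chains.
double psrf(const std::vector<ChainStats>& cs, int v) {
  int m = (int)cs.size();
  double W = 0.0, mbar = 0.0;
  std::vector<double> mu(m);
  long n2min = (long)1e18;
  for (int c = 0; c < m; ++c) {
    long n2 = cs[c].n - cs[c].hb;
    if (n2 < 2) return R_PosInf;
    n2min = std::min(n2min, n2);
    double s1 = cs[c].sa[v] - cs[c].sb[v];
    double s2 = cs[c].ssa[v] - cs[c].ssb[v];
    mu[c] = s1 / n2;
    double var = (s2 - n2 * mu[c] * mu[c]) / (n2 - 1);
    W += std::max(var, 0.0);
    mbar += mu[c];
  }
  W /= m;
  mbar /= m;
  double vb = 0.0;
  for (int c = 0; c < m; ++c) vb += (mu[c] - mbar) * (mu[c] - mbar);
  vb /= (m - 1);
  if (W < 1e-18) return (vb < 1e-18) ? 1.0 : R_PosInf;
  double n2 = (double)n2min;
  double vhat = (n2 - 1.0) / n2 * W + (1.0 + 1.0 / m) * vb;
  return std::sqrt(vhat / W);
}

double max_psrf(const std::vector<ChainStats>& cs) {
  double mx = 1.0;
  int nv = cs[0].n_var;
  for (int v = 0; v < nv; ++v) {
    double r = psrf(cs, v);
    if (r > mx) mx = r;
    if (!R_FINITE(mx)) return mx;
  }
  return mx;
}

}  // namespace

// [[Rcpp::export(name = ".gibbs_run")]]
List gibbs_run(int n_tf, int n_gene, IntegerVector edge_tf,
               IntegerVector edge_gene, IntegerVector edge_ann,
               IntegerVector y, NumericVector zeta, NumericVector q, double p0,
               NumericMatrix obs, NumericMatrix s_prior,
               NumericVector theta_grid, NumericVector theta_prior,
               bool resample_s, int n_chains, int check_period,
               double r_threshold, int max_iter, int min_iter,
               double burn_frac, int seed) {
  Model M = make_model(n_tf, n_gene, edge_tf, edge_gene, edge_ann, y, zeta, q,
                       p0, obs, s_prior, theta_grid, theta_prior, resample_s);

  std::vector<Chain> chains;
  std::vector<ChainStats> cs(n_chains);
  for (int c = 0; c < n_chains; ++c) {
    uint64_t sd = (uint64_t)seed * 2654435761ULL + 1000003ULL * (c + 1);
    chains.push_back(init_chain(M, sd));
    cs[c].init(M);
  }

  std::vector<double> tbuf(M.grid.size());
  bool converged = false;
  double max_r = R_PosInf;
  std::vector<double> r_iter, r_val;
  long n = 0;

  while (n < max_iter) {
    long block = std::min((long)check_period, (long)max_iter - n);
    for (int c = 0; c < n_chains; ++c) {
      for (long it = 0; it < block; ++it) {
        sweep(M, chains[c], tbuf);
        cs[c].record(M, chains[c]);
      }
      cs[c].advance_burn(M, burn_frac);
    }
    n += block;
    max_r = max_psrf(cs);
    r_iter.push_back((double)n);
    r_val.push_back(max_r);
    if (n >= min_iter && R_FINITE(max_r) && max_r < r_threshold) {
      converged = true;
      break;
    }
    Rcpp::checkUserInterrupt();
  }

  // Pooled post-burn-in summaries.
  int nt = M.n_tf, ne = M.n_edge, ng = M.n_gene;
  NumericVector x_mean(nt), theta_mean(nt);
  NumericMatrix x_chain(nt, n_chains);
  double n2tot = 0.0;
  for (int c = 0; c < n_chains; ++c) n2tot += cs[c].n - cs[c].hb;
  for (int i = 0; i < nt; ++i) {
    double sx = 0.0, st = 0.0;
    for (int c = 0; c < n_chains; ++c) {
      long n2 = cs[c].n - cs[c].hb;
      sx += cs[c].sa[i] - cs[c].sb[i];
      st += cs[c].sa[nt + i] - cs[c].sb[nt + i];
      x_chain(i, c) = (cs[c].sa[i] - cs[c].sb[i]) / n2;
    }
    x_mean[i] = sx / n2tot;
    theta_mean[i] = st / n2tot;
  }
  NumericMatrix s_mean(ne, 3), h_mean(ng, 3);
  for (int e = 0; e < ne; ++e)
    for (int svv = 0; svv < 3; ++svv) {
      long long cnt = 0;
      for (int c = 0; c < n_chains; ++c)
        cnt += cs[c].s_cnt_a[(size_t)e * 3 + svv] -
               cs[c].s_cnt_b[(size_t)e * 3 + svv];
      s_mean(e, svv) = cnt / n2tot;
    }
  for (int j = 0; j < ng; ++j)
    for (int hv = 0; hv < 3; ++hv) {
      long long cnt = 0;
      for (int c = 0; c < n_chains; ++c)
        cnt += cs[c].h_cnt_a[(size_t)j * 3 + hv] -
               cs[c].h_cnt_b[(size_t)j * 3 + hv];
      h_mean(j, hv) = cnt / n2tot;
    }

  NumericVector r_var(cs[0].n_var);
  for (int v = 0; v < cs[0].n_var; ++v) r_var[v] = psrf(cs, v);

  // final chain states (diagnostics)
  List states(n_chains);
  for (int c = 0; c < n_chains; ++c)
    states[c] = List::create(
        _["x"] = IntegerVector(chains[c].x.begin(), chains[c].x.end()),
        _["theta"] = NumericVector(chains[c].tv.begin(), chains[c].tv.end()),
        _["s"] = IntegerVector(chains[c].s.begin(), chains[c].s.end()),
        _["h"] = IntegerVector(chains[c].h.begin(), chains[c].h.end()));

  return List::create(
      _["x_mean"] = x_mean, _["theta_mean"] = theta_mean,
      _["x_chain"] = x_chain, _["s_mean"] = s_mean, _["h_mean"] = h_mean,
      _["converged"] = converged, _["iterations"] = (double)n,
      _["max_r"] = max_r, _["r_var"] = r_var, _["states"] = states,
      _["r_history"] = DataFrame::create(_["iteration"] = r_iter,
                                         _["max_r"] = r_val));
}

// Conditional distribution of a single variable given a full state; used to
// validate the sampler's full conditionals against independent enumeration.
// [[Rcpp::export(name = ".gibbs_cond")]]
NumericVector gibbs_cond(std::string what, int idx, IntegerVector x,
                         NumericVector theta, IntegerVector s, IntegerVector h,
                         int n_tf, int n_gene, IntegerVector edge_tf,
                         IntegerVector edge_gene, IntegerVector edge_ann,
                         IntegerVector y, NumericVector zeta, NumericVector q,
                         double p0, NumericMatrix obs, NumericMatrix s_prior,
                         NumericVector theta_grid, NumericVector theta_prior,
                         bool resample_s) {
  Model M = make_model(n_tf, n_gene, edge_tf, edge_gene, edge_ann, y, zeta, q,
                       p0, obs, s_prior, theta_grid, theta_prior, resample_s);
  Chain C;
  C.x.assign(x.begin(), x.end());
  C.tv.assign(theta.begin(), theta.end());
  C.s.assign(s.begin(), s.end());
  C.h.assign(h.begin(), h.end());
  if (what == "x") {
    return NumericVector::create(cond_x(M, C, idx));
  } else if (what == "xm") {
    std::vector<double> w;
    return NumericVector::create(cond_x_marginal(M, C, idx, w));
  } else if (what == "theta") {
    std::vector<double> w;
    cond_theta(M, C, idx, w);
    return NumericVector(w.begin(), w.end());
  } else if (what == "s") {
    double w[3];
    cond_s(M, C, idx, w);
    return NumericVector::create(w[0], w[1], w[2]);
  } else if (what == "h") {
    double w[3];
    cond_h(M, C, idx, w);
    return NumericVector::create(w[0], w[1], w[2]);
  }
  stop("unknown conditional '%s'", what);
}
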