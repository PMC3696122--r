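// Discrete Bayesian-network machinery: Cooper-Herskovits (K2) family
// scores, Metropolis-Hastings structure MCMC over bounded-indegree DAGs,
// and exhaustive DAG enumeration for small variable sets (the exact
// posterior oracle). All scores are kept in log space.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// ---- Cooper-Herskovits family score -----------------------------------

// log marginal likelihood of variable v given a parent set, uniform
// Dirichlet (all hyperparameters 1):
//   sum_j [ lgamma(r_v) - lgamma(N_j + r_v) + sum_k lgamma(N_jk + 1) ]
static double family_score(const IntegerMatrix& X, const IntegerVector& r,
                           int v, const std::vector<int>& parents) {
  const int n = X.nrow();
  const int rv = r[v];
  std::unordered_map<long long, std::vector<int> > tab;
  for (int i = 0; i < n; ++i) {
    long long code = 0;
    for (size_t j = 0; j < parents.size(); ++j)
      code = code * r[parents[j]] + X(i, parents[j]);
    std::vector<int>& cell = tab[code];
    if (cell.empty()) cell.assign(rv, 0);
    cell[X(i, v)]++;
  }
  double s = 0.0;
  for (std::unordered_map<long long, std::vector<int> >::const_iterator
         it = tab.begin(); it != tab.end(); ++it) {
    int Nj = 0;
    for (int k = 0; k < rv; ++k) Nj += it->second[k];
    s += lgamma((double)rv) - lgamma((double)(Nj + rv));
    for (int k = 0; k < rv; ++k) s += lgamma((double)(it->second[k] + 1));
  }
  return s;
}

static std::vector<int> mask_to_parents(unsigned int mask, int p) {
  std::vector<int> out;
  for (int j = 0; j < p; ++j) if (mask & (1u << j)) out.push_back(j);
  return out;
}

struct ScoreCache {
  const IntegerMatrix& X;
  const IntegerVector& r;
  int p;
  std::unordered_map<unsigned long long, double> map;
  ScoreCache(const IntegerMatrix& X_, const IntegerVector& r_, int p_)
    : X(X_), r(r_), p(p_) {}
  double get(int v, unsigned int mask) {
    unsigned long long key = ((unsigned long long)v << p) | mask;
    std::unordered_map<unsigned long long, double>::iterator it = map.find(key);
    if (it != map.end()) return it->second;
    double s = family_score(X, r, v, mask_to_parents(mask, p));
    map[key] = s;
    return s;
  }
};

// [[Rcpp::export]]
double cpp_family_score(IntegerMatrix X, IntegerVector r, int v,
                        IntegerVector parents) {
  std::vector<int> ps(parents.begin(), parents.end());
  return family_score(X, r, v, ps);
}

// ---- graph utilities ---------------------------------------------------

// is there a directed path (length >= 1) from a to b?
static bool has_path(const std::vector<std::vector<char> >& adj,
                     int a, int b, int p) {
  std::vector<char> seen(p, 0);
  std::vector<int> stack;
  stack.push_back(a);
  while (!stack.empty()) {
    int u = stack.back(); stack.pop_back();
    for (int v = 0; v < p; ++v) {
      if (adj[u][v] && !seen[v]) {
        if (v == b) return true;
        seen[v] = 1;
        stack.push_back(v);
      }
    }
  }
  return false;
}

// reach[a][b] = path of length >= 1 from a to b
static void reachability(const std::vector<std::vector<char> >& adj, int p,
                         std::vector<std::vector<char> >& reach) {
  for (int a = 0; a < p; ++a) {
    std::fill(reach[a].begin(), reach[a].end(), 0);
    std::vector<int> stack;
    stack.push_back(a);
    std::vector<char> seen(p, 0);
    while (!stack.empty()) {
      int u = stack.back(); stack.pop_back();
      for (int v = 0; v < p; ++v) {
        if (adj[u][v] && !seen[v]) {
          seen[v] = 1; reach[a][v] = 1;
          stack.push_back(v);
        }
      }
    }
  }
}

struct Move { int type; int u; int v; }; // 0 = add, 1 = delete, 2 = reverse

static void enumerate_moves(std::vector<std::vector<char> >& adj,
                            const std::vector<int>& npar,
                            int p, int max_parents,
                            std::vector<Move>& out) {
  out.clear();
  static std::vector<std::vector<char> > reach;
  if ((int)reach.size() != p) reach.assign(p, std::vector<char>(p, 0));
  reachability(adj, p, reach);
  for (int u = 0; u < p; ++u) {
    for (int v = 0; v < p; ++v) {
      if (u == v) continue;
      if (adj[u][v]) {
        Move d; d.type = 1; d.u = u; d.v = v;
        out.push_back(d);
        if (npar[u] < max_parents) {
          adj[u][v] = 0; // reverse is valid iff no alternative path u -> v
          bool alt = has_path(adj, u, v, p);
          adj[u][v] = 1;
          if (!alt) { Move m; m.type = 2; m.u = u; m.v = v; out.push_back(m); }
        }
      } else if (npar[v] < max_parents && !reach[v][u]) {
        Move a; a.type = 0; a.u = u; a.v = v;
        out.push_back(a);
      }
    }
  }
}

static int mb_mask_of(const std::vector<std::vector<char> >& adj,
                      int p, int target) {
  int mask = 0;
  for (int u = 0; u < p; ++u) if (adj[u][target]) mask |= (1 << u);
  for (int v = 0; v < p; ++v) {
    if (adj[target][v]) {
      mask |= (1 << v);
      for (int w = 0; w < p; ++w)
        if (w != target && adj[w][v]) mask |= (1 << w);
    }
  }
  mask &= ~(1 << target);
  return mask;
}

// ---- structure MCMC ----------------------------------------------------

// [[Rcpp::export]]
List cpp_structure_mcmc(IntegerMatrix X, IntegerVector r, int target,
                        double steps, double burn_in, int max_parents,
                        int thin) {
  const int p = X.ncol();
  if (p < 2) stop("need at least 2 variables");
  if (steps <= burn_in) stop("steps must exceed burn_in");
  ScoreCache cache(X, r, p);

  std::vector<std::vector<char> > adj(p, std::vector<char>(p, 0));
  std::vector<int> npar(p, 0);
  std::vector<unsigned int> pmask(p, 0);
  std::vector<double> nodescore(p);
  for (int v = 0; v < p; ++v) nodescore[v] = cache.get(v, 0);

  std::vector<Move> cur_moves, prop_moves;
  enumerate_moves(adj, npar, p, max_parents, cur_moves);

  long n_keep = (long)std::floor((steps - burn_in) / thin);
  IntegerMatrix samples(n_keep, p * p);
  IntegerVector mb_masks(n_keep);
  long kept = 0;
  double accepted = 0;

  for (double s = 1; s <= steps; ++s) {
    if (cur_moves.empty()) stop("no valid moves from current structure");
    int mi = (int)std::floor(unif_rand() * cur_moves.size());
    if (mi == (int)cur_moves.size()) mi--;
    Move m = cur_moves[mi];

    // tentative apply + delta score
    double delta = 0.0;
    unsigned int new_pm_v = pmask[m.v], new_pm_u = pmask[m.u];
    double new_sc_v = nodescore[m.v], new_sc_u = nodescore[m.u];
    if (m.type == 0) {            // add u -> v
      adj[m.u][m.v] = 1; npar[m.v]++;
      new_pm_v = pmask[m.v] | (1u << m.u);
      new_sc_v = cache.get(m.v, new_pm_v);
      delta = new_sc_v - nodescore[m.v];
    } else if (m.type == 1) {     // delete u -> v
      adj[m.u][m.v] = 0; npar[m.v]--;
      new_pm_v = pmask[m.v] & ~(1u << m.u);
      new_sc_v = cache.get(m.v, new_pm_v);
      delta = new_sc_v - nodescore[m.v];
    } else {                      // reverse u -> v
      adj[m.u][m.v] = 0; adj[m.v][m.u] = 1;
      npar[m.v]--; npar[m.u]++;
      new_pm_v = pmask[m.v] & ~(1u << m.u);
      new_pm_u = pmask[m.u] | (1u << m.v);
      new_sc_v = cache.get(m.v, new_pm_v);
      new_sc_u = cache.get(m.u, new_pm_u);
      delta = (new_sc_v - nodescore[m.v]) + (new_sc_u - nodescore[m.u]);
    }
    enumerate_moves(adj, npar, p, max_parents, prop_moves);
    double log_alpha = delta + std::log((double)cur_moves.size())
                             - std::log((double)prop_moves.size());
    if (std::log(unif_rand()) < log_alpha) {
      // accept
      pmask[m.v] = new_pm_v; nodescore[m.v] = new_sc_v;
      if (m.type == 2) { pmask[m.u] = new_pm_u; nodescore[m.u] = new_sc_u; }
      cur_moves.swap(prop_moves);
      accepted += 1;
    } else {
      // revert
      if (m.type == 0) { adj[m.u][m.v] = 0; npar[m.v]--; }
      else if (m.type == 1) { adj[m.u][m.v] = 1; npar[m.v]++; }
      else { adj[m.u][m.v] = 1; adj[m.v][m.u] = 0; npar[m.v]++; npar[m.u]--; }
    }
    if (s > burn_in) {
      long post = (long)(s - burn_in);
      if (post % thin == 0 && kept < n_keep) {
        for (int u = 0; u < p; ++u)
          for (int v = 0; v < p; ++v)
            samples(kept, u * p + v) = adj[u][v];
        mb_masks[kept] = mb_mask_of(adj, p, target);
        kept++;
      }
    }
  }
  double total_score = 0;
  for (int v = 0; v < p; ++v) total_score += nodescore[v];
  return List::create(
    _["samples"] = samples, _["mb_masks"] = mb_masks,
    _["n_samples"] = (double)kept,
    _["acceptance_rate"] = accepted / steps,
    _["final_log_score"] = total_score,
    _["cache_size"] = (double)cache.map.size());
}

// ---- exhaustive enumeration (exact posterior oracle) -------------------

static bool acyclic(const std::vector<std::vector<char> >& adj, int p) {
  // Kahn's algorithm
  std::vector<int> indeg(p, 0);
  for (int u = 0; u < p; ++u)
    for (int v = 0; v < p; ++v) if (adj[u][v]) indeg[v]++;
  std::vector<int> queue;
  for (int v = 0; v < p; ++v) if (indeg[v] == 0) queue.push_back(v);
  int seen = 0;
  while (!queue.empty()) {
    int u = queue.back(); queue.pop_back();
    seen++;
    for (int v = 0; v < p; ++v)
      if (adj[u][v] && --indeg[v] == 0) queue.push_back(v);
  }
  return seen == p;
}

// [[Rcpp::export]]
List cpp_exhaustive(IntegerMatrix X, IntegerVector r, int target,
                    int max_parents) {
  const int p = X.ncol();
  if (p > 5) stop("exhaustive enumeration supports at most 5 variables; use structure MCMC");
  ScoreCache cache(X, r, p);
  const int n_edges = p * (p - 1);
  std::vector<std::pair<int, int> > slots;
  for (int u = 0; u < p; ++u)
    for (int v = 0; v < p; ++v) if (u != v) slots.push_back(std::make_pair(u, v));

  std::vector<double> logscores;
  std::vector<int> mbms;
  std::vector<unsigned int> adjmasks;
  std::vector<std::vector<char> > adj(p, std::vector<char>(p, 0));

  const unsigned long total = 1ul << n_edges;
  for (unsigned long code = 0; code < total; ++code) {
    for (int u = 0; u < p; ++u) std::fill(adj[u].begin(), adj[u].end(), 0);
    std::vector<int> npar(p, 0);
    bool ok = true;
    for (int e = 0; e < n_edges; ++e) {
      if (code & (1ul << e)) {
        adj[slots[e].first][slots[e].second] = 1;
        if (++npar[slots[e].second] > max_parents) { ok = false; break; }
      }
    }
    if (!ok || !acyclic(adj, p)) continue;
    double sc = 0;
    for (int v = 0; v < p; ++v) {
      unsigned int pm = 0;
      for (int u = 0; u < p; ++u) if (adj[u][v]) pm |= (1u << u);
      sc += cache.get(v, pm);
    }
    unsigned int am = 0;
    for (int u = 0; u < p; ++u)
      for (int v = 0; v < p; ++v) if (adj[u][v]) am |= (1u << (u * p + v));
    logscores.push_back(sc);
    mbms.push_back(mb_mask_of(adj, p, target));
    adjmasks.push_back(am);
  }
  const size_t nd = logscores.size();
  double mx = R_NegInf;
  for (size_t i = 0; i < nd; ++i) if (logscores[i] > mx) mx = logscores[i];
  double Z = 0;
  std::vector<double> w(nd);
  for (size_t i = 0; i < nd; ++i) { w[i] = std::exp(logscores[i] - mx); Z += w[i]; }

  NumericVector mbm(p);
  NumericMatrix edge_post(p, p);
  std::unordered_map<int, double> mbs;
  for (size_t i = 0; i < nd; ++i) {
    double wi = w[i] / Z;
    mbs[mbms[i]] += wi;
    for (int j = 0; j < p; ++j) if (mbms[i] & (1 << j)) mbm[j] += wi;
    for (int u = 0; u < p; ++u)
      for (int v = 0; v < p; ++v)
        if (adjmasks[i] & (1u << (u * p + v))) edge_post(u, v) += wi;
  }
  IntegerVector mbs_mask(mbs.size());
  NumericVector mbs_prob(mbs.size());
  int k = 0;
  for (std::unordered_map<int, double>::const_iterator it = mbs.begin();
       it != mbs.end(); ++it) {
    mbs_mask[k] = it->first; mbs_prob[k] = it->second; k++;
  }
  return List::create(
    _["mbm"] = mbm, _["mbs_masks"] = mbs_mask, _["mbs_probs"] = mbs_prob,
    _["edge_posteriors"] = edge_post, _["n_dags"] = (double)nd,
    _["log_evidence"] = mx + std::log(Z));
}
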