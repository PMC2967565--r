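#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Decomposable family scores on a discrete sample matrix D (rows = samples,
// columns = variables, levels 1..nlev[j]).
//
// type 0: Cooper-Herskovits marginal likelihood (uniform Dirichlet(1) prior),
//         log Prod_j (r-1)!/(N_j + r - 1)! Prod_k N_jk!
// type 1: BIC, log-likelihood - 0.5 log(n) * q * (r - 1)

static double family_score(const IntegerMatrix &D, int node,
                           const std::vector<int> &parents,
                           const IntegerVector &nlev, int type) {
  const int n = D.nrow();
  const int r = nlev[node];
  int q = 1;
  for (int p : parents) q *= nlev[p];
  std::vector<double> njk((size_t)q * r, 0.0);
  std::vector<double> nj(q, 0.0);
  for (int s = 0; s < n; ++s) {
    int j = 0, base = 1;
    for (int p : parents) {
      j += (D(s, p) - 1) * base;
      base *= nlev[p];
    }
    int k = D(s, node) - 1;
    njk[(size_t)j * r + k] += 1.0;
    nj[j] += 1.0;
  }
  double score = 0.0;
  if (type == 0) {
    for (int j = 0; j < q; ++j) {
      score += std::lgamma((double)r) - std::lgamma(nj[j] + r);
      for (int k = 0; k < r; ++k)
        score += std::lgamma(njk[(size_t)j * r + k] + 1.0);
    }
  } else {
    for (int j = 0; j < q; ++j) {
      if (nj[j] == 0.0) continue;
      for (int k = 0; k < r; ++k) {
        double c = njk[(size_t)j * r + k];
        if (c > 0.0) score += c * std::log(c / nj[j]);
      }
    }
    score -= 0.5 * std::log((double)n) * q * (r - 1);
  }
  return score;
}

// [[Rcpp::export(name = ".family_score_cpp")]]
double family_score_cpp(IntegerMatrix D, int node, IntegerVector parents,
                        IntegerVector nlev, int type) {
  std::vector<int> pa(parents.begin(), parents.end());
  return family_score(D, node - 1, [&] {
    std::vector<int> v;
    for (int p : pa) v.push_back(p - 1);
    return v;
  }(), nlev, type);
}

// K2: greedy parent selection per node, candidates restricted to
// predecessors in `order` (1-based permutation), ties keep the current set.
// [[Rcpp::export(name = ".k2_cpp")]]
IntegerMatrix k2_cpp(IntegerMatrix D, IntegerVector order, int max_parents,
                     IntegerVector nlev) {
  const int N = D.ncol();
  std::vector<std::pair<int, int>> edges;
  for (int pos = 0; pos < N; ++pos) {
    int node = order[pos] - 1;
    std::vector<int> parents;
    double cur = family_score(D, node, parents, nlev, 0);
    while ((int)parents.size() < max_parents) {
      int best = -1;
      double best_score = cur;
      for (int pp = 0; pp < pos; ++pp) {
        int cand = order[pp] - 1;
        bool used = false;
        for (int p : parents) if (p == cand) { used = true; break; }
        if (used) continue;
        std::vector<int> trial = parents;
        trial.push_back(cand);
        double sc = family_score(D, node, trial, nlev, 0);
        if (sc > best_score + 1e-12) { best_score = sc; best = cand; }
      }
      if (best < 0) break;
      parents.push_back(best);
      cur = best_score;
    }
    for (int p : parents) edges.emplace_back(p, node);
  }
  IntegerMatrix out(edges.size(), 2);
  for (size_t i = 0; i < edges.size(); ++i) {
    out(i, 0) = edges[i].first + 1;
    out(i, 1) = edges[i].second + 1;
  }
  return out;
}

// path existence a ->* b over adjacency matrix (DFS), used for acyclicity
static bool has_path(const std::vector<std::vector<char>> &adj, int a, int b,
                     int N) {
  if (a == b) return true;
  std::vector<char> seen(N, 0);
  std::vector<int> stack{a};
  seen[a] = 1;
  while (!stack.empty()) {
    int u = stack.back();
    stack.pop_back();
    for (int v = 0; v < N; ++v) {
      if (adj[u][v] && !seen[v]) {
        if (v == b) return true;
        seen[v] = 1;
        stack.push_back(v);
      }
    }
  }
  return false;
}

// Greedy hill-climbing DAG search from the empty graph with add / delete /
// reverse moves. First-ascent: ordered pairs (a, b) are scanned
// lexicographically, the first strictly improving move is applied and the
// scan continues from the next pair; search stops after a full sweep with
// no improvement. type: 0 = CH marginal likelihood, 1 = BIC.
// [[Rcpp::export(name = ".greedy_cpp")]]
IntegerMatrix greedy_cpp(IntegerMatrix D, int max_parents, IntegerVector nlev,
                         int type) {
  const int N = D.ncol();
  std::vector<std::vector<char>> adj(N, std::vector<char>(N, 0));
  std::vector<std::vector<int>> parents(N);
  std::vector<double> fam(N);
  for (int v = 0; v < N; ++v) fam[v] = family_score(D, v, parents[v], nlev, type);
  const double eps = 1e-9;

  auto with_parent = [&](int v, int add, int drop) {
    std::vector<int> pa;
    for (int p : parents[v]) if (p != drop) pa.push_back(p);
    if (add >= 0) pa.push_back(add);
    return pa;
  };

  bool improved = true;
  while (improved) {
    improved = false;
    for (int a = 0; a < N; ++a) {
      for (int b = 0; b < N; ++b) {
        if (a == b) continue;
        if (!adj[a][b]) {
          // add a -> b
          if ((int)parents[b].size() >= max_parents) continue;
          if (adj[b][a]) continue;  // reverse handled from the other side
          if (has_path(adj, b, a, N)) continue;  // would create a cycle
          std::vector<int> pa = with_parent(b, a, -1);
          double sc = family_score(D, b, pa, nlev, type);
          if (sc > fam[b] + eps) {
            adj[a][b] = 1;
            parents[b] = pa;
            fam[b] = sc;
            improved = true;
          }
        } else {
          // delete a -> b
          std::vector<int> pa_del = with_parent(b, -1, a);
          double sc_del = family_score(D, b, pa_del, nlev, type);
          double delta_del = sc_del - fam[b];
          // reverse a -> b to b -> a
          double delta_rev = -1.0;
          double sc_a_rev = 0.0;
          bool rev_ok = false;
          if ((int)parents[a].size() < max_parents) {
            adj[a][b] = 0;  // temporarily drop for the cycle test
            rev_ok = !has_path(adj, a, b, N);
            adj[a][b] = 1;
            if (rev_ok) {
              std::vector<int> pa_a = with_parent(a, b, -1);
              sc_a_rev = family_score(D, a, pa_a, nlev, type);
              delta_rev = delta_del + (sc_a_rev - fam[a]);
            }
          }
          if (delta_del > eps && delta_del >= delta_rev) {
            adj[a][b] = 0;
            parents[b] = pa_del;
            fam[b] = sc_del;
            improved = true;
          } else if (rev_ok && delta_rev > eps) {
            adj[a][b] = 0;
            adj[b][a] = 1;
            parents[b] = pa_del;
            fam[b] = sc_del;
            parents[a] = with_parent(a, b, -1);
            fam[a] = sc_a_rev;
            improved = true;
          }
        }
      }
    }
  }
  std::vector<std::pair<int, int>> edges;
  for (int a = 0; a < N; ++a)
    for (int b = 0; b < N; ++b)
      if (adj[a][b]) edges.emplace_back(a, b);
  IntegerMatrix out(edges.size(), 2);
  for (size_t i = 0; i < edges.size(); ++i) {
    out(i, 0) = edges[i].first + 1;
    out(i, 1) = edges[i].second + 1;
  }
  return out;
}

// Total score of a DAG given as an edge list (for tests and invariants).
// [[Rcpp::export(name = ".dag_score_cpp")]]
double dag_score_cpp(IntegerMatrix D, IntegerMatrix edges, IntegerVector nlev,
                     int type) {
  const int N = D.ncol();
  std::vector<std::vector<int>> parents(N);
  for (int i = 0; i < edges.nrow(); ++i)
    parents[edges(i, 1) - 1].push_back(edges(i, 0) - 1);
  double total = 0.0;
  for (int v = 0; v < N; ++v)
    total += family_score(D, v, parents[v], nlev, type);
  return total;
}
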