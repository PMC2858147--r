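#include <Rcpp.h>
#include <climits>
using namespace Rcpp;

// Sequence states are nucleotide bitmasks: A=1, C=2, G=4, T=8; IUPAC
// ambiguity codes are unions of these; '-' / 'N' carry the full set 15
// (missing = union of all states, the standard Fitch convention).

namespace {

struct FitchTree {
  // Rooted-binary working representation of an unrooted tree.  Tips are
  // 0..ntip-1, internal nodes are allocated upwards from ntip; the root has
  // parent -1 and exactly two children (it subdivides one unrooted edge).
  int ntip;
  std::vector<int> kid1, kid2, par;
  std::vector<bool> tip_in;
  int root;
  int next_internal;

  FitchTree(int n) : ntip(n), kid1(2 * n, -1), kid2(2 * n, -1),
                     par(2 * n, -1), tip_in(n, false), root(-1),
                     next_internal(n) {}

  void init3(int a, int b, int c) {
    int m = next_internal++;
    int r = next_internal++;
    kid1[m] = a; kid2[m] = b; par[a] = m; par[b] = m;
    kid1[r] = m; kid2[r] = c; par[m] = r; par[c] = r;
    par[r] = -1; root = r;
    tip_in[a] = tip_in[b] = tip_in[c] = true;
  }

  // Candidate attachment points: every node except the root and one of the
  // root's children (both root-child edges are the same unrooted edge).
  void candidates(std::vector<int> &out) const {
    out.clear();
    for (int x = 0; x < next_internal; ++x) {
      if (x < ntip && !tip_in[x]) continue;
      if (x == root || x == kid2[root]) continue;
      out.push_back(x);
    }
  }

  int insert_tip(int t, int x) {  // attach tip t on edge above x
    int m = next_internal++;
    int p = par[x];
    if (kid1[p] == x) kid1[p] = m; else kid2[p] = m;
    par[m] = p;
    kid1[m] = x; kid2[m] = t;
    par[x] = m; par[t] = m;
    tip_in[t] = true;
    return m;
  }

  void remove_tip(int t) {  // inverse of insert_tip (t's parent was the last
    int m = par[t];         // allocated internal node)
    int x = (kid1[m] == t) ? kid2[m] : kid1[m];
    int p = par[m];
    if (kid1[p] == m) kid1[p] = x; else kid2[p] = x;
    par[x] = p;
    tip_in[t] = false;
    next_internal--;
  }

  void postorder(std::vector<int> &ord) const {
    ord.clear();
    std::vector<int> stack;
    std::vector<int> out;
    stack.push_back(root);
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      out.push_back(v);
      if (v >= ntip) { stack.push_back(kid1[v]); stack.push_back(kid2[v]); }
    }
    ord.assign(out.rbegin(), out.rend());
  }
};

// Fitch length of the current topology; states is ntip x S column-major
// (as an R matrix), weights per site pattern.
int fitch_score(const FitchTree &tr, const IntegerMatrix &states,
                const IntegerVector &weights,
                std::vector<int> &buf, std::vector<int> &ord) {
  const int S = states.ncol();
  const int stride = 2 * tr.ntip;
  tr.postorder(ord);
  int total = 0;
  for (int s = 0; s < S; ++s) {
    int changes = 0;
    const int off = s * stride;
    for (size_t k = 0; k < ord.size(); ++k) {
      int v = ord[k];
      if (v < tr.ntip) { buf[off + v] = states(v, s); continue; }
      int a = buf[off + tr.kid1[v]], b = buf[off + tr.kid2[v]];
      int inter = a & b;
      if (inter) buf[off + v] = inter;
      else { buf[off + v] = a | b; ++changes; }
    }
    total += changes * weights[s];
  }
  return total;
}

// Incremental scorer: caches per-node per-site state sets and per-node
// weighted union counts for the current committed topology, so candidate
// moves (leaf insertions, NNI swaps) are scored by recomputing only the
// path from the modified node to the root.
struct FitchCache {
  int S, stride;
  std::vector<int> sets;     // node-major: sets[v * S + s]
  std::vector<int> contrib;  // weighted unions at node v
  long total;

  FitchCache(int nodes_max, int S_) : S(S_), stride(S_),
    sets(nodes_max * S_, 0), contrib(nodes_max, 0), total(0) {}

  void full_eval(const FitchTree &tr, const IntegerMatrix &states,
                 const IntegerVector &weights, std::vector<int> &ord) {
    tr.postorder(ord);
    std::fill(contrib.begin(), contrib.end(), 0);
    total = 0;
    for (size_t k = 0; k < ord.size(); ++k) {
      int v = ord[k];
      if (v < tr.ntip) {
        for (int s = 0; s < S; ++s) sets[v * stride + s] = states(v, s);
        continue;
      }
      const int *a = &sets[tr.kid1[v] * stride];
      const int *b = &sets[tr.kid2[v] * stride];
      int *out = &sets[v * stride];
      long c = 0;
      for (int s = 0; s < S; ++s) {
        int inter = a[s] & b[s];
        if (inter) out[s] = inter;
        else { out[s] = a[s] | b[s]; c += weights[s]; }
      }
      contrib[v] = (int)c;
      total += c;
    }
  }

  // score after inserting tip t on the edge above x (not committed)
  long eval_insert(const FitchTree &tr, const IntegerMatrix &states,
                   const IntegerVector &weights, int t, int x) const {
    long old_path = 0;
    for (int v = tr.par[x]; v != -1; v = tr.par[v]) old_path += contrib[v];
    long new_unions = 0;
    std::vector<int> cur(S);
    // new node m joins x's stored set with tip t
    for (int s = 0; s < S; ++s) {
      int inter = sets[x * stride + s] & states(t, s);
      if (inter) cur[s] = inter;
      else { cur[s] = sets[x * stride + s] | states(t, s);
             new_unions += weights[s]; }
    }
    int child = x;
    for (int v = tr.par[x]; v != -1; v = tr.par[v]) {
      int sib = (tr.kid1[v] == child) ? tr.kid2[v] : tr.kid1[v];
      const int *o = &sets[sib * stride];
      for (int s = 0; s < S; ++s) {
        int inter = cur[s] & o[s];
        if (inter) cur[s] = inter;
        else { cur[s] |= o[s]; new_unions += weights[s]; }
      }
      child = v;
    }
    return total - old_path + new_unions;
  }

  // score after an already-applied (tentative) child swap below node m:
  // recompute m, then every ancestor of m, from stored child sets
  long eval_path(const FitchTree &tr, const IntegerVector &weights,
                 int m) const {
    long old_path = 0;
    for (int v = m; v != -1; v = tr.par[v]) old_path += contrib[v];
    long new_unions = 0;
    std::vector<int> cur(S);
    {
      const int *a = &sets[tr.kid1[m] * stride];
      const int *b = &sets[tr.kid2[m] * stride];
      for (int s = 0; s < S; ++s) {
        int inter = a[s] & b[s];
        if (inter) cur[s] = inter;
        else { cur[s] = a[s] | b[s]; new_unions += weights[s]; }
      }
    }
    int child = m;
    for (int v = tr.par[m]; v != -1; v = tr.par[v]) {
      int sib = (tr.kid1[v] == child) ? tr.kid2[v] : tr.kid1[v];
      const int *o = &sets[sib * stride];
      for (int s = 0; s < S; ++s) {
        int inter = cur[s] & o[s];
        if (inter) cur[s] = inter;
        else { cur[s] |= o[s]; new_unions += weights[s]; }
      }
      child = v;
    }
    return total - old_path + new_unions;
  }

  // score after a tentative swap across the root edge: both root children
  // have modified child sets, so recompute a, b, then the root
  long eval_root(const FitchTree &tr, const IntegerVector &weights) const {
    int r = tr.root, a = tr.kid1[r], b = tr.kid2[r];
    long old_path = contrib[a] + contrib[b] + contrib[r];
    long new_unions = 0;
    const int *a1 = &sets[tr.kid1[a] * stride];
    const int *a2 = &sets[tr.kid2[a] * stride];
    const int *b1 = &sets[tr.kid1[b] * stride];
    const int *b2 = &sets[tr.kid2[b] * stride];
    for (int s = 0; s < S; ++s) {
      int sa = a1[s] & a2[s];
      if (!sa) { sa = a1[s] | a2[s]; new_unions += weights[s]; }
      int sb = b1[s] & b2[s];
      if (!sb) { sb = b1[s] | b2[s]; new_unions += weights[s]; }
      if (!(sa & sb)) new_unions += weights[s];
    }
    return total - old_path + new_unions;
  }
};

IntegerMatrix tree_edges(const FitchTree &tr) {
  // Return edges as a 2-column matrix of internal node ids (C++ ids).
  std::vector<std::pair<int,int> > e;
  for (int x = 0; x < tr.next_internal; ++x) {
    if (x < tr.ntip && !tr.tip_in[x]) continue;
    if (x == tr.root) continue;
    e.push_back(std::make_pair(tr.par[x], x));
  }
  IntegerMatrix m(e.size(), 2);
  for (size_t i = 0; i < e.size(); ++i) { m(i,0) = e[i].first; m(i,1) = e[i].second; }
  return m;
}

void swap_children(FitchTree &tr, int A, bool firstA, int B, bool firstB) {
  int &ca = firstA ? tr.kid1[A] : tr.kid2[A];
  int &cb = firstB ? tr.kid1[B] : tr.kid2[B];
  int u = ca, v = cb;
  ca = v; cb = u;
  tr.par[u] = B; tr.par[v] = A;
}

// One NNI hill-climbing run (first-improvement, deterministic node order).
// `cache` must hold the full evaluation of the current tree; it is
// refreshed after every accepted move.
int nni_climb(FitchTree &tr, const IntegerMatrix &states,
              const IntegerVector &weights, int best, FitchCache &cache,
              std::vector<int> &ord, int max_moves) {
  bool improved = true;
  int moves = 0;
  while (improved && moves < max_moves) {
    improved = false;
    for (int m = tr.ntip; m < tr.next_internal && !improved; ++m) {
      if (m == tr.root) continue;
      int p = tr.par[m];
      if (p == tr.root) continue;  // handled via the root edge below
      bool mIsFirst = (tr.kid1[p] == m);
      for (int which = 0; which < 2 && !improved; ++which) {
        swap_children(tr, m, which == 0, p, !mIsFirst);
        long sc = cache.eval_path(tr, weights, m);
        if (sc < best) {
          best = (int)sc; improved = true; ++moves;
          cache.full_eval(tr, states, weights, ord);
        } else {
          swap_children(tr, m, which == 0, p, !mIsFirst);
        }
      }
    }
    if (!improved) {
      int a = tr.kid1[tr.root], b = tr.kid2[tr.root];
      if (a >= tr.ntip && b >= tr.ntip) {
        for (int which = 0; which < 2 && !improved; ++which) {
          swap_children(tr, a, false, b, which == 0);
          long sc = cache.eval_root(tr, weights);
          if (sc < best) {
            best = (int)sc; improved = true; ++moves;
            cache.full_eval(tr, states, weights, ord);
          } else {
            swap_children(tr, a, false, b, which == 0);
          }
        }
      }
    }
  }
  return best;
}

void copy_tree(const FitchTree &src, FitchTree &dst) { dst = src; }

void exact_rec(FitchTree &tr, const IntegerVector &order, int i,
               const IntegerMatrix &states, const IntegerVector &weights,
               std::vector<int> &buf, std::vector<int> &ord,
               int &best, FitchTree &best_tree) {
  if (i == order.size()) {
    int sc = fitch_score(tr, states, weights, buf, ord);
    if (sc < best) { best = sc; copy_tree(tr, best_tree); }
    return;
  }
  std::vector<int> cand;
  tr.candidates(cand);
  for (size_t j = 0; j < cand.size(); ++j) {
    tr.insert_tip(order[i], cand[j]);
    exact_rec(tr, order, i + 1, states, weights, buf, ord, best, best_tree);
    tr.remove_tip(order[i]);
  }
}

}  // namespace

// [[Rcpp::export]]
int cpp_fitch_edges(IntegerMatrix states, IntegerVector weights,
                    IntegerMatrix edge, int ntip) {
  // Fitch length for a rooted-binary ape edge matrix (1-based node ids,
  // tips 1..ntip), edges already in postorder (ape reorder "postorder").
  int nnode = 0;
  for (int i = 0; i < edge.nrow(); ++i)
    nnode = std::max(nnode, std::max(edge(i,0), edge(i,1)));
  const int S = states.ncol();
  std::vector<int> set_(nnode);
  long total = 0;
  for (int s = 0; s < S; ++s) {
    int changes = 0;
    for (int i = 0; i < edge.nrow(); ++i) {
      int child = edge(i,1) - 1;
      if (child < ntip) set_[child] = states(child, s);
    }
    // process edges in postorder, accumulating into parents
    std::vector<int> acc(nnode, 0);
    std::vector<int> nk(nnode, 0);
    for (int i = 0; i < edge.nrow(); ++i) {
      int p = edge(i,0) - 1, c = edge(i,1) - 1;
      int cs = (c < ntip) ? states(c, s) : set_[c];
      if (nk[p] == 0) { acc[p] = cs; nk[p] = 1; }
      else {
        int inter = acc[p] & cs;
        if (inter) acc[p] = inter; else { acc[p] |= cs; ++changes; }
        nk[p]++;
      }
      set_[p] = acc[p];
    }
    total += (long)changes * weights[s];
  }
  return (int)total;
}

// [[Rcpp::export]]
List cpp_mp_search(IntegerMatrix states, IntegerVector weights,
                   IntegerVector order, int nni_max) {
  const int ntip = states.nrow();
  FitchTree tr(ntip);
  std::vector<int> ord;
  if (ntip == 3) {
    std::vector<int> buf(2 * ntip * states.ncol());
    tr.init3(order[0], order[1], order[2]);
    int sc = fitch_score(tr, states, weights, buf, ord);
    return List::create(_["edge"] = tree_edges(tr), _["length"] = sc,
                        _["root"] = tr.root);
  }
  tr.init3(order[0], order[1], order[2]);
  FitchCache cache(2 * ntip, states.ncol());
  cache.full_eval(tr, states, weights, ord);
  std::vector<int> cand;
  for (int i = 3; i < ntip; ++i) {
    tr.candidates(cand);
    long best_sc = LONG_MAX; int best_x = -1;
    for (size_t j = 0; j < cand.size(); ++j) {
      long sc = cache.eval_insert(tr, states, weights, order[i], cand[j]);
      if (sc < best_sc) { best_sc = sc; best_x = cand[j]; }
    }
    tr.insert_tip(order[i], best_x);
    cache.full_eval(tr, states, weights, ord);
  }
  int best = (int)cache.total;
  best = nni_climb(tr, states, weights, best, cache, ord, nni_max);
  return List::create(_["edge"] = tree_edges(tr), _["length"] = best,
                      _["root"] = tr.root);
}

// [[Rcpp::export]]
List cpp_mp_exact(IntegerMatrix states, IntegerVector weights) {
  const int ntip = states.nrow();
  FitchTree tr(ntip), best_tree(ntip);
  std::vector<int> buf(2 * ntip * states.ncol());
  std::vector<int> ord;
  IntegerVector order(ntip);
  for (int i = 0; i < ntip; ++i) order[i] = i;
  tr.init3(0, 1, 2);
  int best = INT_MAX;
  if (ntip == 3) {
    best = fitch_score(tr, states, weights, buf, ord);
    copy_tree(tr, best_tree);
  } else {
    exact_rec(tr, order, 3, states, weights, buf, ord, best, best_tree);
  }
  return List::create(_["edge"] = tree_edges(best_tree), _["length"] = best,
                      _["root"] = best_tree.root);
}

// [[Rcpp::export]]
NumericVector cpp_phi_perms(NumericMatrix L, IntegerVector ia,
                            IntegerVector ib, int n_perm) {
  // permutation null for the Phi statistic: permute which informative
  // site occupies which alignment position (R's RNG, so seed-controlled)
  const int S = L.nrow();
  const int np = ia.size();
  NumericVector out(n_perm);
  for (int k = 0; k < n_perm; ++k) {
    IntegerVector p = Rcpp::sample(S, S, false);
    double s = 0; int cnt = 0;
    for (int j = 0; j < np; ++j) {
      double v = L(p[ia[j] - 1] - 1, p[ib[j] - 1] - 1);
      if (!ISNAN(v)) { s += v; ++cnt; }
    }
    out[k] = cnt ? s / cnt : NA_REAL;
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_pair_incompat(IntegerMatrix X) {
  // X: n x S site matrix coded 0 (missing/ambiguous/gap) or 1..4.
  // Returns the refined-incompatibility score l for every site pair:
  // l = V + C - k_a - k_b with V = distinct joint states, C = connected
  // components of the bipartite state-sharing graph, k = per-site state
  // counts.  NA when fewer than two jointly scored sequences remain.
  const int n = X.nrow(), S = X.ncol();
  NumericMatrix L(S, S);
  std::vector<int> parent(8);
  for (int a = 0; a < S; ++a) {
    L(a, a) = 0.0;
    for (int b = a + 1; b < S; ++b) {
      bool joint[4][4] = {{false}};
      bool sa[4] = {false}, sb[4] = {false};
      int used = 0;
      for (int i = 0; i < n; ++i) {
        int xa = X(i, a), xb = X(i, b);
        if (xa == 0 || xb == 0) continue;
        joint[xa - 1][xb - 1] = true;
        sa[xa - 1] = true; sb[xb - 1] = true;
        ++used;
      }
      if (used < 2) { L(a, b) = L(b, a) = NA_REAL; continue; }
      int V = 0, ka = 0, kb = 0;
      for (int i = 0; i < 4; ++i) { if (sa[i]) ++ka; if (sb[i]) ++kb; }
      for (int i = 0; i < 8; ++i) parent[i] = i;
      // union-find over the bipartite graph (a-states 0..3, b-states 4..7)
      for (int i = 0; i < 4; ++i)
        for (int j = 0; j < 4; ++j)
          if (joint[i][j]) {
            ++V;
            int u = i, v = 4 + j;
            while (parent[u] != u) u = parent[u];
            while (parent[v] != v) v = parent[v];
            if (u != v) parent[u] = v;
          }
      int C = 0;
      for (int i = 0; i < 4; ++i) if (sa[i] && parent[i] == i) ++C;
      for (int j = 0; j < 4; ++j) if (sb[j] && parent[4 + j] == 4 + j) ++C;
      double l = (double)V + C - ka - kb;
      L(a, b) = L(b, a) = l;
    }
  }
  return L;
}
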