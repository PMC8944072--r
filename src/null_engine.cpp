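#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Graphs arrive as CSR adjacency (0-based): indptr has length n_nodes + 1,
// indices lists the neighbours of node v in [indptr[v], indptr[v+1]).
// Undirected edges are stored twice. All null engines consume R's RNG
// (unif_rand) so draws are reproducible under set.seed().

static inline int runif_int(int n) {
  // uniform integer on 0..n-1; unif_rand() is on the open interval (0,1)
  int k = (int)(unif_rand() * n);
  return (k >= n) ? n - 1 : k;
}

// Draw `count` nodes without replacement from pool[0..size) by partial
// Fisher-Yates; the drawn nodes end up in pool[0..count). The pool stays
// permuted between calls, which does not bias later draws.
static inline void draw_into(std::vector<int> &pool, int count) {
  int n = (int)pool.size();
  for (int j = 0; j < count; ++j) {
    int idx = j + runif_int(n - j);
    std::swap(pool[j], pool[idx]);
  }
}

// Size of the largest connected component of the subgraph induced by
// `members`, using stamp arrays sized to the full graph.
static int lcc_of(const int *indptr, const int *indices,
                  const std::vector<int> &members, int stamp,
                  std::vector<int> &mark, std::vector<int> &seen,
                  std::vector<int> &stack) {
  for (size_t i = 0; i < members.size(); ++i) mark[members[i]] = stamp;
  int best = 0;
  for (size_t i = 0; i < members.size(); ++i) {
    int v = members[i];
    if (seen[v] == stamp) continue;
    // BFS from v restricted to marked nodes
    int comp = 0;
    stack.clear();
    stack.push_back(v);
    seen[v] = stamp;
    while (!stack.empty()) {
      int u = stack.back();
      stack.pop_back();
      ++comp;
      for (int e = indptr[u]; e < indptr[u + 1]; ++e) {
        int w = indices[e];
        if (mark[w] == stamp && seen[w] != stamp) {
          seen[w] = stamp;
          stack.push_back(w);
        }
      }
    }
    if (comp > best) best = comp;
  }
  return best;
}

// [[Rcpp::export]]
int cpp_lcc_size(IntegerVector indptr, IntegerVector indices,
                 IntegerVector members, int n_nodes) {
  if (members.size() == 0) return 0;
  std::vector<int> mem(members.begin(), members.end());
  std::vector<int> mark(n_nodes, -1), seen(n_nodes, -1), stack;
  return lcc_of(indptr.begin(), indices.begin(), mem, 0, mark, seen, stack);
}

// [[Rcpp::export]]
IntegerVector cpp_lcc_members(IntegerVector indptr, IntegerVector indices,
                              IntegerVector members, int n_nodes) {
  // 0-based node ids of the largest connected induced component
  std::vector<int> mark(n_nodes, -1), seen(n_nodes, -1), stack, best, cur;
  for (int i = 0; i < members.size(); ++i) mark[members[i]] = 0;
  for (int i = 0; i < members.size(); ++i) {
    int v = members[i];
    if (seen[v] == 0) continue;
    cur.clear();
    stack.clear();
    stack.push_back(v);
    seen[v] = 0;
    while (!stack.empty()) {
      int u = stack.back();
      stack.pop_back();
      cur.push_back(u);
      for (int e = indptr[u]; e < indptr[u + 1]; ++e) {
        int w = indices[e];
        if (mark[w] == 0 && seen[w] != 0) {
          seen[w] = 0;
          stack.push_back(w);
        }
      }
    }
    if (cur.size() > best.size()) best = cur;
  }
  return IntegerVector(best.begin(), best.end());
}

static std::vector<std::vector<int> > pools_from(List bin_nodes) {
  std::vector<std::vector<int> > pools;
  for (int b = 0; b < bin_nodes.size(); ++b) {
    IntegerVector bn = bin_nodes[b];
    pools.push_back(std::vector<int>(bn.begin(), bn.end()));
  }
  return pools;
}

// [[Rcpp::export]]
IntegerVector cpp_null_lcc(IntegerVector indptr, IntegerVector indices,
                           int n_nodes, List bin_nodes,
                           IntegerVector bin_counts, int n_samples) {
  std::vector<std::vector<int> > pools = pools_from(bin_nodes);
  int nb = (int)pools.size();
  int k = 0;
  for (int b = 0; b < nb; ++b) k += bin_counts[b];
  IntegerVector out(n_samples);
  std::vector<int> mark(n_nodes, -1), seen(n_nodes, -1), stack, sel;
  sel.reserve(k);
  for (int s = 0; s < n_samples; ++s) {
    sel.clear();
    for (int b = 0; b < nb; ++b) {
      int c = bin_counts[b];
      if (c == 0) continue;
      draw_into(pools[b], c);
      for (int j = 0; j < c; ++j) sel.push_back(pools[b][j]);
    }
    out[s] = lcc_of(indptr.begin(), indices.begin(), sel, s, mark, seen, stack);
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_null_within(IntegerVector indptr, IntegerVector indices,
                              int n_nodes, List bin_nodes,
                              IntegerVector bin_counts, int n_samples) {
  std::vector<std::vector<int> > pools = pools_from(bin_nodes);
  int nb = (int)pools.size();
  IntegerVector out(n_samples);
  std::vector<int> mark(n_nodes, -1), sel;
  const int *ip = indptr.begin(), *ix = indices.begin();
  for (int s = 0; s < n_samples; ++s) {
    sel.clear();
    for (int b = 0; b < nb; ++b) {
      int c = bin_counts[b];
      if (c == 0) continue;
      draw_into(pools[b], c);
      for (int j = 0; j < c; ++j) sel.push_back(pools[b][j]);
    }
    for (size_t i = 0; i < sel.size(); ++i) mark[sel[i]] = s;
    int cnt = 0;
    for (size_t i = 0; i < sel.size(); ++i) {
      int v = sel[i];
      for (int e = ip[v]; e < ip[v + 1]; ++e) {
        int w = ix[e];
        if (mark[w] == s && w > v) ++cnt;  // each undirected edge once
      }
    }
    out[s] = cnt;
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_null_cross(IntegerVector indptr, IntegerVector indices,
                             int n_nodes, List bin_nodes,
                             IntegerVector counts_a, IntegerVector counts_b,
                             int n_samples) {
  // Jointly resample degree-matched surrogates for two disjoint sets:
  // within each bin draw cA+cB nodes without replacement, assign the first
  // cA to A and the rest to B, then count A-B edges.
  std::vector<std::vector<int> > pools = pools_from(bin_nodes);
  int nb = (int)pools.size();
  IntegerVector out(n_samples);
  std::vector<int> side(n_nodes, -1), sela, selb;
  const int *ip = indptr.begin(), *ix = indices.begin();
  for (int s = 0; s < n_samples; ++s) {
    sela.clear();
    selb.clear();
    for (int b = 0; b < nb; ++b) {
      int ca = counts_a[b], cb = counts_b[b];
      if (ca + cb == 0) continue;
      draw_into(pools[b], ca + cb);
      for (int j = 0; j < ca; ++j) sela.push_back(pools[b][j]);
      for (int j = ca; j < ca + cb; ++j) selb.push_back(pools[b][j]);
    }
    for (size_t i = 0; i < sela.size(); ++i) side[sela[i]] = 2 * s;
    for (size_t i = 0; i < selb.size(); ++i) side[selb[i]] = 2 * s + 1;
    int cnt = 0;
    for (size_t i = 0; i < sela.size(); ++i) {
      int v = sela[i];
      for (int e = ip[v]; e < ip[v + 1]; ++e)
        if (side[ix[e]] == 2 * s + 1) ++cnt;
    }
    out[s] = cnt;
  }
  return out;
}

// [[Rcpp::export]]
int cpp_count_cross(IntegerVector indptr, IntegerVector indices, int n_nodes,
                    IntegerVector a, IntegerVector b) {
  std::vector<int> side(n_nodes, -1);
  for (int i = 0; i < a.size(); ++i) side[a[i]] = 0;
  for (int i = 0; i < b.size(); ++i) side[b[i]] = 1;
  int cnt = 0;
  const int *ip = indptr.begin(), *ix = indices.begin();
  for (int i = 0; i < a.size(); ++i) {
    int v = a[i];
    for (int e = ip[v]; e < ip[v + 1]; ++e)
      if (side[ix[e]] == 1) ++cnt;
  }
  return cnt;
}

// [[Rcpp::export]]
int cpp_count_within(IntegerVector indptr, IntegerVector indices, int n_nodes,
                     IntegerVector members) {
  std::vector<int> mark(n_nodes, -1);
  for (int i = 0; i < members.size(); ++i) mark[members[i]] = 0;
  int cnt = 0;
  const int *ip = indptr.begin(), *ix = indices.begin();
  for (int i = 0; i < members.size(); ++i) {
    int v = members[i];
    for (int e = ip[v]; e < ip[v + 1]; ++e) {
      int w = ix[e];
      if (mark[w] == 0 && w > v) ++cnt;
    }
  }
  return cnt;
}
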