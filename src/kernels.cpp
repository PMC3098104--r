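#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <climits>
#include <functional>
using namespace Rcpp;

// Greedy one-to-one matching of two sorted band lists of a single type.
// Two-pointer sweep: advance the smaller size; a band participates in at
// most one match. Sizes must be sorted ascending.
static int match_type(const int* a, int na, const int* b, int nb, int tol,
                      std::vector<std::pair<int,int> >* pairs,
                      int off_a, int off_b, double* kw,
                      const double* wa) {
  int i = 0, j = 0, k = 0;
  while (i < na && j < nb) {
    int d = a[i] - b[j];
    if (d < -tol) { ++i; }
    else if (d > tol) { ++j; }
    else {
      ++k;
      if (pairs) pairs->push_back(std::make_pair(off_a + i, off_b + j));
      if (kw && wa) *kw += wa[i];
      ++i; ++j;
    }
  }
  return k;
}

// Greedy shared-band count between two fingerprints, bands sorted by
// (type, size). Returns count and 1-based matched index pairs.
// [[Rcpp::export]]
List cpp_pair_overlap(IntegerVector type1, IntegerVector size1,
                      IntegerVector type2, IntegerVector size2, int tol) {
  std::vector<std::pair<int,int> > pairs;
  int n1 = type1.size(), n2 = type2.size();
  int i = 0, j = 0, k = 0;
  while (i < n1 && j < n2) {
    if (type1[i] < type2[j]) { ++i; continue; }
    if (type1[i] > type2[j]) { ++j; continue; }
    int t = type1[i];
    int i2 = i, j2 = j;
    while (i2 < n1 && type1[i2] == t) ++i2;
    while (j2 < n2 && type2[j2] == t) ++j2;
    k += match_type(&size1[i], i2 - i, &size2[j], j2 - j, tol,
                    &pairs, i, j, (double*)0, (double*)0);
    i = i2; j = j2;
  }
  IntegerMatrix pm(pairs.size(), 2);
  for (size_t r = 0; r < pairs.size(); ++r) {
    pm(r, 0) = pairs[r].first + 1;
    pm(r, 1) = pairs[r].second + 1;
  }
  return List::create(_["k"] = k, _["pairs"] = pm);
}

// All-pairs greedy shared-band counts over a fingerprint database.
// Bands are concatenated per clone (sorted by type then size within clone);
// starts is a 0-based offset vector of length n_clones + 1.
// weights holds -ln f_b per band (may be length 0 to skip k_weighted).
// Pairs with k < min_k are not reported.
// [[Rcpp::export]]
DataFrame cpp_all_pairs(IntegerVector starts, IntegerVector types,
                        IntegerVector sizes, NumericVector weights,
                        int tol, int min_k) {
  int n = starts.size() - 1;
  bool wt = weights.size() == sizes.size();
  std::vector<int> vi, vj, vk;
  std::vector<double> vkw;
  for (int a = 0; a < n; ++a) {
    int sa = starts[a], ea = starts[a + 1];
    for (int b = a + 1; b < n; ++b) {
      int sb = starts[b], eb = starts[b + 1];
      int i = sa, j = sb, k = 0;
      double kw = 0.0;
      while (i < ea && j < eb) {
        if (types[i] < types[j]) { ++i; continue; }
        if (types[i] > types[j]) { ++j; continue; }
        int t = types[i];
        int i2 = i, j2 = j;
        while (i2 < ea && types[i2] == t) ++i2;
        while (j2 < eb && types[j2] == t) ++j2;
        k += match_type(&sizes[i], i2 - i, &sizes[j], j2 - j, tol,
                        (std::vector<std::pair<int,int> >*)0, 0, 0,
                        wt ? &kw : (double*)0, wt ? &weights[i] : (double*)0);
        i = i2; j = j2;
      }
      if (k >= min_k) {
        vi.push_back(a + 1); vj.push_back(b + 1);
        vk.push_back(k); vkw.push_back(kw);
      }
    }
  }
  return DataFrame::create(_["i"] = vi, _["j"] = vj, _["k"] = vk,
                           _["kw"] = vkw);
}

// Fast internal PRNG (xoshiro256++), seeded from R's RNG so that results
// remain reproducible under set.seed(); unif_rand() is too slow for the
// calibration volume (hundreds of models x 2e5 clone pairs x ~250 draws).
struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro() {
    for (int i = 0; i < 4; ++i) {
      uint64_t hi = (uint64_t)(unif_rand() * 4294967296.0);
      uint64_t lo = (uint64_t)(unif_rand() * 4294967296.0);
      s[i] = (hi << 32) ^ lo ^ (uint64_t)0x9E3779B97F4A7C15ULL;
    }
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  double runif() { return (next() >> 11) * 0x1.0p-53; }
};

// Monte-Carlo null for the shared-band count: both clones draw bands
// uniformly (with replacement, duplicates collapse) from a universe of G
// values; the statistic is the exact-match intersection size.
// [[Rcpp::export]]
IntegerVector cpp_mc_counts(int n1, int n2, int G, int reps) {
  IntegerVector out(reps);
  Xoshiro rng;
  std::vector<int> stamp1(G + 1, -1), stamp2(G + 1, -1);
  for (int r = 0; r < reps; ++r) {
    for (int d = 0; d < n1; ++d) {
      int v = (int)(rng.runif() * G) + 1;
      if (v > G) v = G;
      stamp1[v] = r;
    }
    int k = 0;
    for (int d = 0; d < n2; ++d) {
      int v = (int)(rng.runif() * G) + 1;
      if (v > G) v = G;
      if (stamp2[v] != r) { stamp2[v] = r; if (stamp1[v] == r) ++k; }
    }
    out[r] = k;
  }
  return out;
}

// Monte-Carlo null for the abundance-weighted statistic k_w = -sum ln f_b:
// bands are drawn from the band-class distribution probs (normalized
// internally), duplicates collapse, shared classes contribute weights[c].
// Walker alias sampling gives O(1) draws.
// [[Rcpp::export]]
NumericVector cpp_mc_weighted(int n1, int n2, NumericVector probs,
                              NumericVector weights, int reps) {
  int G = probs.size();
  // build alias table
  double tot = 0;
  for (int i = 0; i < G; ++i) tot += probs[i];
  std::vector<double> q(G);
  std::vector<int> alias(G, 0);
  std::vector<int> small, large;
  for (int i = 0; i < G; ++i) {
    q[i] = probs[i] / tot * G;
    (q[i] < 1.0 ? small : large).push_back(i);
  }
  while (!small.empty() && !large.empty()) {
    int s = small.back(); small.pop_back();
    int l = large.back(); large.pop_back();
    alias[s] = l;
    q[l] = q[l] + q[s] - 1.0;
    (q[l] < 1.0 ? small : large).push_back(l);
  }
  while (!large.empty()) { q[large.back()] = 1.0; large.pop_back(); }
  while (!small.empty()) { q[small.back()] = 1.0; small.pop_back(); }
  NumericVector out(reps);
  Xoshiro rng;
  std::vector<int> stamp1(G, -1), stamp2(G, -1);
  for (int r = 0; r < reps; ++r) {
    for (int d = 0; d < n1; ++d) {
      double u = rng.runif() * G;
      int v = (int)u;
      if (v >= G) v = G - 1;
      if (u - v >= q[v]) v = alias[v];
      stamp1[v] = r;
    }
    double kw = 0.0;
    for (int d = 0; d < n2; ++d) {
      double u = rng.runif() * G;
      int v = (int)u;
      if (v >= G) v = G - 1;
      if (u - v >= q[v]) v = alias[v];
      if (stamp2[v] != r) { stamp2[v] = r; if (stamp1[v] == r) kw += weights[v]; }
    }
    out[r] = kw;
  }
  return out;
}

// ---- bounded parallel-path search -------------------------------------
// Graph in CSR form: adj_ptr (n+1, 0-based), adj_idx (0-based neighbor ids).

struct PathSearch {
  const int* ptr; const int* idx; int n;
  std::vector<int> dist, dstamp, onpath, pstamp;
  int stamp;
  PathSearch(const int* p, const int* x, int n_)
      : ptr(p), idx(x), n(n_), dist(n_), dstamp(n_, -1), onpath(n_),
        pstamp(n_, -1), stamp(0) {}

  // BFS from src up to depth maxd, avoiding vertex 'avoid' (-1 = none).
  void bfs(int src, int maxd, int avoid) {
    ++stamp;
    std::vector<int> q;
    q.push_back(src);
    dstamp[src] = stamp; dist[src] = 0;
    size_t head = 0;
    while (head < q.size()) {
      int v = q[head++];
      if (dist[v] >= maxd) continue;
      for (int e = ptr[v]; e < ptr[v + 1]; ++e) {
        int w = idx[e];
        if (w == avoid || dstamp[w] == stamp) continue;
        dstamp[w] = stamp; dist[w] = dist[v] + 1;
        q.push_back(w);
      }
    }
  }
  int d(int v) const { return dstamp[v] == stamp ? dist[v] : INT_MAX; }

  // Depth-first search for a simple path src..dst of length in [lmin, lmax]
  // avoiding vertex 'avoid' and (optionally) the direct edge src-dst
  // (ban_u/ban_v). Pruned by the BFS lower bound d().
  bool dfs(int v, int dst, int depth, int lmin, int lmax,
           int avoid, int ban_u, int ban_v) {
    if (v == dst) return depth >= lmin;
    if (depth >= lmax) return false;
    for (int e = ptr[v]; e < ptr[v + 1]; ++e) {
      int w = idx[e];
      if (w == avoid) continue;
      if ((v == ban_u && w == ban_v) || (v == ban_v && w == ban_u)) continue;
      if (w != dst && pstamp[w] == stamp && onpath[w]) continue;
      if (w == dst && depth + 1 < lmin) continue;
      int rem = d(w);
      if (rem == INT_MAX || depth + 1 + rem > lmax) continue;
      if (w != dst) { pstamp[w] = stamp; onpath[w] = 1; }
      bool hit = dfs(w, dst, depth + 1, lmin, lmax, avoid, ban_u, ban_v);
      if (w != dst) onpath[w] = 0;  // clean up even on success
      if (hit) return true;
    }
    return false;
  }

  bool query(int u, int v, int lmin, int lmax, int avoid, bool ban_direct) {
    bfs(v, lmax, avoid);  // lower bounds towards target
    if (pstamp[u] == stamp) { /* keep stamps aligned */ }
    pstamp[u] = stamp; onpath[u] = 1;
    bool ok = dfs(u, v, 0, lmin, lmax, avoid,
                  ban_direct ? u : -1, ban_direct ? v : -1);
    onpath[u] = 0;
    return ok;
  }
};

// For each edge (u,v): is there a parallel simple path of lmin..lmax edges
// connecting u and v without using the edge itself?
// [[Rcpp::export]]
LogicalVector cpp_edge_support(int n, IntegerVector adj_ptr,
                               IntegerVector adj_idx,
                               IntegerVector eu, IntegerVector ev,
                               int lmin, int lmax) {
  PathSearch ps(&adj_ptr[0], &adj_idx[0], n);
  int m = eu.size();
  LogicalVector out(m);
  for (int e = 0; e < m; ++e)
    out[e] = ps.query(eu[e], ev[e], lmin, lmax, -1, true);
  return out;
}

// For each vertex c0: do all pairs of its neighbors have a parallel simple
// path of lmin..lmax edges avoiding c0? Returns per-vertex support flag.
// [[Rcpp::export]]
LogicalVector cpp_vertex_support(int n, IntegerVector adj_ptr,
                                 IntegerVector adj_idx,
                                 IntegerVector verts, int lmin, int lmax) {
  PathSearch ps(&adj_ptr[0], &adj_idx[0], n);
  int m = verts.size();
  LogicalVector out(m);
  for (int q = 0; q < m; ++q) {
    int c0 = verts[q];
    bool ok = true;
    int deg = adj_ptr[c0 + 1] - adj_ptr[c0];
    for (int a = 0; a < deg && ok; ++a) {
      int c2 = adj_idx[adj_ptr[c0] + a];
      ps.bfs(c2, lmax, c0);
      for (int b = 0; b < a && ok; ++b) {
        int c1 = adj_idx[adj_ptr[c0] + b];
        ps.pstamp[c1] = ps.stamp; ps.onpath[c1] = 1;
        bool found = ps.dfs(c1, c2, 0, lmin, lmax, c0, -1, -1);
        ps.onpath[c1] = 0;
        if (!found) ok = false;
      }
    }
    out[q] = ok;
  }
  return out;
}

// ---- open-path TSP heuristic ------------------------------------------
// Nearest-neighbour construction from a given start plus 2-opt (segment
// reversal) and Or-opt (relocation of 1..3 clone blocks) until no gain.

static double path_len(const std::vector<int>& p, const NumericMatrix& d) {
  double s = 0;
  for (size_t i = 1; i < p.size(); ++i) s += d(p[i - 1], p[i]);
  return s;
}

static void improve(std::vector<int>& p, const NumericMatrix& d) {
  int n = p.size();
  bool gain = true;
  while (gain) {
    gain = false;
    // 2-opt: reverse p[i..j]; for an open path the cost change only
    // involves the (up to two) boundary edges.
    for (int i = 0; i < n - 1; ++i) {
      for (int j = i + 1; j < n; ++j) {
        double delta = 0;
        if (i > 0) delta += d(p[i - 1], p[j]) - d(p[i - 1], p[i]);
        if (j < n - 1) delta += d(p[i], p[j + 1]) - d(p[j], p[j + 1]);
        if (delta < -1e-12) {
          std::reverse(p.begin() + i, p.begin() + j + 1);
          gain = true;
        }
      }
    }
    // Or-opt: move a block of 1..8 consecutive clones elsewhere, in either
    // orientation (insertion before original position j); O(1) delta per
    // candidate. Long blocks matter: the typical stuck configuration is a
    // whole sub-segment hooked onto the wrong contig end.
    int maxblk = n < 8 ? n - 1 : 8;
    for (int len = 1; len <= maxblk; ++len) {
      for (int a = 0; a + len <= n; ++a) {
        int b = a + len - 1;
        double removed = 0;
        if (a > 0) removed += d(p[a - 1], p[a]);
        if (b < n - 1) removed += d(p[b], p[b + 1]);
        double closed = (a > 0 && b < n - 1) ? d(p[a - 1], p[b + 1]) : 0.0;
        bool moved = false;
        for (int j = 0; j <= n && !moved; ++j) {
          if (j >= a && j <= b + 1) continue;  // inside block or no-op
          double broken = (j > 0 && j < n) ? d(p[j - 1], p[j]) : 0.0;
          for (int rev = 0; rev < 2 && !moved; ++rev) {
            int head = rev ? p[b] : p[a];   // first clone after insertion
            int tail2 = rev ? p[a] : p[b];  // last clone of inserted block
            double added;
            if (j == 0) added = d(tail2, p[0]);
            else if (j == n) added = d(p[n - 1], head);
            else added = d(p[j - 1], head) + d(tail2, p[j]);
            double delta = closed - removed - broken + added;
            if (delta < -1e-12) {
              std::vector<int> q, r;
              q.reserve(n - len); r.reserve(n);
              for (int t = 0; t < n; ++t)
                if (t < a || t > b) q.push_back(p[t]);
              int jj = (j > b) ? j - len : j;
              r.assign(q.begin(), q.begin() + jj);
              if (rev) for (int t = b; t >= a; --t) r.push_back(p[t]);
              else for (int t = a; t <= b; ++t) r.push_back(p[t]);
              r.insert(r.end(), q.begin() + jj, q.end());
              p = r; gain = true; moved = true;
            }
          }
        }
      }
    }
  }
}

// Greedy-edge construction: repeatedly add the cheapest edge that joins
// two distinct path fragments at their free ends (union-find, degree <= 2).
// Unlike nearest-neighbour it does not produce "hooks" that start a path
// mid-region and double back.
static std::vector<int> greedy_edge_path(const NumericMatrix& d) {
  int n = d.nrow();
  struct E { double w; int a, b; };
  std::vector<E> es;
  es.reserve((size_t)n * (n - 1) / 2);
  for (int a = 0; a < n; ++a)
    for (int b = a + 1; b < n; ++b)
      es.push_back(E{d(a, b), a, b});
  std::sort(es.begin(), es.end(),
            [](const E& x, const E& y) { return x.w < y.w; });
  std::vector<int> comp(n), deg(n, 0);
  std::vector<std::vector<int> > adj(n);
  for (int i = 0; i < n; ++i) comp[i] = i;
  std::function<int(int)> find = [&](int v) {
    while (comp[v] != v) { comp[v] = comp[comp[v]]; v = comp[v]; }
    return v;
  };
  int added = 0;
  for (size_t i = 0; i < es.size() && added < n - 1; ++i) {
    int a = es[i].a, b = es[i].b;
    if (deg[a] >= 2 || deg[b] >= 2) continue;
    int ra = find(a), rb = find(b);
    if (ra == rb) continue;
    comp[ra] = rb;
    adj[a].push_back(b); adj[b].push_back(a);
    ++deg[a]; ++deg[b]; ++added;
  }
  // walk the single path from one endpoint
  int start = 0;
  for (int v = 0; v < n; ++v) if (deg[v] <= 1) { start = v; break; }
  std::vector<int> p;
  std::vector<char> used(n, 0);
  int cur = start, prev = -1;
  for (int step = 0; step < n; ++step) {
    p.push_back(cur); used[cur] = 1;
    int nxt = -1;
    for (size_t e = 0; e < adj[cur].size(); ++e)
      if (adj[cur][e] != prev && !used[adj[cur][e]]) { nxt = adj[cur][e]; break; }
    if (nxt < 0) break;
    prev = cur; cur = nxt;
  }
  for (int v = 0; v < n; ++v) if (!used[v]) p.push_back(v);  // safety
  return p;
}

// [[Rcpp::export]]
IntegerVector cpp_tsp_path(NumericMatrix d, IntegerVector starts) {
  int n = d.nrow();
  std::vector<int> best;
  double best_len = R_PosInf;
  {
    std::vector<int> p = greedy_edge_path(d);
    improve(p, d);
    double len = path_len(p, d);
    if (len < best_len) { best_len = len; best = p; }
  }
  for (int s = 0; s < starts.size(); ++s) {
    std::vector<int> p;
    std::vector<char> used(n, 0);
    int cur = starts[s];
    p.push_back(cur); used[cur] = 1;
    for (int step = 1; step < n; ++step) {
      int nxt = -1; double bd = R_PosInf;
      for (int v = 0; v < n; ++v)
        if (!used[v] && d(cur, v) < bd) { bd = d(cur, v); nxt = v; }
      p.push_back(nxt); used[nxt] = 1; cur = nxt;
    }
    improve(p, d);
    double len = path_len(p, d);
    if (len < best_len) { best_len = len; best = p; }
  }
  return IntegerVector(best.begin(), best.end());
}
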