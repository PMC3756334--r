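// Maximum-parsimony engine: Fitch/Wagner scoring, stepwise addition with
// SPR/TBR branch swapping, exhaustive enumeration for small taxon counts,
// plateau collection of equally parsimonious trees, and rooted-clade
// summaries. Trees are manipulated as unrooted binary topologies over
// leaves 0..n-1 (internal nodes n..2n-3) and exported as ape-style edge
// matrices rooted on the outgroup's pendant edge.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <array>
#include <string>
#include <set>
#include <map>
#include <queue>
#include <algorithm>
#include <random>
#include <functional>
#include <climits>
#include <cstdio>

using namespace Rcpp;

static const uint16_t FULLMASK = 0x3FF; // states 0..9

struct CharData {
  int nleaf = 0;
  int nun = 0;  // unordered characters
  int nor_ = 0; // ordered characters
  // leaf-major rows, shared buffer with internal scratch rows in Engine
  std::vector<uint16_t> umask; // nleaf * nun
  std::vector<uint8_t> olo, ohi; // nleaf * nor_
};

static CharData build_chardata(const IntegerMatrix& cells,
                               const LogicalVector& ordered) {
  CharData D;
  D.nleaf = cells.nrow();
  int nchar = cells.ncol();
  std::vector<int> un, od;
  for (int c = 0; c < nchar; ++c) {
    if (ordered.size() > 0 && ordered[c]) od.push_back(c); else un.push_back(c);
  }
  D.nun = (int)un.size();
  D.nor_ = (int)od.size();
  D.umask.assign((size_t)D.nleaf * D.nun, FULLMASK);
  D.olo.assign((size_t)D.nleaf * D.nor_, 0);
  D.ohi.assign((size_t)D.nleaf * D.nor_, 9);
  for (int t = 0; t < D.nleaf; ++t) {
    for (int j = 0; j < D.nun; ++j) {
      int v = cells(t, un[j]);
      D.umask[(size_t)t * D.nun + j] =
        (v == NA_INTEGER || v == 0) ? FULLMASK : (uint16_t)v;
    }
    for (int j = 0; j < D.nor_; ++j) {
      int v = cells(t, od[j]);
      if (v == NA_INTEGER || v == 0) continue; // keep [0,9]
      int lo = 0; while (!((v >> lo) & 1)) ++lo;
      int hi = 9; while (!((v >> hi) & 1)) --hi;
      D.olo[(size_t)t * D.nor_ + j] = (uint8_t)lo;
      D.ohi[(size_t)t * D.nor_ + j] = (uint8_t)hi;
    }
  }
  return D;
}

static const int BIG = INT_MAX / 4;

struct Engine {
  CharData D;
  int nleaf = 0;
  int NN = 0; // node slots: 2*nleaf - 2
  std::vector<std::array<int, 3>> nb;
  // scratch state rows for every node slot (leaves prefilled once)
  std::vector<uint16_t> SU;
  std::vector<uint8_t> SLO, SHI;
  std::vector<int> post, parArr;
  std::mt19937 rng;
  long long evals = 0;

  void setup(const CharData& d, uint32_t seed) {
    D = d;
    nleaf = D.nleaf;
    NN = 2 * nleaf - 2;
    nb.assign(NN, {-1, -1, -1});
    SU.assign((size_t)NN * D.nun, 0);
    SLO.assign((size_t)NN * D.nor_, 0);
    SHI.assign((size_t)NN * D.nor_, 0);
    for (int t = 0; t < nleaf; ++t) {
      std::copy(D.umask.begin() + (size_t)t * D.nun,
                D.umask.begin() + (size_t)(t + 1) * D.nun,
                SU.begin() + (size_t)t * D.nun);
      std::copy(D.olo.begin() + (size_t)t * D.nor_,
                D.olo.begin() + (size_t)(t + 1) * D.nor_,
                SLO.begin() + (size_t)t * D.nor_);
      std::copy(D.ohi.begin() + (size_t)t * D.nor_,
                D.ohi.begin() + (size_t)(t + 1) * D.nor_,
                SHI.begin() + (size_t)t * D.nor_);
    }
    parArr.assign(NN, -1);
    post.reserve(NN);
    rng.seed(seed);
  }

  inline void link(int a, int b) {
    for (int k = 0; k < 3; ++k) if (nb[a][k] < 0) { nb[a][k] = b; break; }
    for (int k = 0; k < 3; ++k) if (nb[b][k] < 0) { nb[b][k] = a; break; }
  }
  inline void replace_nb(int node, int from, int to) {
    for (int k = 0; k < 3; ++k) if (nb[node][k] == from) { nb[node][k] = to; return; }
  }
  inline void clear_node(int v) { nb[v] = {-1, -1, -1}; }

  // postorder (children before parents) rooted at leaf `rootleaf`
  void build_post(int rootleaf) {
    post.clear();
    int start = nb[rootleaf][0];
    std::vector<int> stk; stk.push_back(start);
    parArr[start] = rootleaf;
    while (!stk.empty()) {
      int v = stk.back(); stk.pop_back();
      post.push_back(v);
      if (v >= nleaf) {
        for (int k = 0; k < 3; ++k) {
          int w = nb[v][k];
          if (w >= 0 && w != parArr[v]) { parArr[w] = v; stk.push_back(w); }
        }
      }
    }
    std::reverse(post.begin(), post.end());
  }

  // Fitch (unordered, bitmask) + Farris interval (ordered) length of the
  // current tree, virtually rooted on rootleaf's pendant edge.
  // Returns a value > bound as soon as the running total exceeds bound.
  int score(int rootleaf, int bound) {
    ++evals;
    build_post(rootleaf);
    int steps = 0;
    const int nun = D.nun, nor_ = D.nor_;
    for (int v : post) {
      if (v < nleaf) continue;
      int c1 = -1, c2 = -1;
      for (int k = 0; k < 3; ++k) {
        int w = nb[v][k];
        if (w >= 0 && w != parArr[v]) { if (c1 < 0) c1 = w; else c2 = w; }
      }
      const uint16_t* A = &SU[(size_t)c1 * nun];
      const uint16_t* B = &SU[(size_t)c2 * nun];
      uint16_t* V = &SU[(size_t)v * nun];
      for (int c = 0; c < nun; ++c) {
        uint16_t in = (uint16_t)(A[c] & B[c]);
        if (in) V[c] = in; else { V[c] = (uint16_t)(A[c] | B[c]); ++steps; }
      }
      if (nor_) {
        const uint8_t* L1 = &SLO[(size_t)c1 * nor_]; const uint8_t* H1 = &SHI[(size_t)c1 * nor_];
        const uint8_t* L2 = &SLO[(size_t)c2 * nor_]; const uint8_t* H2 = &SHI[(size_t)c2 * nor_];
        uint8_t* LV = &SLO[(size_t)v * nor_]; uint8_t* HV = &SHI[(size_t)v * nor_];
        for (int c = 0; c < nor_; ++c) {
          int l = std::max(L1[c], L2[c]), h = std::min(H1[c], H2[c]);
          if (l <= h) { LV[c] = (uint8_t)l; HV[c] = (uint8_t)h; }
          else { steps += l - h; LV[c] = (uint8_t)h; HV[c] = (uint8_t)l; }
        }
      }
      if (steps > bound) return steps;
    }
    int start = nb[rootleaf][0];
    if (start >= nleaf) {
      const uint16_t* R = &SU[(size_t)start * nun];
      const uint16_t* L = &SU[(size_t)rootleaf * nun];
      for (int c = 0; c < nun; ++c) if (!(R[c] & L[c])) ++steps;
      if (nor_) {
        const uint8_t* RL = &SLO[(size_t)start * nor_]; const uint8_t* RH = &SHI[(size_t)start * nor_];
        const uint8_t* LL = &SLO[(size_t)rootleaf * nor_]; const uint8_t* LH = &SHI[(size_t)rootleaf * nor_];
        for (int c = 0; c < nor_; ++c) {
          int l = std::max(RL[c], LL[c]), h = std::min(RH[c], LH[c]);
          if (l > h) steps += l - h;
        }
      }
    }
    return steps;
  }

  // edges of the component reachable from rootleaf, as (parent, child)
  void edges_from(int rootleaf, std::vector<std::pair<int,int>>& out) {
    build_post(rootleaf);
    out.clear();
    for (int v : post) out.push_back({parArr[v], v});
  }

  std::string canon_node(int v, int par) const {
    if (v < nleaf) return std::to_string(v);
    std::string s1, s2; bool first = true;
    for (int k = 0; k < 3; ++k) {
      int w = nb[v][k];
      if (w < 0 || w == par) continue;
      std::string s = canon_node(w, v);
      if (first) { s1 = s; first = false; } else s2 = s;
    }
    if (s2 < s1) std::swap(s1, s2);
    return "(" + s1 + "," + s2 + ")";
  }
  std::string canon() const { return canon_node(nb[0][0], 0); }

  std::vector<int> dump_nb() const {
    std::vector<int> out((size_t)NN * 3);
    for (int i = 0; i < NN; ++i) for (int k = 0; k < 3; ++k) out[(size_t)i*3+k] = nb[i][k];
    return out;
  }
  void load_nb(const std::vector<int>& flat) {
    for (int i = 0; i < NN; ++i) for (int k = 0; k < 3; ++k) nb[i][k] = flat[(size_t)i*3+k];
  }

  void stepwise(const std::vector<int>& order) {
    nb.assign(NN, {-1, -1, -1});
    int in0 = nleaf;
    link(in0, order[0]); link(in0, order[1]); link(in0, order[2]);
    int next_int = nleaf + 1;
    std::vector<std::pair<int,int>> E;
    for (size_t k = 3; k < order.size(); ++k) {
      int t = order[k];
      edges_from(order[0], E);
      int best = BIG;
      std::vector<std::pair<int,int>> ties;
      int w = next_int;
      for (auto& e : E) {
        int u = e.first, v = e.second;
        replace_nb(u, v, w); replace_nb(v, u, w);
        nb[w] = {u, v, t}; nb[t][0] = w;
        int s = score(order[0], best);
        if (s < best) { best = s; ties.clear(); ties.push_back(e); }
        else if (s == best) ties.push_back(e);
        replace_nb(u, w, v); replace_nb(v, w, u);
        clear_node(w); nb[t][0] = -1;
      }
      std::uniform_int_distribution<size_t> pick(0, ties.size() - 1);
      auto e = ties[pick(rng)];
      int u = e.first, v = e.second;
      replace_nb(u, v, w); replace_nb(v, u, w);
      nb[w] = {u, v, t}; nb[t][0] = w;
      ++next_int;
    }
  }
};

// tree pool with canonical-form dedup
struct Pool {
  std::set<std::string> seen;
  std::vector<std::vector<int>> trees;
  std::vector<char> swapped;
  bool add(Engine& E) {
    std::string key = E.canon();
    if (seen.count(key)) return false;
    seen.insert(key);
    trees.push_back(E.dump_nb());
    swapped.push_back(0);
    return true;
  }
  void clear() { seen.clear(); trees.clear(); swapped.clear(); }
  size_t size() const { return trees.size(); }
};

struct SearchCtl {
  int best = BIG;
  Pool pool;
  size_t max_trees = 10000;
  long long eval_budget = LLONG_MAX;
  bool hit_tree_cap = false, hit_eval_cap = false;
  long long collected_this_rep = 0;
  long long hold = LLONG_MAX;
};

// One scan of the SPR neighbourhood of the current tree in E.
// mode 0: first-improvement (returns true and leaves the tree modified).
// mode 1: collect equal-best neighbours into ctl.pool (tree restored); an
//         improving neighbour is adopted and true is returned.
static bool spr_scan(Engine& E, int& cur, SearchCtl& ctl, int mode) {
  int nleaf = E.nleaf;
  std::vector<std::pair<int,int>> E2;
  for (int p = nleaf; p < E.NN; ++p) {
    if (E.nb[p][0] < 0) continue;
    for (int ks = 0; ks < 3; ++ks) {
      int s = E.nb[p][ks];
      int a = E.nb[p][(ks + 1) % 3], b = E.nb[p][(ks + 2) % 3];
      // detach subtree (p,s); smooth p out of the remaining tree
      E.replace_nb(a, p, b); E.replace_nb(b, p, a);
      // a leaf inside the remaining component
      int rl = a;
      if (rl >= nleaf) {
        // DFS for a leaf
        std::vector<int> stk{a}; int prev = b;
        (void)prev;
        std::vector<int> par(E.NN, -2);
        par[a] = -1;
        while (!stk.empty()) {
          int v = stk.back(); stk.pop_back();
          if (v < nleaf) { rl = v; break; }
          for (int k = 0; k < 3; ++k) {
            int w = E.nb[v][k];
            if (w >= 0 && par[w] == -2) { par[w] = v; stk.push_back(w); }
          }
        }
      }
      E.edges_from(rl, E2);
      bool improved = false;
      for (auto& e : E2) {
        int u = e.first, v = e.second;
        if ((u == a && v == b) || (u == b && v == a)) continue; // original
        E.replace_nb(u, v, p); E.replace_nb(v, u, p);
        E.nb[p] = {u, v, s};
        int bound = (mode == 0) ? (cur - 1) : ctl.best;
        int sc = E.score(rl, bound);
        if (sc < cur && mode == 0) { cur = sc; return true; }
        if (mode == 1) {
          if (sc < ctl.best) { cur = sc; return true; }
          if (sc == ctl.best && ctl.pool.size() < ctl.max_trees &&
              ctl.collected_this_rep < ctl.hold) {
            if (ctl.pool.add(E)) ++ctl.collected_this_rep;
          }
        }
        E.replace_nb(u, p, v); E.replace_nb(v, p, u);
        if (E.evals > ctl.eval_budget) { improved = false; break; }
      }
      // restore original attachment
      E.replace_nb(a, b, p); E.replace_nb(b, a, p);
      E.nb[p] = {a, b, s};
      (void)improved;
      if (E.evals > ctl.eval_budget) { ctl.hit_eval_cap = true; return false; }
    }
  }
  return false;
}

// TBR moves on internal edges with the pruned part rerooted; combinations
// equal to SPR moves (either side reattached at its original edge) are
// skipped because spr_scan covers them.
static bool tbr_scan(Engine& E, int& cur, SearchCtl& ctl, int mode) {
  int nleaf = E.nleaf;
  std::vector<std::pair<int,int>> E1, E2;
  for (int p = nleaf; p < E.NN; ++p) {
    if (E.nb[p][0] < 0) continue;
    for (int kq = 0; kq < 3; ++kq) {
      int q = E.nb[p][kq];
      if (q < nleaf || q < p) continue; // internal edges once
      int a1 = E.nb[p][(kq + 1) % 3], a2 = E.nb[p][(kq + 2) % 3];
      int b1 = -1, b2 = -1;
      for (int k = 0; k < 3; ++k) {
        int w = E.nb[q][k];
        if (w != p) { if (b1 < 0) b1 = w; else b2 = w; }
      }
      // smooth out p and q
      E.replace_nb(a1, p, a2); E.replace_nb(a2, p, a1);
      E.replace_nb(b1, q, b2); E.replace_nb(b2, q, b1);
      // leaves for each component
      auto find_leaf = [&](int from) {
        if (from < nleaf) return from;
        std::vector<int> stk{from};
        std::vector<char> vis(E.NN, 0); vis[from] = 1;
        while (!stk.empty()) {
          int v = stk.back(); stk.pop_back();
          if (v < nleaf) return v;
          for (int k = 0; k < 3; ++k) {
            int w = E.nb[v][k];
            if (w >= 0 && !vis[w]) { vis[w] = 1; stk.push_back(w); }
          }
        }
        return -1;
      };
      int rl1 = find_leaf(a1), rl2 = find_leaf(b1);
      E.edges_from(rl1, E1);
      E.edges_from(rl2, E2);
      bool done = false;
      for (auto& e1 : E1) {
        int u1 = e1.first, v1 = e1.second;
        bool e1orig = (u1 == a1 && v1 == a2) || (u1 == a2 && v1 == a1);
        if (e1orig) continue; // covered by SPR
        E.replace_nb(u1, v1, p); E.replace_nb(v1, u1, p);
        E.nb[p] = {u1, v1, q};
        for (auto& e2 : E2) {
          int u2 = e2.first, v2 = e2.second;
          bool e2orig = (u2 == b1 && v2 == b2) || (u2 == b2 && v2 == b1);
          if (e2orig) continue;
          E.replace_nb(u2, v2, q); E.replace_nb(v2, u2, q);
          E.nb[q] = {u2, v2, p};
          int bound = (mode == 0) ? (cur - 1) : ctl.best;
          int sc = E.score(rl1, bound);
          if (sc < cur && mode == 0) { cur = sc; return true; }
          if (mode == 1) {
            if (sc < ctl.best) { cur = sc; return true; }
            if (sc == ctl.best && ctl.pool.size() < ctl.max_trees &&
                ctl.collected_this_rep < ctl.hold) {
              if (ctl.pool.add(E)) ++ctl.collected_this_rep;
            }
          }
          E.replace_nb(u2, q, v2); E.replace_nb(v2, q, u2);
          if (E.evals > ctl.eval_budget) { done = true; break; }
        }
        E.replace_nb(u1, p, v1); E.replace_nb(v1, p, u1);
        if (done) break;
      }
      // restore
      E.replace_nb(a1, a2, p); E.replace_nb(a2, a1, p);
      E.replace_nb(b1, b2, q); E.replace_nb(b2, b1, q);
      E.nb[p] = {a1, a2, q}; E.nb[q] = {b1, b2, p};
      if (E.evals > ctl.eval_budget) { ctl.hit_eval_cap = true; return false; }
    }
  }
  return false;
}

static void hill_climb(Engine& E, int& cur, SearchCtl& ctl, bool tbr) {
  for (;;) {
    if (spr_scan(E, cur, ctl, 0)) continue;
    if (ctl.hit_eval_cap) return;
    if (tbr && tbr_scan(E, cur, ctl, 0)) continue;
    break;
  }
}

// ape edge matrix rooted on the outgroup's pendant edge (preorder rows)
static IntegerMatrix to_ape(const Engine& E, int og) {
  int n = E.nleaf;
  IntegerMatrix edge(2 * n - 2, 2);
  int row = 0, next_internal = n + 2;
  int root = n + 1;
  edge(row, 0) = root; edge(row, 1) = og + 1; ++row;
  // iterative preorder from the internal node adjacent to og
  struct Fr { int v, par, apar; };
  std::vector<Fr> stk;
  int start = E.nb[og][0];
  stk.push_back({start, og, root});
  while (!stk.empty()) {
    Fr f = stk.back(); stk.pop_back();
    int id;
    if (f.v < n) id = f.v + 1; else id = next_internal++;
    edge(row, 0) = f.apar; edge(row, 1) = id; ++row;
    if (f.v >= n) {
      for (int k = 2; k >= 0; --k) {
        int w = E.nb[f.v][k];
        if (w >= 0 && w != f.par) stk.push_back({w, f.v, id});
      }
    }
  }
  return edge;
}

// depth-based root distances: for each leaf, number of internal nodes
// strictly between the leaf and the root (root = node where the outgroup
// attaches); accumulated into sums
static void add_root_distances(const Engine& E, int og, std::vector<double>& sums) {
  int n = E.nleaf;
  std::vector<int> stk, dep(E.NN, 0);
  int start = E.nb[og][0];
  std::vector<int> par(E.NN, -1);
  par[start] = og; dep[start] = 1;
  stk.push_back(start);
  sums[og] += 0.0;
  while (!stk.empty()) {
    int v = stk.back(); stk.pop_back();
    if (v < n) { sums[v] += dep[v] - 1; continue; }
    for (int k = 0; k < 3; ++k) {
      int w = E.nb[v][k];
      if (w >= 0 && w != par[v]) { par[w] = v; dep[w] = dep[v] + 1; stk.push_back(w); }
    }
  }
}

// rooted clades (as 64-bit leaf masks) of the current tree in E
static void tree_clade_masks(const Engine& E, int og, std::set<uint64_t>& out) {
  // postorder accumulation of leaf masks below each internal node,
  // rooted above og
  int n = E.nleaf;
  std::vector<int> order, par(E.NN, -1), stk;
  int start = E.nb[og][0];
  par[start] = og; stk.push_back(start);
  while (!stk.empty()) {
    int v = stk.back(); stk.pop_back();
    order.push_back(v);
    if (v >= n) for (int k = 0; k < 3; ++k) {
      int w = E.nb[v][k];
      if (w >= 0 && w != par[v]) { par[w] = v; stk.push_back(w); }
    }
  }
  std::vector<uint64_t> m(E.NN, 0);
  for (auto it = order.rbegin(); it != order.rend(); ++it) {
    int v = *it;
    if (v < n) { m[v] = (uint64_t)1 << v; continue; }
    uint64_t acc = 0;
    for (int k = 0; k < 3; ++k) {
      int w = E.nb[v][k];
      if (w >= 0 && w != par[v]) acc |= m[w];
    }
    m[v] = acc;
    out.insert(acc); // includes the full-ingroup clade; R filters trivia
  }
}

static std::string mask_to_hex(uint64_t m) {
  char buf[20];
  snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)m);
  return std::string(buf);
}

static List summarize_pool(Engine& E, SearchCtl& ctl, int og, bool return_trees) {
  size_t nt = ctl.pool.size();
  std::vector<double> sums(E.nleaf, 0.0);
  std::set<uint64_t> common;
  bool first = true;
  List trees(return_trees ? (int)nt : 0);
  for (size_t i = 0; i < nt; ++i) {
    E.load_nb(ctl.pool.trees[i]);
    add_root_distances(E, og, sums);
    std::set<uint64_t> cl;
    tree_clade_masks(E, og, cl);
    if (first) { common = cl; first = false; }
    else {
      std::set<uint64_t> inter;
      std::set_intersection(common.begin(), common.end(), cl.begin(), cl.end(),
                            std::inserter(inter, inter.begin()));
      common.swap(inter);
    }
    if (return_trees) trees[(int)i] = to_ape(E, og);
  }
  NumericVector mrd(E.nleaf);
  for (int i = 0; i < E.nleaf; ++i) mrd[i] = sums[i] / (double)nt;
  CharacterVector cl(common.size());
  int j = 0;
  for (uint64_t m : common) cl[j++] = mask_to_hex(m);
  List out = List::create(
    _["score"] = ctl.best,
    _["n_trees"] = (int)nt,
    _["mean_root_distance"] = mrd,
    _["common_clades"] = cl,
    _["evals"] = (double)E.evals,
    _["hit_tree_cap"] = ctl.hit_tree_cap,
    _["hit_eval_cap"] = ctl.hit_eval_cap);
  if (return_trees) out["trees"] = trees;
  return out;
}

// [[Rcpp::export]]
List heuristic_search_cpp(IntegerMatrix cells, LogicalVector ordered, int outgroup,
                          int n_addition, std::string swap, int hold,
                          int max_trees, double plateau_budget, int seed,
                          bool return_trees) {
  CharData D = build_chardata(cells, ordered);
  if (D.nleaf < 4) stop("heuristic search requires at least 4 taxa");
  Engine E;
  E.setup(D, (uint32_t)seed);
  bool tbr = (swap == "tbr");
  SearchCtl ctl;
  ctl.max_trees = (size_t)max_trees;
  ctl.hold = hold;

  std::vector<int> order(E.nleaf);
  for (int i = 0; i < E.nleaf; ++i) order[i] = i;

  for (int rep = 0; rep < n_addition; ++rep) {
    std::shuffle(order.begin(), order.end(), E.rng);
    E.stepwise(order);
    int cur = E.score(0, BIG);
    hill_climb(E, cur, ctl, tbr);
    if (cur < ctl.best) { ctl.best = cur; ctl.pool.clear(); }
    if (cur == ctl.best && ctl.pool.size() < ctl.max_trees) ctl.pool.add(E);
    // collect equal-score neighbours of this optimum
    if (cur == ctl.best) {
      ctl.collected_this_rep = 0;
      for (;;) {
        bool better = spr_scan(E, cur, ctl, 1);
        if (!better && tbr) better = tbr_scan(E, cur, ctl, 1);
        if (!better) break;
        hill_climb(E, cur, ctl, tbr);
        if (cur < ctl.best) { ctl.best = cur; ctl.pool.clear(); }
        if (ctl.pool.size() < ctl.max_trees) ctl.pool.add(E);
        ctl.collected_this_rep = 0;
      }
    }
  }

  // plateau closure: swap every held tree, collecting its equal-score
  // neighbours, until no unswapped trees remain or a cap is hit
  ctl.eval_budget = (plateau_budget <= 0) ? LLONG_MAX : (long long)plateau_budget;
  ctl.hold = LLONG_MAX;
  bool progress = true;
  while (progress && !ctl.hit_eval_cap) {
    progress = false;
    for (size_t i = 0; i < ctl.pool.size(); ++i) {
      if (ctl.pool.swapped[i]) continue;
      if (ctl.pool.size() >= ctl.max_trees) { ctl.hit_tree_cap = true; break; }
      ctl.pool.swapped[i] = 1;
      progress = true;
      E.load_nb(ctl.pool.trees[i]);
      int cur = ctl.best;
      ctl.collected_this_rep = 0;
      bool better = spr_scan(E, cur, ctl, 1);
      if (!better && tbr) better = tbr_scan(E, cur, ctl, 1);
      if (better) {
        hill_climb(E, cur, ctl, tbr);
        ctl.best = cur;
        ctl.pool.clear();
        ctl.pool.add(E);
        break;
      }
      if (ctl.hit_eval_cap) break;
    }
    if (ctl.pool.size() >= ctl.max_trees) ctl.hit_tree_cap = true;
  }

  return summarize_pool(E, ctl, outgroup, return_trees);
}

// [[Rcpp::export]]
List exhaustive_search_cpp(IntegerMatrix cells, LogicalVector ordered,
                           int outgroup, bool return_trees) {
  CharData D = build_chardata(cells, ordered);
  int n = D.nleaf;
  if (n < 4) stop("exhaustive search requires at least 4 taxa");
  if (n > 9) stop("exhaustive search is limited to 9 taxa");
  Engine E;
  E.setup(D, 1u);
  SearchCtl ctl;
  ctl.max_trees = SIZE_MAX;
  long long n_topologies = 0;

  // start with taxa 0,1,2 on one internal node
  E.nb.assign(E.NN, {-1, -1, -1});
  E.link(n, 0); E.link(n, 1); E.link(n, 2);

  std::vector<std::pair<int,int>> Ebuf;
  std::function<void(int)> rec = [&](int k) {
    if (k == n) {
      ++n_topologies;
      int s = E.score(0, ctl.best);
      if (s < ctl.best) { ctl.best = s; ctl.pool.clear(); }
      if (s == ctl.best) ctl.pool.add(E);
      return;
    }
    std::vector<std::pair<int,int>> Elocal;
    E.edges_from(0, Elocal);
    int w = n + (k - 2);
    for (auto& e : Elocal) {
      int u = e.first, v = e.second;
      E.replace_nb(u, v, w); E.replace_nb(v, u, w);
      E.nb[w] = {u, v, k}; E.nb[k][0] = w;
      rec(k + 1);
      E.replace_nb(u, w, v); E.replace_nb(v, w, u);
      E.clear_node(w); E.nb[k][0] = -1;
    }
  };
  rec(3);

  List out = summarize_pool(E, ctl, outgroup, return_trees);
  out["n_topologies"] = (double)n_topologies;
  return out;
}

// Parsimony length of a rooted/unrooted ape tree (children combined
// pairwise; exact for binary trees). Tip i (1-based) uses row i-1 of cells.
// [[Rcpp::export]]
int tree_length_cpp(IntegerMatrix edge, int ntip, IntegerMatrix cells,
                    LogicalVector ordered) {
  CharData D = build_chardata(cells, ordered);
  int nnode = 0;
  for (int i = 0; i < edge.nrow(); ++i) nnode = std::max(nnode, std::max(edge(i,0), edge(i,1)));
  std::vector<std::vector<int>> kids(nnode + 1);
  std::vector<char> ischild(nnode + 1, 0);
  for (int i = 0; i < edge.nrow(); ++i) {
    kids[edge(i, 0)].push_back(edge(i, 1));
    ischild[edge(i, 1)] = 1;
  }
  int root = -1;
  for (int v = ntip + 1; v <= nnode; ++v) if (!ischild[v]) { root = v; break; }
  if (root < 0) stop("could not locate root");
  // postorder
  std::vector<int> order, stk{root};
  while (!stk.empty()) {
    int v = stk.back(); stk.pop_back();
    order.push_back(v);
    for (int w : kids[v]) stk.push_back(w);
  }
  std::reverse(order.begin(), order.end());
  int nun = D.nun, nor_ = D.nor_;
  std::vector<uint16_t> SU((size_t)(nnode + 1) * nun);
  std::vector<uint8_t> SLO((size_t)(nnode + 1) * nor_), SHI((size_t)(nnode + 1) * nor_);
  int steps = 0;
  for (int v : order) {
    if (v <= ntip) {
      std::copy(D.umask.begin() + (size_t)(v - 1) * nun,
                D.umask.begin() + (size_t)v * nun, SU.begin() + (size_t)v * nun);
      std::copy(D.olo.begin() + (size_t)(v - 1) * nor_,
                D.olo.begin() + (size_t)v * nor_, SLO.begin() + (size_t)v * nor_);
      std::copy(D.ohi.begin() + (size_t)(v - 1) * nor_,
                D.ohi.begin() + (size_t)v * nor_, SHI.begin() + (size_t)v * nor_);
      continue;
    }
    bool first = true;
    uint16_t* V = &SU[(size_t)v * nun];
    uint8_t* LV = &SLO[(size_t)v * nor_]; uint8_t* HV = &SHI[(size_t)v * nor_];
    for (int w : kids[v]) {
      const uint16_t* A = &SU[(size_t)w * nun];
      const uint8_t* LA = &SLO[(size_t)w * nor_]; const uint8_t* HA = &SHI[(size_t)w * nor_];
      if (first) {
        std::copy(A, A + nun, V);
        std::copy(LA, LA + nor_, LV); std::copy(HA, HA + nor_, HV);
        first = false;
        continue;
      }
      for (int c = 0; c < nun; ++c) {
        uint16_t in = (uint16_t)(V[c] & A[c]);
        if (in) V[c] = in; else { V[c] = (uint16_t)(V[c] | A[c]); ++steps; }
      }
      for (int c = 0; c < nor_; ++c) {
        int l = std::max(LV[c], LA[c]), h = std::min(HV[c], HA[c]);
        if (l <= h) { LV[c] = (uint8_t)l; HV[c] = (uint8_t)h; }
        else { steps += l - h; LV[c] = (uint8_t)h; HV[c] = (uint8_t)l; }
      }
    }
  }
  return steps;
}

// ACCTRAN edge lengths of a rooted ape tree: Fitch/Wagner downpass, then a
// top-down single-assignment uppass that keeps the parent state whenever the
// child's preliminary set allows it (changes placed as rootward as possible).
// The root state is resolved toward the outgroup (tip 1's) state set.
// [[Rcpp::export]]
NumericVector acctran_lengths_cpp(IntegerMatrix edge, int ntip,
                                  IntegerMatrix cells, LogicalVector ordered,
                                  int outgroup_tip) {
  CharData D = build_chardata(cells, ordered);
  int nnode = 0;
  for (int i = 0; i < edge.nrow(); ++i) nnode = std::max(nnode, std::max(edge(i,0), edge(i,1)));
  std::vector<std::vector<int>> kids(nnode + 1);
  std::vector<std::vector<int>> kid_edge(nnode + 1);
  std::vector<char> ischild(nnode + 1, 0);
  for (int i = 0; i < edge.nrow(); ++i) {
    kids[edge(i, 0)].push_back(edge(i, 1));
    kid_edge[edge(i, 0)].push_back(i);
    ischild[edge(i, 1)] = 1;
  }
  int root = -1;
  for (int v = ntip + 1; v <= nnode; ++v) if (!ischild[v]) { root = v; break; }
  if (root < 0) stop("could not locate root");
  std::vector<int> order, stk{root};
  while (!stk.empty()) {
    int v = stk.back(); stk.pop_back();
    order.push_back(v);
    for (int w : kids[v]) stk.push_back(w);
  }
  std::reverse(order.begin(), order.end());
  int nun = D.nun, nor_ = D.nor_;
  std::vector<uint16_t> P((size_t)(nnode + 1) * nun);
  std::vector<uint8_t> PLO((size_t)(nnode + 1) * nor_), PHI((size_t)(nnode + 1) * nor_);
  // downpass
  for (int v : order) {
    if (v <= ntip) {
      std::copy(D.umask.begin() + (size_t)(v - 1) * nun,
                D.umask.begin() + (size_t)v * nun, P.begin() + (size_t)v * nun);
      std::copy(D.olo.begin() + (size_t)(v - 1) * nor_,
                D.olo.begin() + (size_t)v * nor_, PLO.begin() + (size_t)v * nor_);
      std::copy(D.ohi.begin() + (size_t)(v - 1) * nor_,
                D.ohi.begin() + (size_t)v * nor_, PHI.begin() + (size_t)v * nor_);
      continue;
    }
    bool first = true;
    uint16_t* V = &P[(size_t)v * nun];
    uint8_t* LV = &PLO[(size_t)v * nor_]; uint8_t* HV = &PHI[(size_t)v * nor_];
    for (int w : kids[v]) {
      const uint16_t* A = &P[(size_t)w * nun];
      const uint8_t* LA = &PLO[(size_t)w * nor_]; const uint8_t* HA = &PHI[(size_t)w * nor_];
      if (first) {
        std::copy(A, A + nun, V);
        std::copy(LA, LA + nor_, LV); std::copy(HA, HA + nor_, HV);
        first = false; continue;
      }
      for (int c = 0; c < nun; ++c) {
        uint16_t in = (uint16_t)(V[c] & A[c]);
        V[c] = in ? in : (uint16_t)(V[c] | A[c]);
      }
      for (int c = 0; c < nor_; ++c) {
        int l = std::max(LV[c], LA[c]), h = std::min(HV[c], HA[c]);
        if (l <= h) { LV[c] = (uint8_t)l; HV[c] = (uint8_t)h; }
        else { LV[c] = (uint8_t)h; HV[c] = (uint8_t)l; }
      }
    }
  }
  // uppass with single-state assignments
  std::vector<uint16_t> S((size_t)(nnode + 1) * nun);
  std::vector<uint8_t> SO((size_t)(nnode + 1) * nor_);
  NumericVector len(edge.nrow());
  // root: prefer states shared with the outgroup tip
  for (int c = 0; c < nun; ++c) {
    uint16_t pr = P[(size_t)root * nun + c];
    uint16_t og = D.umask[(size_t)(outgroup_tip - 1) * nun + c];
    uint16_t pick = (uint16_t)(pr & og);
    if (!pick) pick = pr;
    S[(size_t)root * nun + c] = (uint16_t)(pick & (~pick + 1)); // lowest bit
  }
  for (int c = 0; c < nor_; ++c) {
    uint8_t lo = PLO[(size_t)root * nor_ + c];
    uint8_t hi = PHI[(size_t)root * nor_ + c];
    uint8_t og = D.olo[(size_t)(outgroup_tip - 1) * nor_ + c];
    SO[(size_t)root * nor_ + c] = og < lo ? lo : (og > hi ? hi : og);
  }
  // preorder
  for (auto it = order.rbegin(); it != order.rend(); ++it) {
    int u = *it;
    if (u <= ntip) continue;
    for (size_t k = 0; k < kids[u].size(); ++k) {
      int v = kids[u][k];
      int e = kid_edge[u][k];
      double steps = 0;
      for (int c = 0; c < nun; ++c) {
        uint16_t su = S[(size_t)u * nun + c];
        uint16_t pv = P[(size_t)v * nun + c];
        if (su & pv) S[(size_t)v * nun + c] = su;
        else { S[(size_t)v * nun + c] = (uint16_t)(pv & (~pv + 1)); steps += 1; }
      }
      for (int c = 0; c < nor_; ++c) {
        uint8_t su = SO[(size_t)u * nor_ + c];
        uint8_t lo = PLO[(size_t)v * nor_ + c], hi = PHI[(size_t)v * nor_ + c];
        uint8_t sv = su < lo ? lo : (su > hi ? hi : su);
        steps += std::abs((int)sv - (int)su);
        SO[(size_t)v * nor_ + c] = sv;
      }
      len[e] = steps;
    }
  }
  return len;
}

// Rooted clades of an ape tree, as hex leaf masks (one per internal node,
// including the root's full set; duplicates collapsed)
// [[Rcpp::export]]
CharacterVector tree_clades_cpp(IntegerMatrix edge, int ntip) {
  if (ntip > 64) stop("clade masks support at most 64 tips");
  int nnode = 0;
  for (int i = 0; i < edge.nrow(); ++i) nnode = std::max(nnode, std::max(edge(i,0), edge(i,1)));
  std::vector<std::vector<int>> kids(nnode + 1);
  std::vector<char> ischild(nnode + 1, 0);
  for (int i = 0; i < edge.nrow(); ++i) {
    kids[edge(i, 0)].push_back(edge(i, 1));
    ischild[edge(i, 1)] = 1;
  }
  int root = -1;
  for (int v = ntip + 1; v <= nnode; ++v) if (!ischild[v]) { root = v; break; }
  std::vector<int> order, stk{root};
  while (!stk.empty()) {
    int v = stk.back(); stk.pop_back();
    order.push_back(v);
    for (int w : kids[v]) stk.push_back(w);
  }
  std::reverse(order.begin(), order.end());
  std::vector<uint64_t> m(nnode + 1, 0);
  std::set<uint64_t> out;
  for (int v : order) {
    if (v <= ntip) { m[v] = (uint64_t)1 << (v - 1); continue; }
    uint64_t acc = 0;
    for (int w : kids[v]) acc |= m[w];
    m[v] = acc;
    out.insert(acc);
  }
  CharacterVector res(out.size());
  int j = 0;
  for (uint64_t x : out) res[j++] = mask_to_hex(x);
  return res;
}
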