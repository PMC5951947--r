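// Core graph routines for LDOI computation and GRASP target control.
//
// Virtual nodes are 0-based here with node i ON = 2i, OFF = 2i+1, so the
// negation of v is v ^ 1. The R side uses 1-based indices (ON odd).

#include <Rcpp.h>
#include <algorithm>
#include <map>
#include <vector>
using namespace Rcpp;

struct ExpNet {
  int nv;                                  // number of virtual nodes (2N)
  std::vector<std::vector<int>> vv;        // virtual -> virtual
  std::vector<std::vector<int>> vc;        // virtual -> composite
  std::vector<std::vector<int>> comp_in;   // composite inputs
  std::vector<std::vector<int>> comp_out;  // composite -> virtual
};

static std::vector<std::vector<int>> to_adj(List l) {
  std::vector<std::vector<int>> out(l.size());
  for (R_xlen_t i = 0; i < l.size(); ++i) {
    IntegerVector v = l[i];
    out[i].assign(v.begin(), v.end());
    for (int& x : out[i]) x -= 1;
  }
  return out;
}

// [[Rcpp::export]]
SEXP cpp_net_build(int nv, List vv, List vc, List comp_in, List comp_out) {
  ExpNet* net = new ExpNet();
  net->nv = nv;
  net->vv = to_adj(vv);
  net->vc = to_adj(vc);
  net->comp_in = to_adj(comp_in);
  net->comp_out = to_adj(comp_out);
  return XPtr<ExpNet>(net, true);
}

// [[Rcpp::export]]
bool cpp_net_ok(SEXP ptr) {
  return R_ExternalPtrAddr(ptr) != NULL;
}

struct LdoiOut {
  std::vector<char> member;    // per virtual node
  std::vector<char> expanded;  // members plus the intervention itself
  std::vector<int> pend;       // remaining unsatisfied inputs per composite
  bool conflict;
};

// Modified BFS of the paper's LDOI search. A composite is traversed only once
// all its inputs are expanded; the negation of an intervention node is never
// added nor expanded (truncation rule, setting the conflict flag); an
// intervention node joins the members only when it is re-visited through an
// edge that does not come from itself (its own self-edge, or a composite
// containing it, does not count -- the re-derivation must be independent).
static void run_ldoi(const ExpNet& n, const std::vector<int>& s, LdoiOut& o) {
  int nv = n.nv, nc = (int)n.comp_in.size();
  o.member.assign(nv, 0);
  o.expanded.assign(nv, 0);
  o.pend.resize(nc);
  for (int c = 0; c < nc; ++c) o.pend[c] = (int)n.comp_in[c].size();
  std::vector<char> in_s(nv, 0), neg_s(nv, 0);
  for (int v : s) {
    in_s[v] = 1;
    neg_s[v ^ 1] = 1;
  }
  o.conflict = false;
  std::vector<int> queue;
  queue.reserve(nv);
  size_t head = 0;
  for (int v : s)
    if (!o.expanded[v]) {
      o.expanded[v] = 1;
      queue.push_back(v);
    }

  // from_v >= 0: arrival over a virtual->virtual edge; comp >= 0: arrival
  // from an activated composite.
  auto visit = [&](int w, int from_v, int comp) {
    if (neg_s[w]) {
      o.conflict = true;
      return;
    }
    bool independent = true;
    if (in_s[w]) {
      if (from_v >= 0) {
        independent = (from_v != w);
      } else {
        for (int x : n.comp_in[comp])
          if (x == w) {
            independent = false;
            break;
          }
      }
    }
    if (independent) o.member[w] = 1;
    if (!o.expanded[w]) {
      o.expanded[w] = 1;
      queue.push_back(w);
    }
  };

  while (head < queue.size()) {
    int u = queue[head++];
    for (int w : n.vv[u]) visit(w, u, -1);
    for (int c : n.vc[u]) {
      if (--o.pend[c] == 0) {
        for (int w : n.comp_out[c]) visit(w, -1, c);
      }
    }
  }
}

static std::vector<int> as_idx0(IntegerVector v) {
  std::vector<int> out(v.begin(), v.end());
  for (int& x : out) x -= 1;
  return out;
}

static IntegerVector as_idx1(const std::vector<int>& v) {
  IntegerVector out(v.size());
  for (size_t i = 0; i < v.size(); ++i) out[i] = v[i] + 1;
  return out;
}

static List ldoi_as_list(const ExpNet& net, const std::vector<int>& s,
                         const LdoiOut& o) {
  std::vector<int> mem;
  for (int w = 0; w < net.nv; ++w)
    if (o.member[w]) mem.push_back(w);
  bool self_contained = !s.empty();
  for (int v : s)
    if (!o.member[v]) self_contained = false;
  std::vector<int> act;
  for (size_t c = 0; c < o.pend.size(); ++c)
    if (o.pend[c] == 0) act.push_back((int)c);
  return List::create(_["members"] = as_idx1(mem), _["conflict"] = o.conflict,
                      _["self_contained"] = self_contained,
                      _["activated"] = as_idx1(act));
}

// [[Rcpp::export]]
List cpp_ldoi(SEXP ptr, IntegerVector s) {
  XPtr<ExpNet> p(ptr);
  std::vector<int> sv = as_idx0(s);
  LdoiOut o;
  run_ldoi(*p, sv, o);
  return ldoi_as_list(*p, sv, o);
}

struct Cache {
  std::vector<std::vector<int>> members;
  std::vector<char> conflict;
  std::vector<int> s1, s2;
};

static void build_cache(const ExpNet& n, Cache& c) {
  int nv = n.nv;
  c.members.resize(nv);
  c.conflict.resize(nv);
  c.s1.resize(nv);
  c.s2.resize(nv);
  LdoiOut o;
  for (int v = 0; v < nv; ++v) {
    std::vector<int> s{v};
    run_ldoi(n, s, o);
    auto& mem = c.members[v];
    mem.clear();
    for (int w = 0; w < nv; ++w)
      if (o.member[w]) mem.push_back(w);
    c.conflict[v] = o.conflict ? 1 : 0;
    c.s1[v] = (int)mem.size();
    int s2 = 0;
    for (size_t k = 0; k < o.pend.size(); ++k) {
      int sz = (int)n.comp_in[k].size();
      int fed = sz - o.pend[k];
      if (fed > 0 && fed < sz) ++s2;  // partially fed, not activated
    }
    c.s2[v] = s2;
  }
}

// [[Rcpp::export]]
List cpp_cache(SEXP ptr) {
  XPtr<ExpNet> p(ptr);
  Cache c;
  build_cache(*p, c);
  int nv = p->nv;
  List members(nv);
  LogicalVector conflict(nv), selfc(nv);
  IntegerVector s1(nv), s2(nv);
  for (int v = 0; v < nv; ++v) {
    members[v] = as_idx1(c.members[v]);
    conflict[v] = c.conflict[v] != 0;
    bool sc = false;
    for (int w : c.members[v])
      if (w == v) sc = true;
    selfc[v] = sc;
    s1[v] = c.s1[v];
    s2[v] = c.s2[v];
  }
  return List::create(_["members"] = members, _["conflict"] = conflict,
                      _["self_contained"] = selfc, _["s1"] = s1, _["s2"] = s2);
}

// Greedy scores (per §-style definitions): 1 = |LDOI|; 2 = number of
// composite nodes partially fed by LDOI(v) + v; 3 = their sum; 4/5 = score 1
// penalized (sign flip / shift by the largest single-node LDOI size) when
// LDOI(v) contains the negation of a target state.
static std::vector<double> scores_for(const Cache& c, int nv,
                                      const std::vector<int>& target,
                                      int score_index) {
  std::vector<char> negT(nv, 0);
  for (int t : target) negT[t ^ 1] = 1;
  int maxs1 = 0;
  for (int v = 0; v < nv; ++v) maxs1 = std::max(maxs1, c.s1[v]);
  std::vector<double> g(nv, 0.0);
  for (int v = 0; v < nv; ++v) {
    bool pen = false;
    for (int w : c.members[v])
      if (negT[w]) {
        pen = true;
        break;
      }
    double s1 = c.s1[v], s2 = c.s2[v];
    switch (score_index) {
      case 1: g[v] = s1; break;
      case 2: g[v] = s2; break;
      case 3: g[v] = s1 + s2; break;
      case 4: g[v] = pen ? -s1 : s1; break;
      case 5: g[v] = pen ? s1 - maxs1 : s1; break;
      default: stop("invalid score index");
    }
  }
  return g;
}

// [[Rcpp::export]]
NumericVector cpp_scores(SEXP ptr, IntegerVector target, int score_index) {
  XPtr<ExpNet> p(ptr);
  Cache c;
  build_cache(*p, c);
  std::vector<int> t = as_idx0(target);
  std::vector<double> g = scores_for(c, p->nv, t, score_index);
  return NumericVector(g.begin(), g.end());
}

static bool covers_ld(const LdoiOut& o, const std::vector<int>& target) {
  for (int t : target)
    if (!o.member[t]) return false;
  return true;
}

// One greedy randomized construction (Algorithm-2 style). `excluded_base`
// marks target states, their negations, forbidden states, and the protected
// initial states. Returns a covering solution (including `init`) or an empty
// vector when the candidate list is exhausted.
static std::vector<int> construct_one(const ExpNet& net,
                                      const std::vector<double>& G,
                                      const std::vector<int>& target,
                                      const std::vector<char>& excluded_base,
                                      const std::vector<int>& init) {
  int nv = net.nv;
  std::vector<int> sol(init);
  LdoiOut o;
  std::vector<char> removed(excluded_base);
  if (!sol.empty()) {
    run_ldoi(net, sol, o);
    if (covers_ld(o, target)) return sol;
    for (int w = 0; w < nv; ++w)
      if (o.member[w]) removed[w] = 1;
  }
  double alpha = unif_rand();
  while (true) {
    std::vector<int> cand;
    for (int v = 0; v < nv; ++v)
      if (!removed[v]) cand.push_back(v);
    if (cand.empty()) return std::vector<int>();
    double gmin = G[cand[0]], gmax = G[cand[0]];
    for (int v : cand) {
      gmin = std::min(gmin, G[v]);
      gmax = std::max(gmax, G[v]);
    }
    double gpass = gmin + alpha * (gmax - gmin);
    std::vector<int> rcl;
    for (int v : cand)
      if (G[v] >= gpass) rcl.push_back(v);
    int pick = (int)(unif_rand() * rcl.size());
    if (pick >= (int)rcl.size()) pick = (int)rcl.size() - 1;
    int v = rcl[pick];
    sol.push_back(v);
    run_ldoi(net, sol, o);
    if (covers_ld(o, target)) return sol;
    removed[v] = 1;
    removed[v ^ 1] = 1;
    for (int w = 0; w < nv; ++w)
      if (o.member[w]) removed[w] = 1;
  }
}

// Single randomized removal pass; protected states are never removed.
static std::vector<int> local_search_one(const ExpNet& net,
                                         const std::vector<int>& target,
                                         const std::vector<int>& sol_in,
                                         const std::vector<char>& prot) {
  int m = (int)sol_in.size();
  std::vector<int> order(m);
  for (int i = 0; i < m; ++i) order[i] = i;
  for (int i = m - 1; i > 0; --i) {
    int j = (int)(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(order[i], order[j]);
  }
  std::vector<char> active(m, 1);
  LdoiOut o;
  // Because the truncation rule makes the LDOI non-monotone in the
  // intervention set, a removal can re-enable an earlier one; repeat the
  // randomized pass until no node can be removed.
  bool changed = true;
  while (changed) {
    changed = false;
    for (int oi = 0; oi < m; ++oi) {
      int idx = order[oi];
      if (!active[idx] || prot[sol_in[idx]]) continue;
      std::vector<int> trial;
      for (int k = 0; k < m; ++k)
        if (active[k] && k != idx) trial.push_back(sol_in[k]);
      run_ldoi(net, trial, o);
      if (covers_ld(o, target)) {
        active[idx] = 0;
        changed = true;
      }
    }
  }
  std::vector<int> out;
  for (int k = 0; k < m; ++k)
    if (active[k]) out.push_back(sol_in[k]);
  return out;
}

static void base_exclusions(int nv, const std::vector<int>& target,
                            const std::vector<int>& forbidden,
                            const std::vector<int>& init,
                            std::vector<char>& excl, std::vector<char>& prot) {
  excl.assign(nv, 0);
  prot.assign(nv, 0);
  for (int t : target) {
    excl[t] = 1;
    excl[t ^ 1] = 1;
  }
  for (int f : forbidden) excl[f] = 1;
  for (int v : init) {
    excl[v] = 1;
    excl[v ^ 1] = 1;
    prot[v] = 1;
  }
}

// [[Rcpp::export]]
IntegerVector cpp_construct(SEXP ptr, IntegerVector target,
                            IntegerVector forbidden, IntegerVector init,
                            int score_index) {
  XPtr<ExpNet> p(ptr);
  std::vector<int> t = as_idx0(target), fb = as_idx0(forbidden),
                   in = as_idx0(init);
  Cache c;
  build_cache(*p, c);
  std::vector<double> G = scores_for(c, p->nv, t, score_index);
  std::vector<char> excl, prot;
  base_exclusions(p->nv, t, fb, in, excl, prot);
  return as_idx1(construct_one(*p, G, t, excl, in));
}

// [[Rcpp::export]]
IntegerVector cpp_local_search(SEXP ptr, IntegerVector target,
                               IntegerVector sol, IntegerVector protected_) {
  XPtr<ExpNet> p(ptr);
  std::vector<int> t = as_idx0(target), s = as_idx0(sol),
                   pr = as_idx0(protected_);
  std::vector<char> prot(p->nv, 0);
  for (int v : pr) prot[v] = 1;
  return as_idx1(local_search_one(*p, t, s, prot));
}

// Full GRASP: max_itr independent construction + local-search rounds,
// collecting distinct locally-minimal solutions.
// [[Rcpp::export]]
List cpp_grasp(SEXP ptr, IntegerVector target, IntegerVector forbidden,
               IntegerVector init, int max_itr, int score_index) {
  XPtr<ExpNet> p(ptr);
  const ExpNet& net = *p;
  std::vector<int> t = as_idx0(target), fb = as_idx0(forbidden),
                   in = as_idx0(init);
  Cache c;
  build_cache(net, c);
  std::vector<double> G = scores_for(c, net.nv, t, score_index);
  std::vector<char> excl, prot;
  base_exclusions(net.nv, t, fb, in, excl, prot);

  std::map<std::vector<int>, int> found;  // solution -> first iteration
  for (int it = 1; it <= max_itr; ++it) {
    std::vector<int> sol = construct_one(net, G, t, excl, in);
    if (sol.empty()) continue;  // candidates exhausted, no solution this round
    sol = local_search_one(net, t, sol, prot);
    std::sort(sol.begin(), sol.end());
    if (found.find(sol) == found.end()) found[sol] = it;
  }
  List sols(found.size());
  IntegerVector iters(found.size());
  int i = 0;
  for (const auto& kv : found) {
    sols[i] = as_idx1(kv.first);
    iters[i] = kv.second;
    ++i;
  }
  return List::create(_["solutions"] = sols, _["iteration"] = iters);
}
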