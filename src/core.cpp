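// Network-free rule-based simulation core.
//
// Mixtures are flat agent arrays: per agent a type, and per site an internal
// state plus a bond slot (index of the partner's flat site slot, or -1).
// Rule patterns are connected site-graph patterns whose non-anchor agents are
// each reached through a bond from an earlier pattern agent, so an anchored
// match is unique (0 or 1 embeddings per anchor agent).  The SSA maintains
// per-pattern anchored match counts in Fenwick trees for O(log n) sampling.

#include <Rcpp.h>
#include <cstdint>
#include <array>
#include <map>
#include <set>
#include <string>
#include <vector>
#include <algorithm>
#include <queue>
#include <sstream>
#include <cmath>

using namespace Rcpp;

// ---------------------------------------------------------------- model ----

struct PatCond {
  int pa, site, kind, a1, a2, st;
  // kind: 0 state-only, 1 FREE, 2 BOUND_ANY, 3 BOUND_TO(a1=pa,a2=site),
  //       4 BOUND_TYPE(a1=type,a2=site).  st: -1 any, else required state.
};

struct Pattern {
  std::vector<int> types;                 // per pattern agent
  std::vector<PatCond> conds;
  // attach[j] = (via_pa, via_site) for j >= 1: the mixture image of agent j
  // is the bond partner of image(via_pa) at via_site.
  std::vector<std::pair<int,int>> attach; // index 0 unused
};

struct Action {
  int op, a1, s1, a2, s2, val;
  // op: 0 BIND(a1,s1,a2,s2)  1 UNBIND(a1,s1)  2 STATE(a1,s1,val)
  //     3 DEGRADE(a1)        4 SYNTH(a1 = agent type)
};

struct Rule {
  double rate, aut;
  std::vector<Pattern> comps;             // 0, 1 or 2 components
  std::vector<Action> actions;
};

struct Model {
  int ntypes;
  std::vector<int> nsites;                       // per type
  std::vector<std::vector<int>> nstates;         // per type, per site
  std::vector<std::string> type_names;
  std::vector<std::vector<std::string>> site_names;
  std::vector<std::vector<std::vector<std::string>>> state_names;
  std::vector<Rule> rules;
  std::vector<Pattern> obs;
  std::vector<std::string> obs_names;
  int scaffold_type;                             // -1 if none
  // sites (type, site) that may bind some site of the scaffold type
  std::set<std::pair<int,int>> scaffold_binders;
  int radius;                                    // max pattern eccentricity
};

static Pattern parse_pattern(List p) {
  Pattern out;
  IntegerVector ty = p["types"];
  out.types.assign(ty.begin(), ty.end());
  IntegerMatrix cm = p["conds"];
  for (int i = 0; i < cm.nrow(); ++i)
    out.conds.push_back(PatCond{cm(i,0), cm(i,1), cm(i,2), cm(i,3), cm(i,4), cm(i,5)});
  IntegerMatrix am = p["attach"];
  out.attach.resize(out.types.size(), std::make_pair(-1,-1));
  for (int i = 0; i < am.nrow(); ++i)
    out.attach[am(i,0)] = std::make_pair(am(i,1), am(i,2));
  return out;
}

static Model parse_model(List m) {
  Model M;
  IntegerVector ns = m["nsites"];
  M.nsites.assign(ns.begin(), ns.end());
  M.ntypes = M.nsites.size();
  List nst = m["nstates"];
  for (int t = 0; t < M.ntypes; ++t) {
    IntegerVector v = nst[t];
    M.nstates.push_back(std::vector<int>(v.begin(), v.end()));
  }
  CharacterVector tn = m["type_names"];
  for (int t = 0; t < M.ntypes; ++t) M.type_names.push_back(as<std::string>(tn[t]));
  List sn = m["site_names"];
  for (int t = 0; t < M.ntypes; ++t) {
    CharacterVector v = sn[t];
    std::vector<std::string> w;
    for (int i = 0; i < v.size(); ++i) w.push_back(as<std::string>(v[i]));
    M.site_names.push_back(w);
  }
  List stn = m["state_names"];
  for (int t = 0; t < M.ntypes; ++t) {
    List per_site = stn[t];
    std::vector<std::vector<std::string>> w;
    for (int s = 0; s < per_site.size(); ++s) {
      CharacterVector v = per_site[s];
      std::vector<std::string> u;
      for (int i = 0; i < v.size(); ++i) u.push_back(as<std::string>(v[i]));
      w.push_back(u);
    }
    M.state_names.push_back(w);
  }
  List rules = m["rules"];
  for (int r = 0; r < rules.size(); ++r) {
    List rl = rules[r];
    Rule R;
    R.rate = as<double>(rl["rate"]);
    R.aut  = as<double>(rl["aut"]);
    List comps = rl["comps"];
    for (int c = 0; c < comps.size(); ++c) R.comps.push_back(parse_pattern(comps[c]));
    IntegerMatrix am = rl["actions"];
    for (int i = 0; i < am.nrow(); ++i)
      R.actions.push_back(Action{am(i,0), am(i,1), am(i,2), am(i,3), am(i,4), am(i,5)});
    M.rules.push_back(R);
  }
  List obs = m["obs"];
  for (int i = 0; i < obs.size(); ++i) M.obs.push_back(parse_pattern(obs[i]));
  CharacterVector on = m["obs_names"];
  for (int i = 0; i < on.size(); ++i) M.obs_names.push_back(as<std::string>(on[i]));
  M.scaffold_type = as<int>(m["scaffold_type"]);
  IntegerMatrix sb = m["scaffold_binders"];
  for (int i = 0; i < sb.nrow(); ++i)
    M.scaffold_binders.insert(std::make_pair(sb(i,0), sb(i,1)));
  M.radius = as<int>(m["radius"]);
  return M;
}

// ---------------------------------------------------------------- state ----

struct Mix {
  const Model *M;
  std::vector<int> type;        // -1 = dead slot
  std::vector<int> off;         // flat site offset per agent
  std::vector<int> st, bd;      // flat per-site state / partner slot (-1)
  std::vector<int> owner;       // flat slot -> owning agent
  int nsites_total = 0;

  int slot(int a, int s) const { return off[a] + s; }
  int partner_agent(int a, int s, int *psite = 0) const {
    int b = bd[off[a] + s];
    if (b < 0) return -1;
    int pa = owner[b];
    if (psite) *psite = b - off[pa];
    return pa;
  }
  void add_agent(int t) {
    type.push_back(t);
    off.push_back(nsites_total);
    int k = M->nsites[t];
    for (int i = 0; i < k; ++i) {
      st.push_back(0); bd.push_back(-1);
      owner.push_back(type.size() - 1);
    }
    nsites_total += k;
  }
};

static Mix parse_state(const Model &M, List s) {
  Mix x; x.M = &M;
  IntegerVector ty = s["type"], stv = s["state"], bdv = s["bond"];
  x.type.assign(ty.begin(), ty.end());
  x.st.assign(stv.begin(), stv.end());
  x.bd.assign(bdv.begin(), bdv.end());
  x.off.resize(x.type.size());
  int acc = 0;
  for (size_t a = 0; a < x.type.size(); ++a) {
    x.off[a] = acc;
    acc += (x.type[a] >= 0) ? M.nsites[x.type[a]] : 0;
  }
  x.nsites_total = acc;
  if ((int)x.st.size() != acc || (int)x.bd.size() != acc)
    stop("state/bond length does not match agent site totals");
  x.owner.resize(acc);
  for (size_t a = 0; a < x.type.size(); ++a)
    if (x.type[a] >= 0)
      for (int s = 0; s < M.nsites[x.type[a]]; ++s) x.owner[x.off[a] + s] = a;
  return x;
}

static List emit_state(const Mix &x) {
  // compact: drop dead agents, remap bonds
  const Model &M = *x.M;
  int n = x.type.size();
  std::vector<int> newoff(n, -1);
  std::vector<int> keep;
  int acc = 0;
  for (int a = 0; a < n; ++a) if (x.type[a] >= 0) {
    keep.push_back(a); newoff[a] = acc; acc += M.nsites[x.type[a]];
  }
  IntegerVector ty(keep.size()), stv(acc), bdv(acc);
  for (size_t i = 0; i < keep.size(); ++i) {
    int a = keep[i]; ty[i] = x.type[a];
    for (int s = 0; s < M.nsites[x.type[a]]; ++s) {
      stv[newoff[a] + s] = x.st[x.off[a] + s];
      int b = x.bd[x.off[a] + s];
      if (b < 0) bdv[newoff[a] + s] = -1;
      else {
        int ps; int pa = x.partner_agent(a, s, &ps);
        bdv[newoff[a] + s] = newoff[pa] + ps;
      }
    }
  }
  return List::create(_["type"] = ty, _["state"] = stv, _["bond"] = bdv);
}

// ------------------------------------------------------------- matching ----

// anchored unique match; returns true and fills assign (pattern agent ->
// mixture agent) when the pattern embeds with agent 0 at `anchor`.
static bool match_anchor(const Mix &x, const Pattern &P, int anchor,
                         std::vector<int> &assign) {
  int n = P.types.size();
  assign.assign(n, -1);
  if (x.type[anchor] != P.types[0]) return false;
  assign[0] = anchor;
  for (int j = 1; j < n; ++j) {
    int via = P.attach[j].first, vs = P.attach[j].second;
    int img = assign[via];
    if (img < 0) return false;
    int ps, pa = x.partner_agent(img, vs, &ps);
    if (pa < 0 || x.type[pa] != P.types[j]) return false;
    assign[j] = pa;
  }
  // injectivity
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (assign[i] == assign[j]) return false;
  // conditions
  for (const PatCond &c : P.conds) {
    int a = assign[c.pa];
    int sl = x.slot(a, c.site);
    if (c.st >= 0 && x.st[sl] != c.st) return false;
    switch (c.kind) {
      case 0: break;
      case 1: if (x.bd[sl] != -1) return false; break;
      case 2: if (x.bd[sl] == -1) return false; break;
      case 3: {
        int ps, pa = x.partner_agent(a, c.site, &ps);
        if (pa < 0 || pa != assign[c.a1] || ps != c.a2) return false;
        break;
      }
      case 4: {
        int ps, pa = x.partner_agent(a, c.site, &ps);
        if (pa < 0 || x.type[pa] != c.a1 || ps != c.a2) return false;
        break;
      }
      default: stop("bad pattern condition kind");
    }
  }
  return true;
}

// -------------------------------------------------------- canonical form ---

// Exact canonicalization of one connected complex: iterative colour
// refinement on (type, states, bonded-site profile), then backtracking over
// remaining colour ties, emitting the lexicographically minimal
// serialization.
struct Canon {
  const Mix &x;
  const Model &M;
  std::vector<int> agents;               // complex members (mixture ids)
  std::map<int,int> local;               // mixture id -> 0..k-1
  std::string best;
  bool have_best = false;

  Canon(const Mix &x_, const std::vector<int> &ag) : x(x_), M(*x_.M), agents(ag) {
    for (size_t i = 0; i < agents.size(); ++i) local[agents[i]] = i;
  }

  std::vector<int> refine(std::vector<long long> col) {
    int k = agents.size();
    std::vector<int> out(k);
    for (int iter = 0; iter < k + 1; ++iter) {
      std::vector<std::vector<long long>> key(k);
      for (int i = 0; i < k; ++i) {
        int a = agents[i];
        key[i].push_back(col[i]);
        std::vector<std::array<long long,3>> nb;
        for (int s = 0; s < M.nsites[x.type[a]]; ++s) {
          int ps, pa = x.partner_agent(a, s, &ps);
          if (pa >= 0) nb.push_back({(long long)s, (long long)ps, col[local[pa]]});
        }
        std::sort(nb.begin(), nb.end());
        for (auto &t : nb) { key[i].push_back(t[0]); key[i].push_back(t[1]); key[i].push_back(t[2]); }
      }
      std::map<std::vector<long long>, int> rank;
      for (int i = 0; i < k; ++i) rank[key[i]] = 0;
      int r = 0;
      for (auto &kv : rank) kv.second = r++;
      bool changed = false;
      for (int i = 0; i < k; ++i) {
        int nc = rank[key[i]];
        if (nc != col[i]) changed = true;
        out[i] = nc;
      }
      if (!changed) break;
      col.assign(out.begin(), out.end());
    }
    return out;
  }

  std::vector<long long> init_colors() {
    int k = agents.size();
    std::vector<std::vector<long long>> key(k);
    for (int i = 0; i < k; ++i) {
      int a = agents[i];
      key[i].push_back(x.type[a]);
      for (int s = 0; s < M.nsites[x.type[a]]; ++s) {
        key[i].push_back(x.st[x.slot(a, s)]);
        key[i].push_back(x.bd[x.slot(a, s)] >= 0 ? 1 : 0);
      }
    }
    std::map<std::vector<long long>, int> rank;
    for (int i = 0; i < k; ++i) rank[key[i]] = 0;
    int r = 0;
    for (auto &kv : rank) kv.second = r++;
    std::vector<long long> col(k);
    for (int i = 0; i < k; ++i) col[i] = rank[key[i]];
    return col;
  }

  std::string serialize(const std::vector<int> &order) {
    // order: positions -> local index
    int k = agents.size();
    std::vector<int> pos(k);
    for (int p = 0; p < k; ++p) pos[order[p]] = p;
    std::map<std::pair<int,int>, int> bondlab; // (min flat slot, max) -> label
    // assign labels in traversal order
    int next = 1;
    std::ostringstream out;
    std::map<long long,int> lab;   // key by canonical (posA,siteA,posB,siteB)
    // first pass to assign labels deterministically
    for (int p = 0; p < k; ++p) {
      int a = agents[order[p]];
      for (int s = 0; s < M.nsites[x.type[a]]; ++s) {
        int ps, pa = x.partner_agent(a, s, &ps);
        if (pa < 0) continue;
        int q = pos[local[pa]];
        long long key = (p < q || (p == q && s < ps))
          ? ((((long long)p * 64 + s) * 4096 + q) * 64 + ps)
          : ((((long long)q * 64 + ps) * 4096 + p) * 64 + s);
        if (!lab.count(key)) lab[key] = 0;
      }
    }
    // label in order of first appearance during serialization
    for (int p = 0; p < k; ++p) {
      int a = agents[order[p]];
      if (p) out << '.';
      out << M.type_names[x.type[a]] << '(';
      bool first = true;
      for (int s = 0; s < M.nsites[x.type[a]]; ++s) {
        int sl = x.slot(a, s);
        bool bonded = x.bd[sl] >= 0;
        bool statey = M.nstates[x.type[a]][s] > 1 && x.st[sl] != 0;
        if (!bonded && !statey) continue;
        if (!first) out << ',';
        first = false;
        out << M.site_names[x.type[a]][s];
        if (M.nstates[x.type[a]][s] > 1 && x.st[sl] != 0)
          out << '~' << M.state_names[x.type[a]][s][x.st[sl]];
        if (bonded) {
          int ps, pa = x.partner_agent(a, s, &ps);
          int q = pos[local[pa]];
          long long key = (p < q || (p == q && s < ps))
            ? ((((long long)p * 64 + s) * 4096 + q) * 64 + ps)
            : ((((long long)q * 64 + ps) * 4096 + p) * 64 + s);
          int &l = lab[key];
          if (l == 0) l = next++;
          out << '!' << l;
        }
      }
      out << ')';
    }
    return out.str();
  }

  void search(std::vector<long long> col, std::vector<int> placed) {
    int k = agents.size();
    std::vector<int> ref = refine(col);
    if ((int)placed.size() == k) {
      // all individualized: order by colour
      std::vector<int> order(k);
      std::vector<std::pair<int,int>> cp(k);
      for (int i = 0; i < k; ++i) cp[i] = std::make_pair(ref[i], i);
      std::sort(cp.begin(), cp.end());
      for (int p = 0; p < k; ++p) order[p] = cp[p].second;
      std::string s = serialize(order);
      if (!have_best || s < best) { best = s; have_best = true; }
      return;
    }
    // discrete colouring? then every agent separated
    std::set<int> uniq(ref.begin(), ref.end());
    if ((int)uniq.size() == k) {
      std::vector<int> all(k);
      for (int i = 0; i < k; ++i) all[i] = i;
      std::vector<long long> c2(ref.begin(), ref.end());
      search(c2, all);
      return;
    }
    // find smallest non-singleton colour class (by colour value)
    std::map<int, std::vector<int>> classes;
    for (int i = 0; i < k; ++i) classes[ref[i]].push_back(i);
    int target = -1;
    for (auto &kv : classes) if (kv.second.size() > 1) { target = kv.first; break; }
    for (int cand : classes[target]) {
      std::vector<long long> c2(ref.begin(), ref.end());
      c2[cand] = k + 1000;               // individualize
      std::vector<int> pl = placed; pl.push_back(cand);
      search(c2, pl);
    }
  }

  std::string run() {
    int k = agents.size();
    if (k == 1) return serialize(std::vector<int>{0});
    if (k == 2) {
      std::string a = serialize(std::vector<int>{0, 1});
      std::string b = serialize(std::vector<int>{1, 0});
      return a < b ? a : b;
    }
    std::vector<long long> col = init_colors();
    search(col, std::vector<int>());
    return best;
  }
};

static void component_of(const Mix &x, int seed, std::vector<int> &out,
                         std::vector<char> &seen) {
  out.clear();
  std::queue<int> q; q.push(seed); seen[seed] = 1;
  while (!q.empty()) {
    int a = q.front(); q.pop();
    out.push_back(a);
    for (int s = 0; s < x.M->nsites[x.type[a]]; ++s) {
      int pa = x.partner_agent(a, s);
      if (pa >= 0 && !seen[pa]) { seen[pa] = 1; q.push(pa); }
    }
  }
  std::sort(out.begin(), out.end());
}

static bool complex_scaffoldable(const Mix &x, const std::vector<int> &ag) {
  const Model &M = *x.M;
  if (M.scaffold_type < 0) return false;
  for (int a : ag) if (x.type[a] == M.scaffold_type) return true;
  for (int a : ag)
    for (int s = 0; s < M.nsites[x.type[a]]; ++s)
      if (x.bd[x.slot(a, s)] == -1 &&
          M.scaffold_binders.count(std::make_pair(x.type[a], s)))
        return true;
  return false;
}

// extract sub-state of one complex (for species structures)
static List sub_state(const Mix &x, const std::vector<int> &ag) {
  const Model &M = *x.M;
  std::map<int,int> newid;
  for (size_t i = 0; i < ag.size(); ++i) newid[ag[i]] = i;
  std::vector<int> noff(ag.size());
  int acc = 0;
  for (size_t i = 0; i < ag.size(); ++i) { noff[i] = acc; acc += M.nsites[x.type[ag[i]]]; }
  IntegerVector ty(ag.size()), stv(acc), bdv(acc);
  for (size_t i = 0; i < ag.size(); ++i) {
    int a = ag[i]; ty[i] = x.type[a];
    for (int s = 0; s < M.nsites[x.type[a]]; ++s) {
      stv[noff[i] + s] = x.st[x.slot(a, s)];
      int ps, pa = x.partner_agent(a, s, &ps);
      bdv[noff[i] + s] = (pa < 0) ? -1 : noff[newid[pa]] + ps;
    }
  }
  return List::create(_["type"] = ty, _["state"] = stv, _["bond"] = bdv);
}

// ----------------------------------------------------------------- RNG -----

struct RNG { // xoshiro-style splitmix64; deterministic across platforms
  uint64_t s;
  RNG(uint64_t seed) : s(seed ^ 0x9E3779B97F4A7C15ULL) { next(); next(); }
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  double unif_pos() { double u; do { u = unif(); } while (u <= 0.0); return u; }
  double rexp(double rate) { return -std::log(unif_pos()) / rate; }
};

// ---------------------------------------------------------------- fenwick --

struct Fenwick {
  std::vector<int> tree;
  int n = 0, total = 0;
  void init(int n_) { n = n_; tree.assign(n + 1, 0); total = 0; }
  void grow(int n_) { // preserve counts
    std::vector<int> cnt(n_, 0);
    for (int i = 0; i < n; ++i) cnt[i] = value(i);
    init(n_);
    for (int i = 0; i < (int)cnt.size(); ++i) if (cnt[i]) update(i, cnt[i]);
  }
  void update(int i, int d) {
    total += d;
    for (++i; i <= n; i += i & (-i)) tree[i] += d;
  }
  int value(int i) const {
    int v = 0;
    for (int j = i + 1; j > 0; j -= j & (-j)) v += tree[j];
    for (int j = i; j > 0; j -= j & (-j)) v -= tree[j];
    return v;
  }
  int sample(double u) const { // u in [0, total): index with cumulative > u
    int pos = 0, rem = (int)u;
    int logn = 1; while ((1 << logn) <= n) ++logn;
    for (int k = logn; k >= 0; --k) {
      int nxt = pos + (1 << k);
      if (nxt <= n && tree[nxt] <= rem) { rem -= tree[nxt]; pos = nxt; }
    }
    return pos; // 0-based index
  }
};

// ---------------------------------------------------------------- SSA ------

struct Store { // anchored matches of one rule component
  int rule, comp, anchor_type;
  Fenwick fen;
  std::vector<char> cnt;
};

struct SSA {
  const Model &M;
  Mix &x;
  RNG rng;
  std::vector<Store> stores;
  std::vector<std::vector<int>> stores_by_type;
  std::vector<std::vector<int>> rule_store; // rule -> store ids per comp

  SSA(const Model &M_, Mix &x_, uint64_t seed) : M(M_), x(x_), rng(seed) {
    stores_by_type.resize(M.ntypes);
    rule_store.resize(M.rules.size());
    for (size_t r = 0; r < M.rules.size(); ++r)
      for (size_t c = 0; c < M.rules[r].comps.size(); ++c) {
        Store s; s.rule = r; s.comp = c;
        s.anchor_type = M.rules[r].comps[c].types[0];
        stores.push_back(s);
        rule_store[r].push_back(stores.size() - 1);
        stores_by_type[s.anchor_type].push_back(stores.size() - 1);
      }
    int cap = x.type.size();
    std::vector<int> assign;
    for (auto &s : stores) {
      s.fen.init(cap);
      s.cnt.assign(cap, 0);
      const Pattern &P = M.rules[s.rule].comps[s.comp];
      for (int a = 0; a < cap; ++a)
        if (x.type[a] == s.anchor_type && match_anchor(x, P, a, assign)) {
          s.cnt[a] = 1; s.fen.update(a, 1);
        }
    }
  }

  std::vector<int> scratch_assign, bfs_nodes, bfs_dist;

  void refresh_agent(int a) {
    if (a >= (int)x.type.size()) return;
    if (x.type[a] >= 0) {
      for (int sid : stores_by_type[x.type[a]]) {
        Store &s = stores[sid];
        int c = match_anchor(x, M.rules[s.rule].comps[s.comp], a, scratch_assign) ? 1 : 0;
        if (c != s.cnt[a]) { s.fen.update(a, c - s.cnt[a]); s.cnt[a] = c; }
      }
    } else { // dead: zero everywhere
      for (auto &s : stores)
        if (a < (int)s.cnt.size() && s.cnt[a]) { s.fen.update(a, -1); s.cnt[a] = 0; }
    }
  }

  void neighborhood(int a, int radius, std::vector<int> &out) {
    out.push_back(a);
    if (x.type[a] < 0) return;
    bfs_nodes.clear(); bfs_dist.clear();
    bfs_nodes.push_back(a); bfs_dist.push_back(0);
    size_t k = 0;
    while (k < bfs_nodes.size()) {
      int u = bfs_nodes[k], d = bfs_dist[k];
      ++k;
      if (d == radius) continue;
      for (int s = 0; s < M.nsites[x.type[u]]; ++s) {
        int pa = x.partner_agent(u, s);
        if (pa < 0) continue;
        bool seen = false;
        for (int v : bfs_nodes) if (v == pa) { seen = true; break; }
        if (!seen) {
          bfs_nodes.push_back(pa); bfs_dist.push_back(d + 1);
          out.push_back(pa);
        }
      }
    }
  }

  // apply rule r at an embedding (left pattern agents -> mixture agents);
  // synthesized agents are appended to the embedding so later actions
  // (state assignment, binding) can target them.
  void apply(int r, const std::vector<int> &emb_in) {
    const Rule &R = M.rules[r];
    std::vector<int> emb = emb_in;
    std::vector<int> seeds;
    for (const Action &A : R.actions) {
      if (A.op == 4) continue;
      if (A.a1 >= (int)emb.size()) continue; // targets a synthesized agent
      switch (A.op) {
        case 0: case 2:
          seeds.push_back(emb[A.a1]);
          if (A.op == 0 && A.a2 < (int)emb.size()) seeds.push_back(emb[A.a2]);
          break;
        case 1: {
          int pa = x.partner_agent(emb[A.a1], A.s1);
          seeds.push_back(emb[A.a1]); if (pa >= 0) seeds.push_back(pa);
          break;
        }
        case 3: {
          int a = emb[A.a1];
          seeds.push_back(a);
          for (int s = 0; s < M.nsites[x.type[a]]; ++s) {
            int pa = x.partner_agent(a, s);
            if (pa >= 0) seeds.push_back(pa);
          }
          break;
        }
        case 4: break;
      }
    }
    std::vector<int> dirty;
    for (int sd : seeds) neighborhood(sd, M.radius, dirty);
    std::vector<int> created;
    for (const Action &A : R.actions) {
      switch (A.op) {
        case 0: {
          int sa = x.slot(emb[A.a1], A.s1), sb = x.slot(emb[A.a2], A.s2);
          if (x.bd[sa] != -1 || x.bd[sb] != -1) stop("stale embedding: site not free");
          x.bd[sa] = sb; x.bd[sb] = sa;
          break;
        }
        case 1: {
          int sa = x.slot(emb[A.a1], A.s1);
          int sb = x.bd[sa];
          if (sb == -1) stop("stale embedding: site not bound");
          x.bd[sa] = -1; x.bd[sb] = -1;
          break;
        }
        case 2: x.st[x.slot(emb[A.a1], A.s1)] = A.val; break;
        case 3: {
          int a = emb[A.a1];
          for (int s = 0; s < M.nsites[x.type[a]]; ++s) {
            int sl = x.slot(a, s);
            if (x.bd[sl] >= 0) { x.bd[x.bd[sl]] = -1; x.bd[sl] = -1; }
            x.st[sl] = 0;
          }
          x.type[a] = -2 - x.type[a]; // mark dead but keep layout width
          break;
        }
        case 4: {
          int before = x.type.size();
          x.add_agent(A.a1);
          created.push_back(before);
          emb.push_back(before);
          for (auto &s : stores) if (s.fen.n < (int)x.type.size()) {
            s.fen.grow(x.type.size() + 16);
            s.cnt.resize(x.type.size() + 16, 0);
          }
          break;
        }
      }
    }
    for (int sd : seeds) neighborhood(sd, M.radius, dirty);
    for (int c : created) neighborhood(c, M.radius, dirty);
    std::sort(dirty.begin(), dirty.end());
    dirty.erase(std::unique(dirty.begin(), dirty.end()), dirty.end());
    for (int a : dirty) {
      if (x.type[a] <= -2) { // dead: zero its counts
        for (auto &s : stores)
          if (a < (int)s.cnt.size() && s.cnt[a]) { s.fen.update(a, -1); s.cnt[a] = 0; }
      } else refresh_agent(a);
    }
  }
};

// dead marker uses type <= -2 internally; emit_state drops type < 0.
// (emit_state checks type >= 0, so both -1 and -2-t are dropped; layout
// widths for dead agents are preserved inside the SSA via off[] already
// computed, since we never rebuild offsets mid-run.)

static List snapshot_species(const Mix &x, bool structures) {
  int n = x.type.size();
  std::vector<char> seen(n, 1);
  for (int a = 0; a < n; ++a) if (x.type[a] >= 0) seen[a] = 0;
  struct Info { int copies; std::vector<int> rep; int nagents; bool scaff; };
  std::map<std::string, Info> sp;
  std::vector<int> comp;
  for (int a = 0; a < n; ++a) {
    if (seen[a]) continue;
    component_of(x, a, comp, seen);
    Canon cn(x, comp);
    std::string key = cn.run();
    auto it = sp.find(key);
    if (it == sp.end())
      sp[key] = Info{1, comp, (int)comp.size(), complex_scaffoldable(x, comp)};
    else it->second.copies++;
  }
  int k = sp.size();
  CharacterVector species(k);
  IntegerVector copies(k), sizes(k);
  LogicalVector scaff(k);
  List structs(structures ? k : 0);
  int i = 0;
  for (auto &kv : sp) {
    species[i] = kv.first;
    copies[i] = kv.second.copies;
    sizes[i] = kv.second.nagents;
    scaff[i] = kv.second.scaff;
    if (structures) structs[i] = sub_state(x, kv.second.rep);
    ++i;
  }
  List out = List::create(_["species"] = species, _["copies"] = copies,
                          _["size"] = sizes, _["scaffold"] = scaff);
  if (structures) out["structure"] = structs;
  return out;
}

static NumericVector observe(const Mix &x, const Model &M) {
  NumericVector out(M.obs.size());
  std::vector<int> assign;
  for (size_t o = 0; o < M.obs.size(); ++o) {
    const Pattern &P = M.obs[o];
    int tot = 0;
    for (size_t a = 0; a < x.type.size(); ++a)
      if (x.type[a] == P.types[0] && match_anchor(x, P, a, assign)) ++tot;
    out[o] = tot;
  }
  return out;
}

// ------------------------------------------------------------- exports -----

// [[Rcpp::export]]
List ps_cpp_components(List model, List state, bool structures = false) {
  Model M = parse_model(model);
  Mix x = parse_state(M, state);
  return snapshot_species(x, structures);
}

// [[Rcpp::export]]
std::string ps_cpp_canonical(List model, List state) {
  Model M = parse_model(model);
  Mix x = parse_state(M, state);
  int n = x.type.size();
  if (n == 0) stop("empty state has no canonical form");
  std::vector<char> seen(n, 0);
  std::vector<int> comp;
  component_of(x, 0, comp, seen);
  if ((int)comp.size() != n)
    stop("complex is disconnected; split into components first");
  Canon cn(x, comp);
  return cn.run();
}

// [[Rcpp::export]]
IntegerMatrix ps_cpp_component_embeddings(List model, List state, List pattern) {
  // all anchored embeddings of a single connected pattern component
  Model M = parse_model(model);
  Mix x = parse_state(M, state);
  Pattern P = parse_pattern(pattern);
  std::vector<std::vector<int>> found;
  std::vector<int> assign;
  for (size_t a = 0; a < x.type.size(); ++a)
    if (x.type[a] == P.types[0] && match_anchor(x, P, a, assign))
      found.push_back(assign);
  IntegerMatrix out(found.size(), P.types.size());
  for (size_t i = 0; i < found.size(); ++i)
    for (size_t j = 0; j < P.types.size(); ++j) out(i, j) = found[i][j];
  return out;
}

// [[Rcpp::export]]
List ps_cpp_apply(List model, List state, int rule, IntegerVector embedding) {
  Model M = parse_model(model);
  Mix x = parse_state(M, state);
  SSA sim(M, x, 1);
  std::vector<int> emb(embedding.begin(), embedding.end());
  sim.apply(rule, emb);
  return emit_state(x);
}

// [[Rcpp::export]]
List ps_cpp_ssa(List model, List state, double t_start, double t_end,
                NumericVector snap_times, double seed,
                bool structures = false, double max_events = 5e8,
                bool record_species = true) {
  Model M = parse_model(model);
  Mix x = parse_state(M, state);
  SSA sim(M, x, (uint64_t)seed);
  int nr = M.rules.size();
  double t = t_start;
  int snap_i = 0, nsnap = snap_times.size();
  List snaps(nsnap);
  NumericMatrix obs(nsnap, M.obs.size());
  double events = 0, nulls = 0;
  std::vector<double> act(nr);
  std::vector<int> assign1, assign2;
  while (true) {
    double total = 0;
    for (int r = 0; r < nr; ++r) {
      const Rule &R = M.rules[r];
      double a = R.rate;
      for (size_t c = 0; c < R.comps.size(); ++c)
        a *= sim.stores[sim.rule_store[r][c]].fen.total;
      a /= R.aut;
      act[r] = a; total += a;
    }
    double tnext = (total > 0) ? t + sim.rng.rexp(total) : R_PosInf;
    while (snap_i < nsnap && snap_times[snap_i] <= std::min(tnext, t_end) + 1e-12) {
      if (record_species) snaps[snap_i] = snapshot_species(x, structures);
      NumericVector ov = observe(x, M);
      for (int j = 0; j < ov.size(); ++j) obs(snap_i, j) = ov[j];
      ++snap_i;
    }
    if (tnext > t_end || total <= 0) { t = t_end; break; }
    t = tnext;
    if (++events > max_events) stop("event budget exceeded");
    // select rule
    double u = sim.rng.unif() * total, accu = 0;
    int r = nr - 1;
    for (int i = 0; i < nr; ++i) { accu += act[i]; if (u < accu) { r = i; break; } }
    const Rule &R = M.rules[r];
    // select embedding
    std::vector<int> emb;
    bool ok = true;
    if (R.comps.size() >= 1) {
      Store &s1 = sim.stores[sim.rule_store[r][0]];
      int a1 = s1.fen.sample(sim.rng.unif() * s1.fen.total);
      ok = match_anchor(x, R.comps[0], a1, assign1);
      if (ok) emb = assign1;
    }
    if (ok && R.comps.size() == 2) {
      Store &s2 = sim.stores[sim.rule_store[r][1]];
      int a2 = s2.fen.sample(sim.rng.unif() * s2.fen.total);
      ok = match_anchor(x, R.comps[1], a2, assign2);
      if (ok) {
        for (int v : assign2)
          for (int w : emb) if (v == w) { ok = false; break; }
        if (ok) emb.insert(emb.end(), assign2.begin(), assign2.end());
      }
    }
    if (!ok) { ++nulls; continue; } // null event (overlapping reactants)
    sim.apply(r, emb);
  }
  colnames(obs) = wrap(M.obs_names);
  return List::create(_["state"] = emit_state(x), _["snapshots"] = snaps,
                      _["snap_times"] = snap_times, _["obs"] = obs,
                      _["events"] = events, _["null_events"] = nulls);
}

// ------------------------------------------------------------ enumeration --

// [[Rcpp::export]]
List ps_cpp_enumerate(List model, List seed_species, int max_species) {
  Model M = parse_model(model);
  std::map<std::string, int> index;
  std::vector<List> structs;                 // compact state per species
  std::vector<std::vector<char>> comp_match; // per species, per (rule,comp)
  std::vector<char> rule_fired(M.rules.size(), 0);
  bool overflow = false;

  int nslots = 0;
  std::vector<std::pair<int,int>> slot_of;   // (rule, comp)
  for (size_t r = 0; r < M.rules.size(); ++r)
    for (size_t c = 0; c < M.rules[r].comps.size(); ++c)
      slot_of.push_back(std::make_pair(r, c)), ++nslots;

  std::vector<int> assign;

  auto add_species = [&](List st) -> int {
    Mix x = parse_state(M, st);
    if (x.type.size() == 0) return -1;
    std::vector<char> seen(x.type.size(), 0);
    std::vector<int> comp;
    component_of(x, 0, comp, seen);
    Canon cn(x, comp);
    std::string key = cn.run();
    auto it = index.find(key);
    if (it != index.end()) return it->second;
    if ((int)structs.size() >= max_species) { overflow = true; return -1; }
    int id = structs.size();
    index[key] = id;
    structs.push_back(st);
    std::vector<char> cm(nslots, 0);
    for (int sl = 0; sl < nslots; ++sl) {
      const Pattern &P = M.rules[slot_of[sl].first].comps[slot_of[sl].second];
      for (size_t a = 0; a < x.type.size(); ++a)
        if (x.type[a] == P.types[0] && match_anchor(x, P, a, assign)) { cm[sl] = 1; break; }
    }
    comp_match.push_back(cm);
    return id;
  };

  for (int i = 0; i < seed_species.size(); ++i) add_species(seed_species[i]);

  // synthesis-only rules seed their products
  for (size_t r = 0; r < M.rules.size(); ++r)
    if (M.rules[r].comps.size() == 0) {
      Mix x; x.M = &M;
      for (const Action &A : M.rules[r].actions)
        if (A.op == 4) x.add_agent(A.a1);
      if (x.type.size()) {
        rule_fired[r] = 1;
        // split into components (each synthesized agent separate)
        List st = emit_state(x);
        List comps = snapshot_species(parse_state(M, st), true);
        List cs = comps["structure"];
        for (int i = 0; i < cs.size(); ++i) add_species(cs[i]);
      }
    }

  auto apply_all = [&](Mix &x, int r) {
    // enumerate embeddings of rule r in mixture x, apply each on a copy
    const Rule &R = M.rules[r];
    std::vector<std::vector<int>> embs;
    std::vector<int> as1, as2;
    if (R.comps.size() == 1) {
      for (size_t a = 0; a < x.type.size(); ++a)
        if (x.type[a] == R.comps[0].types[0] && match_anchor(x, R.comps[0], a, as1))
          embs.push_back(as1);
    } else if (R.comps.size() == 2) {
      std::vector<std::vector<int>> e1, e2;
      for (size_t a = 0; a < x.type.size(); ++a) {
        if (x.type[a] == R.comps[0].types[0] && match_anchor(x, R.comps[0], a, as1))
          e1.push_back(as1);
        if (x.type[a] == R.comps[1].types[0] && match_anchor(x, R.comps[1], a, as2))
          e2.push_back(as2);
      }
      for (auto &u : e1) for (auto &v : e2) {
        bool ov = false;
        for (int a : u) for (int b : v) if (a == b) ov = true;
        if (ov) continue;
        std::vector<int> e = u;
        e.insert(e.end(), v.begin(), v.end());
        embs.push_back(e);
      }
    }
    for (auto &e : embs) {
      rule_fired[r] = 1;
      List st = emit_state(x);        // fresh copy each application
      Mix y = parse_state(M, st);
      SSA sim(M, y, 1);
      sim.apply(r, e);
      List res = snapshot_species(y, true);
      List cs = res["structure"];
      for (int i = 0; i < cs.size(); ++i) {
        add_species(cs[i]);
        if (overflow) return;
      }
    }
  };

  for (size_t i = 0; i < structs.size() && !overflow; ++i) {
    Rcpp::checkUserInterrupt();
    for (size_t r = 0; r < M.rules.size() && !overflow; ++r) {
      const Rule &R = M.rules[r];
      if (R.comps.size() == 1) {
        Mix x = parse_state(M, structs[i]);
        apply_all(x, r);
      } else if (R.comps.size() == 2) {
        // pair species i with every species j <= i (both orders via embs)
        int sl1 = -1, sl2 = -1;
        for (int sl = 0; sl < nslots; ++sl)
          if (slot_of[sl].first == (int)r)
            (slot_of[sl].second == 0 ? sl1 : sl2) = sl;
        for (size_t j = 0; j <= i && !overflow; ++j) {
          bool try12 = comp_match[i][sl1] && comp_match[j][sl2];
          bool try21 = comp_match[j][sl1] && comp_match[i][sl2];
          if (!try12 && !try21) continue;
          // combined mixture of one copy of each
          List si = structs[i], sj = structs[j];
          IntegerVector ti = si["type"], tj = sj["type"];
          IntegerVector pi = si["state"], pj = sj["state"];
          IntegerVector bi = si["bond"], bj = sj["bond"];
          int offs = pi.size();
          IntegerVector ty(ti.size() + tj.size()), stv(pi.size() + pj.size()),
                        bdv(bi.size() + bj.size());
          for (int k = 0; k < ti.size(); ++k) ty[k] = ti[k];
          for (int k = 0; k < tj.size(); ++k) ty[ti.size() + k] = tj[k];
          for (int k = 0; k < pi.size(); ++k) { stv[k] = pi[k]; bdv[k] = bi[k]; }
          for (int k = 0; k < pj.size(); ++k) {
            stv[offs + k] = pj[k];
            bdv[offs + k] = (bj[k] < 0) ? -1 : bj[k] + offs;
          }
          List comb = List::create(_["type"] = ty, _["state"] = stv, _["bond"] = bdv);
          Mix x = parse_state(M, comb);
          apply_all(x, r);
        }
      }
    }
  }

  int k = structs.size();
  CharacterVector species(k);
  LogicalVector scaff(k);
  List strs(k);
  for (auto &kv : index) {
    int id = kv.second;
    species[id] = kv.first;
    Mix x = parse_state(M, structs[id]);
    std::vector<int> all(x.type.size());
    for (size_t a = 0; a < x.type.size(); ++a) all[a] = a;
    scaff[id] = complex_scaffoldable(x, all);
    strs[id] = structs[id];
  }
  LogicalVector rf(M.rules.size());
  for (size_t r = 0; r < M.rules.size(); ++r) rf[r] = rule_fired[r] != 0;
  return List::create(_["species"] = species, _["scaffold"] = scaff,
                      _["structure"] = strs, _["overflow"] = overflow,
                      _["rule_fired"] = rf);
}
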