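// Bidirected minimizer-space de Bruijn graph: construction from canonical
// k'-min-mers, unitig compaction, tip clipping, superbubble popping, and the
// progressive abundance filter.
//
// Oriented vertex encoding: v = 2*node + o with o = 0 (forward, tuple as
// stored) or 1 (reverse). The mirror of vertex v is v^1; every directed edge
// v->w coexists with its mirror (w^1)->(v^1).
#include <Rcpp.h>
#include <algorithm>
#include <array>
#include <climits>
#include <cstdint>
#include <functional>
#include <map>
#include <set>
#include <string>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

typedef std::vector<int> ivec;

static int lower_median_i(std::vector<int> x) {
  if (x.empty()) return 0;
  std::sort(x.begin(), x.end());
  return x[(x.size() - 1) / 2];
}

struct Unitig {
  ivec path;        // oriented vertex ids
  int abundance;
  bool circular;
  bool tip;
  int nmin;         // length of the minimizer list it spells
};

struct Graph {
  int kprime;
  double d;
  int n;
  std::vector<ivec> tuples;
  ivec abund;
  std::vector<char> tip, alive, palin;
  std::vector<std::vector<int>> out; // size 2n, sorted vectors

  static bool is_palin(const ivec &t) {
    ivec r(t.rbegin(), t.rend());
    return t == r;
  }

  void init_nodes(const List &tuples_, const IntegerVector &abund_,
                  const LogicalVector &tip_, int kp, double dd) {
    kprime = kp; d = dd;
    n = tuples_.size();
    tuples.resize(n); abund.resize(n);
    tip.resize(n); alive.assign(n, 1); palin.resize(n);
    for (int i = 0; i < n; ++i) {
      tuples[i] = as<ivec>(tuples_[i]);
      abund[i] = abund_[i];
      tip[i] = tip_.size() ? (char)(tip_[i] == TRUE) : 0;
      palin[i] = is_palin(tuples[i]);
    }
    out.assign(2 * n, {});
  }

  ivec oriented_seq(int v) const {
    const ivec &t = tuples[v >> 1];
    if ((v & 1) == 0) return t;
    return ivec(t.rbegin(), t.rend());
  }

  void build_edges() {
    // index (k'-1)-prefixes of all oriented vertices
    std::unordered_map<std::string, ivec> pref;
    auto key = [](const ivec &w, int from, int len) {
      std::string s; char buf[16];
      for (int i = 0; i < len; ++i) {
        if (i) s.push_back(',');
        snprintf(buf, sizeof(buf), "%d", w[from + i]);
        s += buf;
      }
      return s;
    };
    for (int node = 0; node < n; ++node) {
      for (int o = 0; o < 2; ++o) {
        ivec s = oriented_seq(2 * node + o);
        pref[key(s, 0, kprime - 1)].push_back(2 * node + o);
      }
    }
    std::set<std::pair<int, int>> eset;
    for (int node = 0; node < n; ++node) {
      for (int o = 0; o < 2; ++o) {
        int v = 2 * node + o;
        ivec s = oriented_seq(v);
        auto it = pref.find(key(s, 1, kprime - 1));
        if (it == pref.end()) continue;
        for (int u : it->second) eset.insert({v, u});
      }
    }
    for (auto &e : eset) out[e.first].push_back(e.second);
    for (auto &a : out) std::sort(a.begin(), a.end());
  }

  void add_directed(int v, int w) {
    auto &a = out[v];
    auto it = std::lower_bound(a.begin(), a.end(), w);
    if (it == a.end() || *it != w) a.insert(it, w);
  }
  void del_directed(int v, int w) {
    auto &a = out[v];
    auto it = std::lower_bound(a.begin(), a.end(), w);
    if (it != a.end() && *it == w) a.erase(it);
  }
  void remove_edge(int v, int w) {
    del_directed(v, w);
    if (w != (v ^ 1)) del_directed(w ^ 1, v ^ 1); // mirror, unless self-mirrored
  }
  int indeg(int v) const { return (int)out[v ^ 1].size(); }
  bool has_self(int node) const {
    for (int o = 0; o < 2; ++o) {
      int v = 2 * node + o;
      for (int u : out[v]) if ((u >> 1) == node) return true;
    }
    return false;
  }
  void kill_node(int node) {
    for (int o = 0; o < 2; ++o) {
      int v = 2 * node + o;
      ivec cp = out[v];
      for (int w : cp) remove_edge(v, w);
    }
    alive[node] = 0;
  }

  // ---- compaction -------------------------------------------------------
  std::vector<Unitig> compact() const {
    std::vector<char> visited(n, 0);
    std::vector<Unitig> units;
    auto extend = [&](int start, std::vector<int> &acc, bool &circ) {
      int cur = start;
      while (true) {
        if (out[cur].size() != 1) return;
        int nxt = out[cur][0];
        if (!alive[nxt >> 1]) return;
        if (indeg(nxt) != 1) return;
        int nn = nxt >> 1;
        if (nn == (start >> 1)) { if (nxt == start) circ = true; return; }
        if (visited[nn] || palin[nn] || has_self(nn)) return;
        acc.push_back(nxt);
        visited[nn] = 1;
        cur = nxt;
      }
    };
    for (int i = 0; i < n; ++i) {
      if (!alive[i] || visited[i]) continue;
      visited[i] = 1;
      Unitig u;
      u.circular = false;
      if (palin[i] || has_self(i)) {
        u.path = {2 * i};
        for (int w : out[2 * i]) if (w == 2 * i) u.circular = true;
      } else {
        std::vector<int> fwd;
        bool circ = false;
        extend(2 * i, fwd, circ);
        std::vector<int> path;
        if (!circ) {
          std::vector<int> bwd;
          bool c2 = false;
          extend(2 * i + 1, bwd, c2);
          for (auto it = bwd.rbegin(); it != bwd.rend(); ++it)
            path.push_back(*it ^ 1);
        }
        path.push_back(2 * i);
        path.insert(path.end(), fwd.begin(), fwd.end());
        u.path = path;
        u.circular = circ;
      }
      normalize(u);
      std::vector<int> abs_;
      u.tip = false;
      for (int v : u.path) {
        abs_.push_back(abund[v >> 1]);
        if (tip[v >> 1]) u.tip = true;
      }
      u.abundance = lower_median_i(abs_);
      int len = (int)u.path.size();
      u.nmin = u.circular ? len : kprime + len - 1;
      units.push_back(std::move(u));
    }
    return units;
  }

  // canonical representation of a unitig path, for deterministic output
  void normalize(Unitig &u) const {
    auto mirror_rev = [](const ivec &p) {
      ivec m(p.rbegin(), p.rend());
      for (auto &v : m) v ^= 1;
      return m;
    };
    if (!u.circular) {
      ivec alt = mirror_rev(u.path);
      if (alt < u.path) u.path = alt;
    } else {
      ivec best = u.path;
      for (const ivec &base : {u.path, mirror_rev(u.path)}) {
        int len = (int)base.size();
        for (int r = 0; r < len; ++r) {
          ivec rot(base.begin() + r, base.end());
          rot.insert(rot.end(), base.begin(), base.begin() + r);
          if (rot < best) best = rot;
        }
      }
      u.path = best;
    }
  }

  double est_len_bp(const Unitig &u) const { return u.nmin / d; }

  // ---- tip clipping -----------------------------------------------------
  int clip_tips(double cap_bp) {
    std::vector<Unitig> units = compact();
    int clipped = 0;
    for (auto &u : units) {
      if (u.circular) continue;
      if (est_len_bp(u) > cap_bp) continue;
      int f = u.path.front(), b = u.path.back();
      int din = indeg(f), dout = (int)out[b].size();
      bool front_dead = (din == 0), back_dead = (dout == 0);
      if (front_dead == back_dead) continue; // isolated or internal
      if (!front_dead) {
        ivec cp = out[f ^ 1];
        for (int m : cp) remove_edge(f ^ 1, m);
      }
      if (!back_dead) {
        ivec cp = out[b];
        for (int m : cp) remove_edge(b, m);
      }
      for (int v : u.path) tip[v >> 1] = 1;
      ++clipped;
    }
    return clipped;
  }

  // ---- superbubbles -----------------------------------------------------
  // Minimal superbubble with source s (standard stack-based detection);
  // search aborted beyond the node-count proxy for the bp cap.
  bool detect_superbubble(int s, int cap_nodes, std::vector<int> &W,
                          int &t_out) const {
    if (out[s].empty()) return false;
    std::map<int, char> state; // 1 = seen, 2 = visited
    std::vector<int> stack{s};
    state[s] = 1;
    int seen_not_visited = 1, visited_cnt = 0;
    while (!stack.empty()) {
      int v = stack.back();
      stack.pop_back();
      if (state[v] == 1) --seen_not_visited;
      state[v] = 2;
      if (++visited_cnt > cap_nodes) return false;
      if (out[v].empty()) return false; // abort: tip inside
      for (int u : out[v]) {
        if (u == s) return false; // cycle through the source
        if ((u >> 1) == (s >> 1)) return false;
        auto it = state.find(u);
        if (it == state.end()) { state[u] = 1; ++seen_not_visited; }
        bool allpar = true;
        for (int m : out[u ^ 1]) {
          int p = m ^ 1;
          auto ip = state.find(p);
          if (ip == state.end() || ip->second != 2) { allpar = false; break; }
        }
        if (allpar) stack.push_back(u);
      }
      if (stack.size() == 1 && seen_not_visited == 1 &&
          state[stack[0]] == 1) {
        int t = stack[0];
        // direct edge t -> s would make it a cycle, not a bubble
        for (int u : out[t]) if (u == s) return false;
        // orientation-consistency: no node in both orientations
        std::set<int> nodes;
        for (auto &kv : state) {
          int node = kv.first >> 1;
          if (nodes.count(node)) return false;
          nodes.insert(node);
        }
        W.clear();
        for (auto &kv : state) W.push_back(kv.first);
        t_out = t;
        return true;
      }
    }
    return false;
  }

  // enumerate s->t paths inside W; returns false if more than cap paths
  bool enum_paths(int s, int t, const std::set<int> &W, int cap,
                  std::vector<ivec> &paths) const {
    ivec cur{s};
    bool ok = true;
    std::function<void(int)> dfs = [&](int v) {
      if (!ok) return;
      if (v == t) {
        paths.push_back(cur);
        if ((int)paths.size() > cap) ok = false;
        return;
      }
      for (int u : out[v]) {
        if (!W.count(u)) continue;
        cur.push_back(u);
        dfs(u);
        cur.pop_back();
      }
    };
    dfs(s);
    return ok;
  }

  // bottleneck (max-min abundance) path fallback for very dense bubbles
  ivec bottleneck_path(int s, int t, const std::set<int> &W) const {
    std::map<int, int> best; // vertex -> bottleneck value
    std::map<int, int> prev;
    for (int v : W) best[v] = -1;
    best[s] = abund[s >> 1];
    // simple Dijkstra-like relaxation on max-min
    std::set<std::pair<int, int>, std::greater<std::pair<int, int>>> q;
    q.insert({best[s], s});
    while (!q.empty()) {
      auto [bv, v] = *q.begin();
      q.erase(q.begin());
      if (bv < best[v]) continue;
      for (int u : out[v]) {
        if (!best.count(u)) continue;
        int cand = std::min(bv, abund[u >> 1]);
        if (cand > best[u]) {
          q.erase({best[u], u});
          best[u] = cand;
          prev[u] = v;
          q.insert({cand, u});
        }
      }
    }
    ivec path;
    int v = t;
    while (true) {
      path.push_back(v);
      if (v == s) break;
      v = prev.at(v);
    }
    std::reverse(path.begin(), path.end());
    return path;
  }

  static std::pair<int, ivec> path_rank(const ivec &p, const ivec &ab) {
    std::vector<int> a;
    for (int v : p) a.push_back(ab[v >> 1]);
    return {lower_median_i(a), p};
  }

  int pop_superbubbles(double cap_bp) {
    int cap_nodes = std::max(3, (int)std::ceil(cap_bp * d));
    int popped = 0;
    bool changed = true;
    int guard = 0;
    while (changed && guard++ < 10000) {
      changed = false;
      for (int node = 0; node < n && !changed; ++node) {
        if (!alive[node]) continue;
        for (int o = 0; o < 2 && !changed; ++o) {
          int s = 2 * node + o;
          // a minimal superbubble with a non-empty interior branches at its
          // source, so sources with out-degree < 2 need no search
          if (out[s].size() < 2) continue;
          std::vector<int> Wv;
          int t = -1;
          if (!detect_superbubble(s, cap_nodes, Wv, t)) continue;
          std::set<int> W(Wv.begin(), Wv.end());
          if ((int)W.size() <= 2) continue; // no interior
          std::vector<ivec> paths;
          ivec bestp;
          if (enum_paths(s, t, W, 4096, paths) && !paths.empty()) {
            int best_med = INT_MIN;
            for (auto &p : paths) {
              auto r = path_rank(p, abund);
              if (r.first > best_med ||
                  (r.first == best_med && node_key_less(p, bestp))) {
                best_med = r.first;
                bestp = p;
              }
            }
          } else {
            bestp = bottleneck_path(s, t, W);
          }
          std::set<int> keep_nodes;
          for (int v : bestp) keep_nodes.insert(v >> 1);
          keep_nodes.insert(s >> 1);
          keep_nodes.insert(t >> 1);
          std::vector<int> to_kill;
          for (int v : W) {
            int nd = v >> 1;
            if (!keep_nodes.count(nd)) to_kill.push_back(nd);
          }
          if (to_kill.empty()) continue;
          for (int nd : to_kill) kill_node(nd);
          popped++;
          changed = true;
        }
      }
    }
    return popped;
  }

  bool node_key_less(const ivec &a, const ivec &b) const {
    if (b.empty()) return true;
    // compare by the sequences of node tuples along the paths
    std::vector<int> fa, fb;
    for (int v : a) {
      ivec s = oriented_seq(v);
      fa.insert(fa.end(), s.begin(), s.end());
    }
    for (int v : b) {
      ivec s = oriented_seq(v);
      fb.insert(fb.end(), s.begin(), s.end());
    }
    return fa < fb;
  }

  // ---- export helpers ---------------------------------------------------
  IntegerMatrix edges_matrix() const {
    std::set<std::array<int, 4>> rows;
    for (int v = 0; v < 2 * n; ++v) {
      for (int w : out[v]) {
        std::array<int, 4> a = {v >> 1, v & 1, w >> 1, w & 1};
        std::array<int, 4> m = {(w ^ 1) >> 1, (w ^ 1) & 1, (v ^ 1) >> 1,
                                (v ^ 1) & 1};
        rows.insert(std::min(a, m));
      }
    }
    IntegerMatrix em((int)rows.size(), 4);
    int i = 0;
    for (auto &r : rows) {
      em(i, 0) = r[0] + 1;          // from node, 1-based
      em(i, 1) = r[1] == 0 ? 1 : 0; // from_fwd
      em(i, 2) = r[2] + 1;          // to node
      em(i, 3) = r[3] == 0 ? 1 : 0; // to_fwd
      ++i;
    }
    return em;
  }

  void load_edges(const IntegerMatrix &em) {
    std::set<std::pair<int, int>> eset;
    for (int i = 0; i < em.nrow(); ++i) {
      int v = 2 * (em(i, 0) - 1) + (em(i, 1) == 1 ? 0 : 1);
      int w = 2 * (em(i, 2) - 1) + (em(i, 3) == 1 ? 0 : 1);
      eset.insert({v, w});
      eset.insert({w ^ 1, v ^ 1});
    }
    for (auto &e : eset) out[e.first].push_back(e.second);
    for (auto &a : out) std::sort(a.begin(), a.end());
  }
};

static Graph graph_from_list(const List &g) {
  Graph G;
  G.init_nodes(g["tuples"], g["abundance"],
               g.containsElementNamed("tip") ? g["tip"] : LogicalVector(0),
               as<int>(g["kprime"]), as<double>(g["d"]));
  G.load_edges(as<IntegerMatrix>(g["edges"]));
  return G;
}

// the minimizer list spelled by a unitig: all k' minimizers of the first
// oriented node plus the last minimizer of each subsequent node (for a
// circular unitig, the last minimizer of every node along the cycle)
static ivec spell_unitig(const Graph &G, const Unitig &u) {
  ivec out;
  out.reserve(u.nmin);
  if (u.circular) {
    for (int v : u.path) {
      ivec s = G.oriented_seq(v);
      out.push_back(s.back());
    }
  } else {
    ivec first = G.oriented_seq(u.path[0]);
    out = first;
    for (size_t j = 1; j < u.path.size(); ++j) {
      ivec s = G.oriented_seq(u.path[j]);
      out.push_back(s.back());
    }
  }
  return out;
}

static List units_to_list(const std::vector<Unitig> &units, const Graph &G) {
  int m = (int)units.size();
  List paths(m), spells(m);
  IntegerVector ab(m), nmin(m);
  LogicalVector circ(m), tip(m);
  NumericVector est(m);
  CharacterVector skey(m);
  for (int i = 0; i < m; ++i) {
    const Unitig &u = units[i];
    IntegerVector p((int)u.path.size());
    for (int j = 0; j < (int)u.path.size(); ++j) {
      int node = (u.path[j] >> 1) + 1;
      p[j] = (u.path[j] & 1) == 0 ? node : -node;
    }
    paths[i] = p;
    ab[i] = u.abundance;
    circ[i] = u.circular;
    tip[i] = u.tip;
    nmin[i] = u.nmin;
    est[i] = u.nmin / G.d;
    ivec sp = spell_unitig(G, u);
    spells[i] = wrap(sp);
    std::string key;
    char buf[16];
    key.reserve(sp.size() * 7);
    for (size_t j = 0; j < sp.size(); ++j) {
      if (j) key.push_back(',');
      snprintf(buf, sizeof(buf), "%d", sp[j]);
      key += buf;
    }
    skey[i] = key;
  }
  return List::create(_["path"] = paths, _["abundance"] = ab,
                      _["is_circular"] = circ, _["tip_derived"] = tip,
                      _["n_minimizers"] = nmin, _["est_len_bp"] = est,
                      _["spell"] = spells, _["skey"] = skey);
}

// [[Rcpp::export]]
List cpp_build_edges(List tuples, IntegerVector abundance, int kprime,
                     double d) {
  Graph G;
  G.init_nodes(tuples, abundance, LogicalVector(0), kprime, d);
  G.build_edges();
  return List::create(_["edges"] = G.edges_matrix());
}

// [[Rcpp::export]]
List cpp_compact(List graph) {
  Graph G = graph_from_list(graph);
  return units_to_list(G.compact(), G);
}

// [[Rcpp::export]]
List cpp_clip_tips(List graph, double cap_bp) {
  Graph G = graph_from_list(graph);
  int clipped = G.clip_tips(cap_bp);
  LogicalVector tip(G.n);
  for (int i = 0; i < G.n; ++i) tip[i] = G.tip[i] != 0;
  return List::create(_["edges"] = G.edges_matrix(), _["tip"] = tip,
                      _["n_clipped"] = clipped);
}

// [[Rcpp::export]]
List cpp_pop_superbubbles(List graph, double cap_bp) {
  Graph G = graph_from_list(graph);
  int popped = G.pop_superbubbles(cap_bp);
  LogicalVector keep(G.n);
  for (int i = 0; i < G.n; ++i) keep[i] = G.alive[i] != 0;
  return List::create(_["edges"] = G.edges_matrix(), _["keep"] = keep,
                      _["n_popped"] = popped);
}

// Algorithm: iterate t = 1..t_max; simplify (tips + bubbles), compact,
// snapshot the unitig set S_t, then drop unitigs with abundance <= t.
// t_max is the abundance of the most abundant unitig of the initial graph.
// [[Rcpp::export]]
List cpp_progressive_filter(List graph, double tip_cap_bp,
                            double bubble_cap_bp, int t_max_override) {
  Graph G = graph_from_list(graph);
  std::vector<Unitig> init = G.compact();
  if (init.empty()) return List::create();
  int t_max = 0;
  for (auto &u : init) t_max = std::max(t_max, u.abundance);
  if (t_max_override > 0) t_max = t_max_override;
  if (t_max > 100000) stop("implausible unitig abundance");
  std::vector<List> snaps;
  for (int t = 1; t <= t_max; ++t) {
    G.clip_tips(tip_cap_bp);
    G.pop_superbubbles(bubble_cap_bp);
    std::vector<Unitig> units = G.compact();
    snaps.push_back(units_to_list(units, G));
    for (auto &u : units) {
      if (u.abundance <= t)
        for (int v : u.path) if (G.alive[v >> 1]) G.kill_node(v >> 1);
    }
    bool any = false;
    for (int i = 0; i < G.n; ++i) if (G.alive[i]) { any = true; break; }
    if (!any) break;
  }
  List out(snaps.size());
  for (size_t i = 0; i < snaps.size(); ++i) out[i] = snaps[i];
  return out;
}
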