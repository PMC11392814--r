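// k'-min-mer extraction, canonicalization, counting, and the abundance
// lifecycle helpers (initial read-local filter, smoothing/rescue,
// propagation to the next k').
#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <string>
#include <vector>
using namespace Rcpp;

typedef std::vector<int> ivec;

// canonical form: compare the window with its reversal element-wise; the one
// whose first differing element is smaller wins; full equality -> forward.
static bool reversed_is_smaller(const ivec &w) {
  int n = (int)w.size();
  for (int i = 0; i < n; ++i) {
    int a = w[i], b = w[n - 1 - i];
    if (a < b) return false;
    if (b < a) return true;
  }
  return false; // palindromic: keep forward
}

static ivec canon_tuple(const ivec &w, bool *rev = nullptr) {
  if (reversed_is_smaller(w)) {
    if (rev) *rev = true;
    return ivec(w.rbegin(), w.rend());
  }
  if (rev) *rev = false;
  return w;
}

static std::string key_of(const ivec &w) {
  std::string s;
  s.reserve(w.size() * 7);
  char buf[16];
  for (size_t i = 0; i < w.size(); ++i) {
    if (i) s.push_back(',');
    snprintf(buf, sizeof(buf), "%d", w[i]);
    s += buf;
  }
  return s;
}

// windows of a minimizer sequence; cyclic (wrap-around) if circular
static void each_window(const ivec &v, bool circular, int kp,
                        const std::function<void(const ivec &)> &fn) {
  int n = (int)v.size();
  if (n < kp) return;
  if (circular) {
    for (int j = 0; j < n; ++j) {
      ivec w(kp);
      for (int u = 0; u < kp; ++u) w[u] = v[(j + u) % n];
      fn(w);
    }
  } else {
    for (int j = 0; j + kp <= n; ++j) {
      ivec w(v.begin() + j, v.begin() + j + kp);
      fn(w);
    }
  }
}

static int lower_median(std::vector<int> x) {
  if (x.empty()) return 0;
  std::sort(x.begin(), x.end());
  return x[(x.size() - 1) / 2];
}

// [[Rcpp::export]]
List cpp_canonicalize_kminmer(IntegerVector window) {
  ivec w = as<ivec>(window);
  bool rev = false;
  ivec c = canon_tuple(w, &rev);
  return List::create(_["mins"] = wrap(c), _["is_reversed"] = rev);
}

struct CountTab {
  std::unordered_map<std::string, int> idx;
  std::vector<ivec> tuples;
  std::vector<long> counts;
  int add(const ivec &canon, const std::string &key, long by) {
    auto it = idx.find(key);
    if (it == idx.end()) {
      int i = (int)tuples.size();
      idx.emplace(key, i);
      tuples.push_back(canon);
      counts.push_back(by);
      return i;
    }
    counts[it->second] += by;
    return it->second;
  }
};

static List tab_to_list(CountTab &tab) {
  // deterministic order: sort by key string (C locale)
  int n = (int)tab.tuples.size();
  std::vector<std::pair<std::string, int>> ord;
  ord.reserve(n);
  for (auto &kv : tab.idx) ord.push_back({kv.first, kv.second});
  std::sort(ord.begin(), ord.end());
  CharacterVector keys(n);
  IntegerVector counts(n);
  List tuples(n);
  for (int i = 0; i < n; ++i) {
    keys[i] = ord[i].first;
    counts[i] = (int)std::min<long>(tab.counts[ord[i].second], INT_MAX);
    tuples[i] = wrap(tab.tuples[ord[i].second]);
  }
  return List::create(_["keys"] = keys, _["abundance"] = counts,
                      _["tuples"] = tuples);
}

// [[Rcpp::export]]
List cpp_count_kminmers(List seqs, LogicalVector circular, int kprime) {
  CountTab tab;
  int ns = seqs.size();
  for (int i = 0; i < ns; ++i) {
    ivec v = as<ivec>(seqs[i]);
    bool circ = circular[i];
    each_window(v, circ, kprime, [&](const ivec &w) {
      ivec c = canon_tuple(w);
      tab.add(c, key_of(c), 1);
    });
  }
  return tab_to_list(tab);
}

// [[Rcpp::export]]
CharacterVector cpp_window_keys(IntegerVector seq, bool circular, int kprime) {
  ivec v = as<ivec>(seq);
  std::vector<std::string> out;
  each_window(v, circular, kprime, [&](const ivec &w) {
    out.push_back(key_of(canon_tuple(w)));
  });
  return wrap(out);
}

// Read-local initial filter: all R_cov values are computed before any
// removal, so the result is order-independent. Returns a keep mask over the
// table rows plus the per-read coverage medians.
// [[Rcpp::export]]
List cpp_initial_filter(List seqs, LogicalVector circular, int kprime,
                        CharacterVector keys, IntegerVector abundance,
                        double beta_err) {
  std::unordered_map<std::string, int> idx;
  for (int i = 0; i < keys.size(); ++i)
    idx.emplace(as<std::string>(keys[i]), i);
  std::vector<bool> discard(keys.size(), false);
  int ns = seqs.size();
  NumericVector rcov(ns);
  for (int i = 0; i < ns; ++i) {
    ivec v = as<ivec>(seqs[i]);
    std::vector<int> rows, abs_;
    each_window(v, circular[i], kprime, [&](const ivec &w) {
      auto it = idx.find(key_of(canon_tuple(w)));
      if (it != idx.end()) {
        rows.push_back(it->second);
        abs_.push_back(abundance[it->second]);
      }
    });
    if (rows.empty()) { rcov[i] = NA_REAL; continue; }
    int med = lower_median(abs_);
    rcov[i] = med;
    double rmin = med * beta_err;
    for (size_t j = 0; j < rows.size(); ++j)
      if (abs_[j] == 1 && 1.0 < rmin) discard[rows[j]] = true;
  }
  LogicalVector keep(keys.size());
  for (int i = 0; i < keys.size(); ++i) keep[i] = !discard[i];
  return List::create(_["keep"] = keep, _["read_cov"] = rcov);
}

// Smoothing + rescue over a set of node-disjoint mContigs.
// [[Rcpp::export]]
IntegerVector cpp_smooth_rescue(List mcontig_seqs, LogicalVector circular,
                                int kprime, CharacterVector keys,
                                IntegerVector abundance) {
  std::unordered_map<std::string, int> idx;
  for (int i = 0; i < keys.size(); ++i)
    idx.emplace(as<std::string>(keys[i]), i);
  IntegerVector out = clone(abundance);
  int ns = mcontig_seqs.size();
  for (int i = 0; i < ns; ++i) {
    ivec v = as<ivec>(mcontig_seqs[i]);
    std::vector<int> rows, abs_;
    each_window(v, circular[i], kprime, [&](const ivec &w) {
      auto it = idx.find(key_of(canon_tuple(w)));
      if (it != idx.end()) {
        rows.push_back(it->second);
        abs_.push_back(out[it->second]);
      }
    });
    if (rows.empty()) continue;
    int ccov = lower_median(abs_);
    for (int r : rows) out[r] = ccov;
    if ((int)rows.size() > 2 * kprime)
      for (int r : rows) if (out[r] == 1) out[r] = 2;
  }
  return out;
}

// Propagate refined (k'-1) abundances to the distinct k'-min-mers present in
// the given sequences; k'-min-mers whose parents are missing, or whose
// propagated abundance is 1, are dropped.
// [[Rcpp::export]]
List cpp_propagate(List seqs, LogicalVector circular, int kprime,
                   CharacterVector prev_keys, IntegerVector prev_abundance) {
  std::unordered_map<std::string, int> prev;
  for (int i = 0; i < prev_keys.size(); ++i)
    prev.emplace(as<std::string>(prev_keys[i]), prev_abundance[i]);
  CountTab tab; // abundance stored directly in counts
  std::unordered_map<std::string, bool> seen;
  long n_dropped = 0;
  int ns = seqs.size();
  for (int i = 0; i < ns; ++i) {
    ivec v = as<ivec>(seqs[i]);
    each_window(v, circular[i], kprime, [&](const ivec &w) {
      ivec c = canon_tuple(w);
      std::string key = key_of(c);
      if (seen.count(key)) return;
      seen.emplace(key, true);
      ivec pre(c.begin(), c.end() - 1), suf(c.begin() + 1, c.end());
      auto ip = prev.find(key_of(canon_tuple(pre)));
      auto is = prev.find(key_of(canon_tuple(suf)));
      if (ip == prev.end() || is == prev.end()) { ++n_dropped; return; }
      int ab = std::min(ip->second, is->second);
      if (ab <= 1) { ++n_dropped; return; }
      tab.add(c, key, ab);
    });
  }
  List out = tab_to_list(tab);
  out["n_dropped"] = (double)n_dropped;
  return out;
}
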