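// Banded pairwise alignment (unit-cost edit distance with traceback) and the
// per-window majority consensus used for contig polishing.
#include <Rcpp.h>
#include <algorithm>
#include <climits>
#include <map>
#include <string>
#include <vector>
using namespace Rcpp;

static const int BIG = INT_MAX / 4;

struct AlnResult {
  int edits, matches, alen;
  int b_start, b_end; // aligned span of b (0-based, half-open) for fitting
  // per-a-position decoding used by the consensus: for row i (1-based a pos)
  // aligned char from b or '-'; insertions collected after a-position i
  std::vector<char> col;            // size |a|
  std::vector<std::string> ins;     // size |a|+1, ins[i] = inserted before a pos i+1
};

// Align a (rows) against b (cols). If fit_b, gaps at both ends of b are free
// (a must be fully aligned, i.e. a "fitting" alignment of a inside b).
static bool banded_align(const std::string &a, const std::string &b, int band,
                         bool fit_b, bool want_cols, AlnResult &res) {
  int n = (int)a.size(), m = (int)b.size();
  int lo = std::min(0, m - n) - band;
  int hi = std::max(0, m - n) + band;
  if (fit_b) { lo = -band; hi = std::max(0, m - n) + band; }
  int W = hi - lo + 1;
  if (W <= 0) return false;
  if ((double)(n + 1) * W > 1.6e8) return false; // refuse absurd DP sizes
  std::vector<int> D((size_t)(n + 1) * W, BIG);
  auto at = [&](int i, int j) -> int & {
    return D[(size_t)i * W + (j - i - lo)];
  };
  auto inband = [&](int i, int j) {
    int k = j - i;
    return j >= 0 && j <= m && k >= lo && k <= hi;
  };
  for (int j = 0; j <= m; ++j)
    if (inband(0, j)) at(0, j) = fit_b ? 0 : j;
  for (int i = 1; i <= n; ++i) {
    int *cur = &D[(size_t)i * W];
    const int *prev = &D[(size_t)(i - 1) * W];
    const char ai = a[i - 1];
    int kmin = std::max(lo, -i);
    int kmax = std::min(hi, m - i);
    for (int k = kmin; k <= kmax; ++k) {
      int j = i + k;
      int bestv = BIG;
      if (j > 0) {
        // diagonal: (i-1, j-1) has the same offset k
        int c = prev[k - lo] + (ai == b[j - 1] ? 0 : 1);
        if (c < bestv) bestv = c;
        // left: (i, j-1) has offset k-1
        if (k - 1 >= lo && cur[k - 1 - lo] + 1 < bestv)
          bestv = cur[k - 1 - lo] + 1;
      }
      // up: (i-1, j) has offset k+1
      if (k + 1 <= hi && prev[k + 1 - lo] + 1 < bestv)
        bestv = prev[k + 1 - lo] + 1;
      cur[k - lo] = bestv;
    }
  }
  // terminal cell
  int jend = m, best = BIG;
  if (fit_b) {
    for (int j = 0; j <= m; ++j)
      if (inband(n, j) && at(n, j) < best) { best = at(n, j); jend = j; }
  } else {
    if (!inband(n, m)) return false;
    best = at(n, m);
  }
  if (best >= BIG) return false;

  // traceback
  int i = n, j = jend;
  int matches = 0, alen = 0, edits = best;
  if (want_cols) {
    res.col.assign(n, '-');
    res.ins.assign(n + 1, "");
  }
  while (i > 0 || (j > 0 && !fit_b)) {
    if (i > 0 && j > 0 && inband(i - 1, j - 1) &&
        at(i, j) == at(i - 1, j - 1) + (a[i - 1] == b[j - 1] ? 0 : 1)) {
      if (a[i - 1] == b[j - 1]) ++matches;
      if (want_cols) res.col[i - 1] = b[j - 1];
      --i; --j; ++alen;
    } else if (i > 0 && inband(i - 1, j) && at(i, j) == at(i - 1, j) + 1) {
      if (want_cols) res.col[i - 1] = '-';
      --i; ++alen;
    } else if (j > 0 && inband(i, j - 1) && at(i, j) == at(i, j - 1) + 1) {
      if (want_cols) res.ins[i] = b[j - 1] + res.ins[i];
      --j; ++alen;
    } else {
      return false; // should not happen
    }
  }
  res.b_start = j;
  res.b_end = jend;
  if (fit_b && want_cols) res.ins[0].clear(); // overhangs are not insertions
  res.edits = edits;
  res.matches = matches;
  res.alen = alen;
  return true;
}

// [[Rcpp::export]]
List cpp_banded_align(std::string a, std::string b, int band, bool fit_b) {
  AlnResult r;
  int bd = std::max(band, 8);
  bool ok = false;
  for (int attempt = 0; attempt < 4 && !ok; ++attempt, bd *= 2)
    ok = banded_align(a, b, bd, fit_b, false, r);
  if (!ok)
    return List::create(_["ok"] = false);
  return List::create(
      _["ok"] = true, _["edits"] = r.edits, _["matches"] = r.matches,
      _["align_len"] = r.alen,
      _["identity"] = r.alen > 0 ? (double)r.matches / r.alen : 0.0,
      _["b_start"] = r.b_start, _["b_end"] = r.b_end);
}

// Majority consensus of a 500-nt (or shorter) window from read fragments.
// The window arrives with short flanks on each side (trim_left/trim_right
// columns) so that variants adjacent to window junctions are interior to
// the alignment; the emitted consensus covers only the core columns, plus
// the insertion junctions after each core column (including the trailing
// one, so every window junction is voted on by exactly one window). Each
// fragment is fit-aligned to the extended window; per-column votes (base or
// deletion) and per-junction insertion votes are tallied. Ties keep the
// window's own base; insertions require a strict majority of fragments.
// [[Rcpp::export]]
std::string cpp_window_consensus(std::string window, CharacterVector fragments,
                                 int band, int trim_left = 0,
                                 int trim_right = 0) {
  int n = (int)window.size();
  int nf = fragments.size();
  int core_lo = trim_left, core_hi = n - trim_right; // core cols (0-based)
  std::string core = window.substr(core_lo, core_hi - core_lo);
  if (nf == 0 || n == 0 || core_hi <= core_lo) return core;
  std::vector<std::map<char, int>> votes(n);
  std::vector<std::map<std::string, int>> ins(n + 1);
  int used = 0;
  for (int f = 0; f < nf; ++f) {
    std::string frag = as<std::string>(fragments[f]);
    if ((int)frag.size() == 0) continue;
    AlnResult r;
    if (!banded_align(window, frag, band, true, true, r)) continue;
    ++used;
    for (int i = 0; i < n; ++i) votes[i][r.col[i]]++;
    for (int i = 0; i <= n; ++i) if (!r.ins[i].empty()) ins[i][r.ins[i]]++;
  }
  if (used == 0) return core;
  std::string out;
  out.reserve(core.size() + 8);
  for (int i = core_lo; i < core_hi; ++i) {
    // column i: majority base or deletion; ties keep the draft base
    char bestc = window[i];
    int bestv = votes[i].count(bestc) ? votes[i][bestc] : 0;
    for (auto &kv : votes[i])
      if (kv.second > bestv) { bestv = kv.second; bestc = kv.first; }
    if (bestc != '-') out.push_back(bestc);
    // insertion junction after column i
    if (!ins[i + 1].empty()) {
      std::string bests;
      int bestv2 = 0;
      for (auto &kv : ins[i + 1])
        if (kv.second > bestv2 ||
            (kv.second == bestv2 && kv.first < bests)) {
          bestv2 = kv.second;
          bests = kv.first;
        }
      if (2 * bestv2 > used) out += bests;
    }
  }
  return out;
}
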