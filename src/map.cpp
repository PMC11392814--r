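// Minimizer-space mapping of mReads onto mContigs: seed on shared raw
// k'-min-mer windows, extend maximal runs of consecutive matches, and keep,
// for every contig window position, the match with the longest run.
#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

typedef std::vector<int> ivec;

static std::string raw_key(const ivec &v, int from, int kp, int n, bool circ) {
  std::string s;
  char buf[16];
  for (int u = 0; u < kp; ++u) {
    int idx = circ ? (from + u) % n : from + u;
    if (u) s.push_back(',');
    snprintf(buf, sizeof(buf), "%d", v[idx]);
    s += buf;
  }
  return s;
}

// [[Rcpp::export]]
List cpp_map_to_contigs(List read_seqs, IntegerVector read_len,
                        List contig_seqs, LogicalVector contig_circ,
                        int kprime) {
  int nc = contig_seqs.size(), nr = read_seqs.size();
  std::vector<ivec> contigs(nc);
  std::vector<int> npos(nc);
  std::unordered_map<std::string, std::vector<std::pair<int, int>>> index;
  for (int c = 0; c < nc; ++c) {
    contigs[c] = as<ivec>(contig_seqs[c]);
    int n = (int)contigs[c].size();
    bool circ = contig_circ[c];
    npos[c] = (n < kprime) ? 0 : (circ ? n : n - kprime + 1);
    for (int p = 0; p < npos[c]; ++p)
      index[raw_key(contigs[c], p, kprime, n, circ)].push_back({c, p});
  }

  // best match per contig window: m, read_len, read, ori, rpos
  std::vector<std::vector<std::array<int, 5>>> best(nc);
  for (int c = 0; c < nc; ++c)
    best[c].assign(npos[c], {0, 0, 0, 0, 0});

  struct Run { int read, ori, c, p0, j0, len; };
  std::vector<Run> runs;

  for (int r = 0; r < nr; ++r) {
    ivec fwd = as<ivec>(read_seqs[r]);
    for (int ori = 0; ori < 2; ++ori) {
      ivec v = fwd;
      if (ori == 1) std::reverse(v.begin(), v.end());
      int n = (int)v.size();
      int nw = n - kprime + 1;
      if (nw <= 0) continue;
      // active runs keyed by (c, p) of the window matched at j-1
      std::unordered_map<uint64_t, int> prev_map, cur_map;
      std::vector<Run> local;
      for (int j = 0; j < nw; ++j) {
        std::string key = raw_key(v, j, kprime, n, false);
        auto it = index.find(key);
        cur_map.clear();
        if (it != index.end()) {
          for (auto &cp : it->second) {
            int c = cp.first, p = cp.second;
            int pprev = (p - 1 + npos[c]) % npos[c];
            uint64_t hprev = ((uint64_t)c << 32) | (uint32_t)pprev;
            auto pit = prev_map.find(hprev);
            int runid;
            if (pit != prev_map.end() && npos[c] > 1) {
              runid = pit->second;
              local[runid].len++;
            } else {
              runid = (int)local.size();
              local.push_back({r + 1, ori, c, p, j, 1});
            }
            cur_map[((uint64_t)c << 32) | (uint32_t)p] = runid;
          }
        }
        std::swap(prev_map, cur_map);
      }
      for (auto &run : local) runs.push_back(run);
    }
  }

  // fill the best-match table
  for (auto &run : runs) {
    int c = run.c;
    int span = std::min(run.len, npos[c]);
    for (int u = 0; u < span; ++u) {
      int cp = (run.p0 + u) % npos[c];
      std::array<int, 5> cand = {run.len, read_len[run.read - 1], run.read,
                                 run.ori, run.j0 + u};
      auto &cur = best[c][cp];
      bool better = false;
      if (cand[0] != cur[0]) better = cand[0] > cur[0];
      else if (cand[1] != cur[1]) better = cand[1] > cur[1];
      else if (cur[2] == 0) better = true;
      else if (cand[2] != cur[2]) better = cand[2] < cur[2];
      else if (cand[3] != cur[3]) better = cand[3] < cur[3];
      else better = cand[4] < cur[4];
      if (cur[2] == 0 || better) cur = cand;
    }
  }

  List best_out(nc);
  for (int c = 0; c < nc; ++c) {
    int np = npos[c];
    IntegerVector m(np), rd(np), ori(np), rpos(np);
    for (int p = 0; p < np; ++p) {
      auto &b = best[c][p];
      if (b[2] == 0) {
        rd[p] = NA_INTEGER; m[p] = 0; ori[p] = NA_INTEGER;
        rpos[p] = NA_INTEGER;
      } else {
        m[p] = b[0]; rd[p] = b[2]; ori[p] = b[3]; rpos[p] = b[4];
      }
    }
    best_out[c] = List::create(_["read"] = rd, _["orient"] = ori,
                               _["rpos"] = rpos, _["m"] = m);
  }
  int nruns = (int)runs.size();
  IntegerMatrix rm(nruns, 6);
  for (int i = 0; i < nruns; ++i) {
    rm(i, 0) = runs[i].read;
    rm(i, 1) = runs[i].ori;
    rm(i, 2) = runs[i].c + 1;
    rm(i, 3) = runs[i].p0;
    rm(i, 4) = runs[i].j0;
    rm(i, 5) = runs[i].len;
  }
  colnames(rm) = CharacterVector::create("read", "orient", "contig", "cpos",
                                         "rpos", "len");
  return List::create(_["best"] = best_out, _["runs"] = rm);
}
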