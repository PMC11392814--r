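// Sequence-level primitives: 2-bit encoding, homopolymer compression,
// seeded 64-bit hashing and universal-minimizer scanning.
#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <vector>
using namespace Rcpp;

static inline int enc_base(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static const char DEC[4] = {'A', 'C', 'G', 'T'};

// splitmix64: deterministic, platform-independent 64-bit mixer.
static inline uint64_t mix64(uint64_t z) {
  z += 0x9E3779B97F4A7C15ULL;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline uint64_t hash_kmer(uint32_t code, uint64_t seed) {
  return mix64(static_cast<uint64_t>(code) ^ (seed * 0x2545F4914F6CDD1DULL));
}

// d * 2^64 as an unsigned threshold; d is in (0,1) so this cannot overflow
// for the values we accept (d <= 0.5 in practice).
static inline uint64_t density_threshold(double d) {
  long double t = (long double)d * 18446744073709551616.0L;
  if (t >= 18446744073709551615.0L) return UINT64_MAX;
  return (uint64_t)t;
}

// canonical encoding: min(code, revcomp-code); numeric order on the 2-bit
// encoding equals lexicographic order on the k-mer string.
static inline uint32_t revcomp_code(uint32_t code, int k) {
  uint32_t rc = 0;
  for (int i = 0; i < k; ++i) {
    rc = (rc << 2) | (3u - (code & 3u));
    code >>= 2;
  }
  return rc;
}

// [[Rcpp::export]]
List cpp_hpc_compress(std::string seq) {
  int n = (int)seq.size();
  std::string out;
  std::vector<int> run_start, run_end;
  out.reserve(n);
  int i = 0;
  while (i < n) {
    char c = (char)toupper(seq[i]);
    int j = i + 1;
    while (j < n && (char)toupper(seq[j]) == c) ++j;
    out.push_back(c);
    run_start.push_back(i);
    run_end.push_back(j);
    i = j;
  }
  return List::create(_["hpc"] = out,
                      _["run_start"] = wrap(run_start),
                      _["run_end"] = wrap(run_end));
}

// [[Rcpp::export]]
CharacterVector cpp_canonical_kmer(CharacterVector kmers) {
  int n = kmers.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(kmers[i]);
    std::string rc(s.size(), 'N');
    bool ok = true;
    for (size_t j = 0; j < s.size(); ++j) {
      int b = enc_base(s[s.size() - 1 - j]);
      if (b < 0) { ok = false; break; }
      rc[j] = DEC[3 - b];
    }
    if (!ok) { out[i] = NA_STRING; continue; }
    std::string up(s);
    for (auto &c : up) c = (char)toupper(c);
    out[i] = (up <= rc) ? up : rc;
  }
  return out;
}

// Hash-based selection test on the canonical form of each k-mer.
// [[Rcpp::export]]
LogicalVector cpp_is_minimizer(CharacterVector kmers, int k, double d,
                               double seed) {
  uint64_t s = (uint64_t)seed;
  uint64_t thr = density_threshold(d);
  int n = kmers.size();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string km = as<std::string>(kmers[i]);
    if ((int)km.size() != k) stop("k-mer length does not match k");
    uint32_t code = 0;
    bool ok = true;
    for (int j = 0; j < k; ++j) {
      int b = enc_base(km[j]);
      if (b < 0) { ok = false; break; }
      code = (code << 2) | (uint32_t)b;
    }
    if (!ok) { out[i] = NA_LOGICAL; continue; }
    uint32_t rc = revcomp_code(code, k);
    uint32_t canon = code < rc ? code : rc;
    out[i] = hash_kmer(canon, s) < thr;
  }
  return out;
}

// Scan a (homopolymer-compressed) sequence; return the canonical 2-bit codes
// and 0-based positions of all k-windows passing the density test. Windows
// containing non-ACGT characters are skipped.
// [[Rcpp::export]]
List cpp_scan_minimizers(std::string seq, int k, double d, double seed) {
  uint64_t sd = (uint64_t)seed;
  uint64_t thr = density_threshold(d);
  int n = (int)seq.size();
  std::vector<int> vals, pos;
  if (n >= k) {
    uint32_t code = 0;
    uint32_t mask = (k >= 16) ? 0xFFFFFFFFu : ((1u << (2 * k)) - 1u);
    int valid = 0; // number of consecutive valid bases ending here
    for (int i = 0; i < n; ++i) {
      int b = enc_base(seq[i]);
      if (b < 0) { valid = 0; code = 0; continue; }
      code = ((code << 2) | (uint32_t)b) & mask;
      ++valid;
      if (valid >= k) {
        uint32_t rc = revcomp_code(code, k);
        uint32_t canon = code < rc ? code : rc;
        if (hash_kmer(canon, sd) < thr) {
          vals.push_back((int)canon);
          pos.push_back(i - k + 1);
        }
      }
    }
  }
  return List::create(_["values"] = wrap(vals), _["pos"] = wrap(pos));
}

// Count k-windows of a sequence passing the density test (with stride),
// without materialising them; used for empirical density estimation.
// [[Rcpp::export]]
IntegerVector cpp_count_selected(std::string seq, int k, double d, double seed,
                                 int stride) {
  uint64_t sd = (uint64_t)seed;
  uint64_t thr = density_threshold(d);
  int n = (int)seq.size();
  long total = 0, hit = 0;
  for (int i = 0; i + k <= n; i += stride) {
    uint32_t code = 0;
    bool ok = true;
    for (int j = 0; j < k; ++j) {
      int b = enc_base(seq[i + j]);
      if (b < 0) { ok = false; break; }
      code = (code << 2) | (uint32_t)b;
    }
    if (!ok) continue;
    uint32_t rc = revcomp_code(code, k);
    uint32_t canon = code < rc ? code : rc;
    ++total;
    if (hash_kmer(canon, sd) < thr) ++hit;
  }
  return IntegerVector::create((int)total, (int)hit);
}

// [[Rcpp::export]]
std::string cpp_revcomp(std::string seq) {
  int n = (int)seq.size();
  std::string out(n, 'N');
  for (int i = 0; i < n; ++i) {
    int b = enc_base(seq[n - 1 - i]);
    out[i] = (b < 0) ? 'N' : DEC[3 - b];
  }
  return out;
}

// Decode a canonical minimizer code back to its k-mer string (debugging aid).
// [[Rcpp::export]]
CharacterVector cpp_decode_kmer(IntegerVector codes, int k) {
  int n = codes.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    uint32_t c = (uint32_t)codes[i];
    std::string s(k, 'A');
    for (int j = k - 1; j >= 0; --j) { s[j] = DEC[c & 3u]; c >>= 2; }
    out[i] = s;
  }
  return out;
}
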