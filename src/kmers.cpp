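// k-mer counting and significance screening over the alphabet {A,C,G,T,N}.
// k-mers with k <= 42 are packed 3 bits/base into an unsigned 128-bit key so
// that multi-million-key tables stay compact; longer k falls back to strings.

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <string>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

typedef unsigned __int128 u128;

struct U128Hash {
  size_t operator()(u128 x) const {
    uint64_t lo = (uint64_t)x, hi = (uint64_t)(x >> 64);
    uint64_t h = lo;
    h ^= hi + 0x9E3779B97F4A7C15ULL + (h << 6) + (h >> 2);
    h ^= h >> 33; h *= 0xFF51AFD7ED558CCDULL; h ^= h >> 33;
    return (size_t)h;
  }
};

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1; case 'G': return 2;
    case 'T': return 3; case 'N': return 4;
  }
  return -1;
}

static const char CODE2BASE[5] = {'A', 'C', 'G', 'T', 'N'};

static const int KMAX_PACKED = 42;

static std::string decode_kmer(u128 code, int k) {
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = CODE2BASE[(int)(code & (u128)7)];
    code >>= 3;
  }
  return s;
}

static void stop_bad_base(char c) {
  stop("read contains a base outside {A,C,G,T,N}: '%c'", c);
}

typedef std::unordered_map<u128, int, U128Hash> PackedCounts;
typedef std::unordered_map<std::string, int> StringCounts;

static void count_reads_packed(const CharacterVector& reads, int k, PackedCounts& tab) {
  const u128 mask = (((u128)1) << (3 * k)) - 1;
  // reserve for the worst case (every window distinct) to avoid rehashing
  // multi-million-entry tables; capped to keep the bucket array bounded
  size_t windows = 0;
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    int len = (int)LENGTH(STRING_ELT(reads, r));
    if (len >= k) windows += (size_t)(len - k + 1);
  }
  tab.reserve(std::min(windows, (size_t)1 << 26));
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    SEXP el = STRING_ELT(reads, r);
    const char* s = CHAR(el);
    int len = (int)LENGTH(el);
    if (len < k) continue;
    u128 code = 0;
    for (int i = 0; i < len; ++i) {
      int b = base_code(s[i]);
      if (b < 0) stop_bad_base(s[i]);
      code = ((code << 3) | (u128)b) & mask;
      if (i >= k - 1) tab[code]++;
    }
  }
}

static void count_reads_string(const CharacterVector& reads, int k, StringCounts& tab) {
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    SEXP el = STRING_ELT(reads, r);
    const char* s = CHAR(el);
    int len = (int)LENGTH(el);
    if (len < k) continue;
    for (int i = 0; i + k <= len; ++i) {
      for (int j = 0; j < k; ++j) if (base_code(s[i + j]) < 0) stop_bad_base(s[i + j]);
      tab[std::string(s + i, k)]++;
    }
  }
}

// Per-sample occurrence counts of every k-mer (sliding window, occurrences
// not reads-containing). Returns an unsorted named integer vector.
// [[Rcpp::export]]
IntegerVector cpp_count_kmers(CharacterVector reads, int k) {
  if (k < 1) stop("k must be a positive integer");
  std::vector<std::string> keys;
  std::vector<int> vals;
  if (k <= KMAX_PACKED) {
    PackedCounts tab;
    count_reads_packed(reads, k, tab);
    keys.reserve(tab.size()); vals.reserve(tab.size());
    for (PackedCounts::const_iterator it = tab.begin(); it != tab.end(); ++it) {
      keys.push_back(decode_kmer(it->first, k));
      vals.push_back(it->second);
    }
  } else {
    StringCounts tab;
    count_reads_string(reads, k, tab);
    for (StringCounts::const_iterator it = tab.begin(); it != tab.end(); ++it) {
      keys.push_back(it->first);
      vals.push_back(it->second);
    }
  }
  IntegerVector out(vals.begin(), vals.end());
  out.names() = wrap(keys);
  return out;
}

// Significance predicate over a count vector: some pair of samples differs by
// >= tau orders of magnitude, with the zero cases handled as printed rules.
static bool significant_counts(const double* c, int n, double tau) {
  if (n < 2) return false;
  bool has_zero = false;
  int nz = 0;
  double lmin = 0, lmax = 0;
  for (int i = 0; i < n; ++i) {
    if (c[i] == 0) { has_zero = true; continue; }
    double l = std::log10(c[i]);
    if (nz == 0) { lmin = lmax = l; }
    else { if (l < lmin) lmin = l; if (l > lmax) lmax = l; }
    ++nz;
  }
  if (nz == 0) return false;
  if (has_zero && lmax >= tau) return true;
  if (nz >= 2 && (lmax - lmin) >= tau) return true;
  return false;
}

// Selects the significant k-mers across all samples without materialising the
// full multi-sample table in R. Two passes: (1) per-sample counting keeps only
// candidate k-mers whose count reaches 10^tau somewhere (a necessary condition
// for every branch of the significance rule); (2) candidates are recounted in
// every sample and the rule is applied.
// [[Rcpp::export]]
CharacterVector cpp_significant_kmers(List sample_reads, int k, double tau) {
  if (k < 1) stop("k must be a positive integer");
  if (!(tau > 0)) stop("tau must be > 0");
  int n = sample_reads.size();
  if (n < 1) stop("at least one sample is required");
  if (k > KMAX_PACKED) stop("the streaming selector supports k <= 42");
  const double thr = std::pow(10.0, tau) - 1e-9;

  std::unordered_set<u128, U128Hash> cand;
  for (int i = 0; i < n; ++i) {
    CharacterVector reads = sample_reads[i];
    PackedCounts tab;
    count_reads_packed(reads, k, tab);
    for (PackedCounts::const_iterator it = tab.begin(); it != tab.end(); ++it)
      if ((double)it->second >= thr) cand.insert(it->first);
    Rcpp::checkUserInterrupt();
  }
  if (cand.empty()) return CharacterVector(0);

  std::unordered_map<u128, int, U128Hash> idx;
  std::vector<u128> keys(cand.begin(), cand.end());
  idx.reserve(keys.size() * 2);
  for (size_t j = 0; j < keys.size(); ++j) idx[keys[j]] = (int)j;
  std::vector<double> counts(keys.size() * (size_t)n, 0.0);

  const u128 mask = (((u128)1) << (3 * k)) - 1;
  for (int i = 0; i < n; ++i) {
    CharacterVector reads = sample_reads[i];
    for (R_xlen_t r = 0; r < reads.size(); ++r) {
      SEXP el = STRING_ELT(reads, r);
      const char* s = CHAR(el);
      int len = (int)LENGTH(el);
      if (len < k) continue;
      u128 code = 0;
      for (int p = 0; p < len; ++p) {
        int b = base_code(s[p]);
        if (b < 0) stop_bad_base(s[p]);
        code = ((code << 3) | (u128)b) & mask;
        if (p >= k - 1) {
          std::unordered_map<u128, int, U128Hash>::const_iterator it = idx.find(code);
          if (it != idx.end()) counts[(size_t)it->second * n + i] += 1.0;
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }

  std::vector<std::string> out;
  for (size_t j = 0; j < keys.size(); ++j)
    if (significant_counts(&counts[j * (size_t)n], n, tau))
      out.push_back(decode_kmer(keys[j], k));
  std::sort(out.begin(), out.end());
  return wrap(out);
}

// Builds one signature per read: the concatenation, in read order, of the
// maximal contiguous stretches covered by significant k-mers. Identical
// signatures are pooled; the first read carrying each signature is kept as
// its exemplar. Reads with no significant k-mer are counted and dropped.
// [[Rcpp::export]]
List cpp_collect_signatures(CharacterVector reads, CharacterVector psi, int k) {
  if (k < 1) stop("k must be a positive integer");
  bool packed = (k <= KMAX_PACKED);
  std::unordered_set<u128, U128Hash> pset;
  std::unordered_set<std::string> sset;
  for (R_xlen_t i = 0; i < psi.size(); ++i) {
    SEXP el = STRING_ELT(psi, i);
    if ((int)LENGTH(el) != k) stop("significant k-mer of length %d does not match k = %d", (int)LENGTH(el), k);
    const char* s = CHAR(el);
    if (packed) {
      u128 code = 0;
      for (int j = 0; j < k; ++j) {
        int b = base_code(s[j]);
        if (b < 0) stop_bad_base(s[j]);
        code = (code << 3) | (u128)b;
      }
      pset.insert(code);
    } else {
      sset.insert(std::string(s, k));
    }
  }

  struct SigInfo { double freq; int first_read; };
  std::unordered_map<std::string, SigInfo> pool;
  int n_empty = 0;
  std::vector<bool> cover;
  const u128 mask = packed ? ((((u128)1) << (3 * k)) - 1) : 0;

  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    SEXP el = STRING_ELT(reads, r);
    const char* s = CHAR(el);
    int len = (int)LENGTH(el);
    bool any = false;
    if (len >= k) {
      cover.assign(len, false);
      if (packed) {
        u128 code = 0;
        for (int p = 0; p < len; ++p) {
          int b = base_code(s[p]);
          if (b < 0) stop_bad_base(s[p]);
          code = ((code << 3) | (u128)b) & mask;
          if (p >= k - 1 && pset.count(code)) {
            any = true;
            for (int q = p - k + 1; q <= p; ++q) cover[q] = true;
          }
        }
      } else {
        for (int p = 0; p + k <= len; ++p) {
          if (sset.count(std::string(s + p, k))) {
            any = true;
            for (int q = p; q < p + k; ++q) cover[q] = true;
          }
        }
      }
    }
    if (!any) { ++n_empty; continue; }
    std::string sig;
    for (int p = 0; p < len; ++p) if (cover[p]) sig.push_back(s[p]);
    std::unordered_map<std::string, SigInfo>::iterator it = pool.find(sig);
    if (it == pool.end()) {
      SigInfo info; info.freq = 1.0; info.first_read = (int)r;
      pool.insert(std::make_pair(sig, info));
    } else {
      it->second.freq += 1.0;
    }
    if ((r & 0xFFF) == 0) Rcpp::checkUserInterrupt();
  }

  size_t m = pool.size();
  CharacterVector seq(m), exemplar(m);
  NumericVector freq(m);
  IntegerVector exidx(m);
  size_t j = 0;
  for (std::unordered_map<std::string, SigInfo>::const_iterator it = pool.begin(); it != pool.end(); ++it, ++j) {
    seq[j] = it->first;
    freq[j] = it->second.freq;
    exemplar[j] = Rcpp::as<std::string>(reads[it->second.first_read]);
    exidx[j] = it->second.first_read + 1;
  }
  return List::create(_["sequence"] = seq, _["frequency"] = freq,
                      _["exemplar"] = exemplar, _["exemplar_index"] = exidx,
                      _["n_empty"] = n_empty);
}
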