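// Smith-Waterman local alignment: best score, and a traceback variant that
// reports the matched/mismatched/gapped column counts needed for the
// identity measure used in germline annotation.

#include <Rcpp.h>
#include "sw.h"
#include "sw_simd.h"

using namespace Rcpp;

static void check_scoring(double M, double MM, double IN) {
  if (!(M > 0)) stop("match score must be > 0");
  if (MM < 0 || IN < 0) stop("mismatch and indel penalties must be >= 0");
}

// [[Rcpp::export]]
int cpp_sw_score(std::string a, std::string b, int M, int MM, int IN) {
  if (a.empty() || b.empty()) stop("sequences must be non-empty");
  check_scoring(M, MM, IN);
  return clonesight::sw_best_score_fast(a.c_str(), (int)a.size(),
                                        b.c_str(), (int)b.size(), M, MM, IN);
}

// Full local alignment with traceback. Ties during traceback prefer
// diagonal over deletion over insertion, and the best cell is the first
// maximum in row-major order, so the result is deterministic.
// [[Rcpp::export]]
List cpp_sw_align(std::string a, std::string b, int M, int MM, int IN) {
  if (a.empty() || b.empty()) stop("sequences must be non-empty");
  check_scoring(M, MM, IN);
  int la = (int)a.size(), lb = (int)b.size();
  std::vector<int> H((size_t)(la + 1) * (lb + 1), 0);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= la; ++i) {
    const char ca = a[i - 1];
    for (int j = 1; j <= lb; ++j) {
      int diag = H[(size_t)(i - 1) * (lb + 1) + (j - 1)] + ((ca == b[j - 1] && ca != 'N') ? M : -MM);
      int up = H[(size_t)(i - 1) * (lb + 1) + j] - IN;
      int left = H[(size_t)i * (lb + 1) + (j - 1)] - IN;
      int v = diag;
      if (up > v) v = up;
      if (left > v) v = left;
      if (v < 0) v = 0;
      H[(size_t)i * (lb + 1) + j] = v;
      if (v > best) { best = v; bi = i; bj = j; }
    }
  }
  int matches = 0, mismatches = 0, gaps = 0;
  int i = bi, j = bj;
  int aend = bi, bend = bj;
  while (i > 0 && j > 0) {
    int v = H[(size_t)i * (lb + 1) + j];
    if (v == 0) break;
    int diag = H[(size_t)(i - 1) * (lb + 1) + (j - 1)] + ((a[i - 1] == b[j - 1] && a[i - 1] != 'N') ? M : -MM);
    if (v == diag) {
      if (a[i - 1] == b[j - 1] && a[i - 1] != 'N') ++matches; else ++mismatches;
      --i; --j;
    } else if (v == H[(size_t)(i - 1) * (lb + 1) + j] - IN) {
      ++gaps; --i;
    } else {
      ++gaps; --j;
    }
  }
  int astart = (best > 0) ? i + 1 : 0;
  int bstart = (best > 0) ? j + 1 : 0;
  if (best == 0) { aend = 0; bend = 0; }
  double denom = matches + mismatches + gaps;
  double identity = (denom > 0) ? matches / denom : 0.0;
  return List::create(
    _["score"] = best, _["matches"] = matches, _["mismatches"] = mismatches,
    _["gaps"] = gaps, _["identity"] = identity,
    _["a_start"] = astart, _["a_end"] = aend,
    _["b_start"] = bstart, _["b_end"] = bend);
}

// [[Rcpp::export]]
double cpp_sim_threshold(int la, int lb, double M, double MM, double IN, double ratio) {
  if (la < 1 || lb < 1) stop("lengths must be >= 1");
  return sim_threshold(la, lb, M, MM, IN, ratio);
}
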