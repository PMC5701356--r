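// Signature correction (within-sample merging of similar signatures) and
// multi-sample clone accumulation. Both use the same similarity predicate:
// Smith-Waterman score strictly greater than the length-dependent threshold.

#include <Rcpp.h>
#include "sw.h"
#include "sw_simd.h"
#include <numeric>

using namespace Rcpp;

struct RankLess {
  const std::vector<double>* freq;
  const std::vector<std::string>* seq;
  bool operator()(int x, int y) const {
    if ((*freq)[x] != (*freq)[y]) return (*freq)[x] > (*freq)[y];
    return (*seq)[x] < (*seq)[y];
  }
};

// Greedy correction to a fixed point: signatures are ranked by (frequency
// descending, sequence ascending); each one is absorbed by the first
// higher-ranked similar survivor, summing frequencies. Returns the
// surviving original indices (1-based) and their corrected frequencies.
// [[Rcpp::export]]
List cpp_correct_signatures(CharacterVector sequence, NumericVector frequency,
                            double M, double MM, double IN, double ratio) {
  int n = sequence.size();
  std::vector<std::string> seq(n);
  std::vector<double> freq(n);
  std::vector<int> len(n);
  std::vector<LetterProfile> prof(n);
  for (int i = 0; i < n; ++i) {
    seq[i] = Rcpp::as<std::string>(sequence[i]);
    freq[i] = frequency[i];
    len[i] = (int)seq[i].size();
    prof[i].compute(seq[i].c_str(), len[i]);
  }
  std::vector<bool> alive(n, true);

  // One rank-ordered pass reaches the fixed point: the similarity predicate
  // depends only on the sequences (not on frequencies), it is symmetric, and
  // every signature that survives its own turn has been tested against every
  // other eventual survivor ranked above it — so no further pass can find a
  // similar surviving pair. Frequencies accumulated into a survivor never
  // change which pairs are similar.
  std::vector<int> ord;
  ord.reserve(n);
  for (int i = 0; i < n; ++i) ord.push_back(i);
  RankLess cmp; cmp.freq = &freq; cmp.seq = &seq;
  std::sort(ord.begin(), ord.end(), cmp);
  for (size_t oi = 1; oi < ord.size(); ++oi) {
    int i = ord[oi];
    for (size_t oj = 0; oj < oi; ++oj) {
      int j = ord[oj];
      if (!alive[j]) continue;
      int mn = std::min(len[i], len[j]);
      double T = sim_threshold(len[i], len[j], M, MM, IN, ratio);
      if (M * mn <= T) continue;                       // score can never exceed T
      if (M * max_common_letters(prof[i], prof[j]) <= T) continue;
      int s = clonesight::sw_best_score_fast(seq[i].c_str(), len[i],
                                             seq[j].c_str(), len[j],
                                             (int)M, (int)MM, (int)IN);
      if ((double)s > T) {
        freq[j] += freq[i];
        alive[i] = false;
        break;
      }
    }
    if ((oi & 0xFF) == 0) Rcpp::checkUserInterrupt();
  }

  std::vector<int> keep;
  for (int i = 0; i < n; ++i) if (alive[i]) keep.push_back(i);
  IntegerVector idx(keep.size());
  NumericVector fq(keep.size());
  for (size_t i = 0; i < keep.size(); ++i) { idx[i] = keep[i] + 1; fq[i] = freq[keep[i]]; }
  return List::create(_["index"] = idx, _["frequency"] = fq);
}

// Accumulates corrected per-sample signature sets into a clone table. Sets
// are processed in sample order; within a set, signatures in (frequency
// descending, sequence ascending) order. Each signature joins the similar
// clone with the highest alignment score (ties: higher total clone
// frequency, then lexicographically smaller clone sequence), or founds a new
// clone whose sequence and exemplar never change afterwards.
// [[Rcpp::export]]
List cpp_accumulate_clones(List sets, int n_samples,
                           double M, double MM, double IN, double ratio) {
  std::vector<std::string> cseq, cexe;
  std::vector<int> clen;
  std::vector<LetterProfile> cprof;
  std::vector<std::vector<double> > ccount; // per clone, length n_samples
  std::vector<double> ctot;

  for (int si = 0; si < sets.size(); ++si) {
    List set = sets[si];
    CharacterVector sequence = set["sequence"];
    NumericVector frequency = set["frequency"];
    CharacterVector exemplar = set["exemplar"];
    int m = sequence.size();
    std::vector<std::string> seq(m), exe(m);
    std::vector<double> freq(m);
    for (int i = 0; i < m; ++i) {
      seq[i] = Rcpp::as<std::string>(sequence[i]);
      exe[i] = Rcpp::as<std::string>(exemplar[i]);
      freq[i] = frequency[i];
    }
    std::vector<int> ord(m);
    std::iota(ord.begin(), ord.end(), 0);
    RankLess cmp; cmp.freq = &freq; cmp.seq = &seq;
    std::sort(ord.begin(), ord.end(), cmp);

    for (int oi = 0; oi < m; ++oi) {
      int i = ord[oi];
      int li = (int)seq[i].size();
      LetterProfile pi; pi.compute(seq[i].c_str(), li);
      int bestClone = -1, bestScore = -1;
      for (size_t c = 0; c < cseq.size(); ++c) {
        int mn = std::min(li, clen[c]);
        double T = sim_threshold(li, clen[c], M, MM, IN, ratio);
        double cap = M * mn;
        if (cap <= T || (bestClone >= 0 && cap < bestScore)) continue;
        double cap2 = M * max_common_letters(pi, cprof[c]);
        if (cap2 <= T || (bestClone >= 0 && cap2 < bestScore)) continue;
        int s = clonesight::sw_best_score_fast(seq[i].c_str(), li,
                                               cseq[c].c_str(), clen[c],
                                               (int)M, (int)MM, (int)IN);
        if ((double)s <= T) continue;
        if (bestClone < 0 || s > bestScore ||
            (s == bestScore && (ctot[c] > ctot[bestClone] ||
             (ctot[c] == ctot[bestClone] && cseq[c] < cseq[bestClone])))) {
          bestClone = (int)c;
          bestScore = s;
        }
      }
      if (bestClone >= 0) {
        ccount[bestClone][si] += freq[i];
        ctot[bestClone] += freq[i];
      } else {
        cseq.push_back(seq[i]);
        cexe.push_back(exe[i]);
        clen.push_back(li);
        LetterProfile p; p.compute(seq[i].c_str(), li);
        cprof.push_back(p);
        std::vector<double> cnt(n_samples, 0.0);
        cnt[si] = freq[i];
        ccount.push_back(cnt);
        ctot.push_back(freq[i]);
      }
      if ((oi & 0xFF) == 0) Rcpp::checkUserInterrupt();
    }
  }

  int nc = (int)cseq.size();
  CharacterVector sequence(nc), exemplar(nc);
  NumericMatrix counts(nc, n_samples);
  for (int c = 0; c < nc; ++c) {
    sequence[c] = cseq[c];
    exemplar[c] = cexe[c];
    for (int j = 0; j < n_samples; ++j) counts(c, j) = ccount[c][j];
  }
  return List::create(_["sequence"] = sequence, _["exemplar"] = exemplar,
                      _["counts"] = counts);
}
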