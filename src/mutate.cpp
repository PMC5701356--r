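// Sequencing-noise injection for the synthetic amplicon simulator: per-base
// substitutions (to a uniformly chosen different base) followed by
// N-masking. Masking is applied either independently per base
// (n_run_len = 1) or in runs of the given length — emulating localized
// quality crashes — with the same marginal per-base N probability in both
// cases. Draws come from R's RNG stream so that results are reproducible
// under set.seed() and byte-identical across runs.

#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// [[Rcpp::export]]
CharacterVector cpp_mutate_reads(CharacterVector reads, double sub_rate,
                                 double n_rate, int n_run_len = 1) {
  if (sub_rate < 0 || sub_rate > 1 || n_rate < 0 || n_rate > 1)
    stop("error rates must lie in [0, 1]");
  if (n_run_len < 1) stop("'n_run_len' must be >= 1");
  RNGScope scope;
  static const char BASES[4] = {'A', 'C', 'G', 'T'};
  // run-start probability giving marginal P(base is N) == n_rate:
  // a base is masked iff a run starts in the n_run_len positions ending at it
  double q = (n_rate >= 1.0) ? 1.0
             : 1.0 - std::pow(1.0 - n_rate, 1.0 / n_run_len);
  int n = reads.size();
  CharacterVector out(n);
  std::string buf;
  for (int r = 0; r < n; ++r) {
    buf = Rcpp::as<std::string>(reads[r]);
    if (sub_rate > 0) {
      for (size_t i = 0; i < buf.size(); ++i) {
        if (unif_rand() < sub_rate) {
          char cur = buf[i];
          int pick = (int)(unif_rand() * 3.0);
          if (pick > 2) pick = 2;
          int seen = 0;
          for (int b = 0; b < 4; ++b) {
            if (BASES[b] == cur) continue;
            if (seen == pick) { buf[i] = BASES[b]; break; }
            ++seen;
          }
        }
      }
    }
    if (n_rate > 0) {
      size_t run_end = 0;
      for (size_t i = 0; i < buf.size(); ++i) {
        if (unif_rand() < q) {
          size_t e = i + (size_t)n_run_len;
          if (e > run_end) run_end = e;
        }
        if (i < run_end) buf[i] = 'N';
      }
    }
    out[r] = buf;
    if ((r & 0xFFF) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
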