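#ifndef CLONESIGHT_SW_H
#define CLONESIGHT_SW_H

#include <string>
#include <vector>
#include <algorithm>

// Local-alignment best score, linear gap penalty. An N never matches anything
// (including another N): it scores as a mismatch.
inline int sw_best_score(const char* a, int la, const char* b, int lb,
                         int M, int MM, int IN) {
  std::vector<int> prev(lb + 1, 0), cur(lb + 1, 0);
  int best = 0;
  for (int i = 1; i <= la; ++i) {
    cur[0] = 0;
    const char ca = a[i - 1];
    for (int j = 1; j <= lb; ++j) {
      int diag = prev[j - 1] + ((ca == b[j - 1] && ca != 'N') ? M : -MM);
      int up = prev[j] - IN;
      int left = cur[j - 1] - IN;
      int v = diag;
      if (up > v) v = up;
      if (left > v) v = left;
      if (v < 0) v = 0;
      cur[j] = v;
      if (v > best) best = v;
    }
    std::swap(prev, cur);
  }
  return best;
}

// Two-branch similarity threshold: pairs whose shorter sequence is below
// lengthRatio of the longer get an unattainable threshold (always different);
// otherwise the threshold is a fixed fraction of the longer length.
inline double sim_threshold(int la, int lb, double M, double MM, double IN,
                            double ratio) {
  double mx = (la > lb) ? la : lb;
  double mn = (la > lb) ? lb : la;
  if (mx * ratio > mn) return mx * M;
  return (M * 4.0 / 5.0 - MM * 2.0 / 50.0 - IN * 2.0 / 10.0) * mx;
}

// Letter profile (A,C,G,T) used for a sound upper bound on the match count of
// any alignment: matches <= sum over letters of min(count_a, count_b).
struct LetterProfile {
  int cnt[4];
  void compute(const char* s, int len) {
    cnt[0] = cnt[1] = cnt[2] = cnt[3] = 0;
    for (int i = 0; i < len; ++i) {
      switch (s[i]) {
        case 'A': ++cnt[0]; break; case 'C': ++cnt[1]; break;
        case 'G': ++cnt[2]; break; case 'T': ++cnt[3]; break;
      }
    }
  }
};

inline int max_common_letters(const LetterProfile& x, const LetterProfile& y) {
  int s = 0;
  for (int i = 0; i < 4; ++i) s += std::min(x.cnt[i], y.cnt[i]);
  return s;
}

#endif
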