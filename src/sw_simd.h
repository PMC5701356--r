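#ifndef CLONESIGHT_SW_SIMD_H
#define CLONESIGHT_SW_SIMD_H

// Striped SIMD Smith-Waterman (Farrar-style, 8 x int16 lanes, linear gap
// penalty, score only). The similarity clustering performs millions of
// pairwise alignments, so the kernel matters; the scalar DP in sw.h is the
// reference implementation and the fallback on non-SSE2 targets.

#include "sw.h"
#include <vector>
#include <cstring>

#ifdef __SSE2__
#include <emmintrin.h>

namespace clonesight {

inline int base_code5(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1; case 'G': return 2;
    case 'T': return 3;
  }
  return 4;  // N and anything else: never matches
}

struct SwBuffers {
  std::vector<__m128i> prof, Hs, Es;
};

// Best local-alignment score of a vs b; +M match, -MM mismatch, -IN per
// gap base; N (code 4) scores as a mismatch against everything.
inline int sw_best_score_simd_impl(const char* a, int la, const char* b, int lb,
                                   int M, int MM, int IN, SwBuffers& buf) {
  const int LANES = 8;
  const int seg = (lb + LANES - 1) / LANES;

  buf.prof.resize((size_t)5 * seg);
  buf.Hs.assign(seg, _mm_setzero_si128());
  buf.Es.assign(seg, _mm_setzero_si128());

  // query profile: prof[s][t] lane l = S(s, b[t + l*seg])
  {
    int16_t tmp[8];
    for (int s = 0; s < 5; ++s) {
      for (int t = 0; t < seg; ++t) {
        for (int l = 0; l < LANES; ++l) {
          int j = t + l * seg;
          int16_t v;
          if (j >= lb) v = (int16_t)(-MM);
          else {
            int bc = base_code5(b[j]);
            v = (int16_t)((s == bc && s != 4) ? M : -MM);
          }
          tmp[l] = v;
        }
        buf.prof[(size_t)s * seg + t] = _mm_loadu_si128((const __m128i*)tmp);
      }
    }
  }

  const __m128i vZero = _mm_setzero_si128();
  const __m128i vGap = _mm_set1_epi16((int16_t)IN);
  __m128i vMax = vZero;

  for (int i = 0; i < la; ++i) {
    const __m128i* P = &buf.prof[(size_t)base_code5(a[i]) * seg];
    // H[i-1][j-1] for t = 0 comes from the last segment shifted one lane
    __m128i vH = _mm_slli_si128(buf.Hs[seg - 1], 2);
    __m128i vF = vZero;
    for (int t = 0; t < seg; ++t) {
      __m128i vHnext = buf.Hs[t];            // becomes the diagonal for t+1
      vH = _mm_adds_epi16(vH, P[t]);
      __m128i vE = buf.Es[t];
      vE = _mm_max_epi16(_mm_subs_epi16(vE, vGap), _mm_subs_epi16(vHnext, vGap));
      buf.Es[t] = vE;
      vH = _mm_max_epi16(vH, vE);
      vH = _mm_max_epi16(vH, vF);
      vH = _mm_max_epi16(vH, vZero);
      buf.Hs[t] = vH;
      vMax = _mm_max_epi16(vMax, vH);
      vF = _mm_max_epi16(_mm_subs_epi16(vF, vGap), _mm_subs_epi16(vH, vGap));
      vH = vHnext;
    }
    // lazy-F: propagate F across the segment wrap until it stops improving
    vF = _mm_slli_si128(vF, 2);
    int t = 0, guard = seg * LANES * 2;
    while (_mm_movemask_epi8(_mm_cmpgt_epi16(vF, buf.Hs[t])) && guard-- > 0) {
      buf.Hs[t] = _mm_max_epi16(buf.Hs[t], vF);
      vMax = _mm_max_epi16(vMax, buf.Hs[t]);
      vF = _mm_subs_epi16(vF, vGap);
      if (++t >= seg) { vF = _mm_slli_si128(vF, 2); t = 0; }
    }
  }

  int16_t out[8];
  _mm_storeu_si128((__m128i*)out, vMax);
  int best = 0;
  for (int l = 0; l < LANES; ++l) if (out[l] > best) best = out[l];
  return best;
}

inline int sw_best_score_fast(const char* a, int la, const char* b, int lb,
                              int M, int MM, int IN) {
  static thread_local SwBuffers buf;
  // striping the longer sequence maximises lane utilisation
  if (la >= lb) return sw_best_score_simd_impl(b, lb, a, la, M, MM, IN, buf);
  return sw_best_score_simd_impl(a, la, b, lb, M, MM, IN, buf);
}

} // namespace clonesight

#define CLONESIGHT_HAVE_SIMD_SW 1

#else

namespace clonesight {
inline int sw_best_score_fast(const char* a, int la, const char* b, int lb,
                              int M, int MM, int IN) {
  return sw_best_score(a, la, b, lb, M, MM, IN);
}
}

#endif
#endif
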