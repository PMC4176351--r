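#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

// Constrained glocal alignment of a read against a small reference.
//
// An alignment is described by: a 5' soft-clip c (0..max_clip5), a
// reference start s, an aligned read length t (read bases c+1..c+t are
// consumed), and 0..2 deletions -- reference bases absent from the read,
// the crosslink-induced error mode.  A deletion is placed "after read
// offset k" (1 <= k <= t-1, so never terminal).  There is no insert state:
// read length decomposes exactly as clip + (ref span - deletions) + tail,
// with the tail being the read suffix beyond the last aligned base.
//
// Score = match * n_match + mismatch * n_mismatch + gap * n_del.  Because
// there are no insertions, for fixed (c, t, d) the score determines the
// mismatch count:  x = (match*t + gap*d - score) / (match - mismatch).
//
// The reported alignment is the maximum-score alignment *among those
// satisfying the constraints* (ref span >= min_match_len, mismatch
// fraction over aligned columns <= max_mismatch_frac, tail length <=
// max_tail_len).  Ties are resolved by, in order: larger read_end (the
// maximal-genomic-extension rule: templated bases are never reported as
// tail), smaller ref_end, fewer deletions, smaller ref_start, smaller
// clip, lexicographically smaller deletion positions.  The enumeration
// oracle in the test suite implements the same total order independently.

struct Cand {
  long score;
  int read_end;   // i = c + t
  int ref_end;    // s + t - 1 + d
  int ndel;
  int ref_start;  // s
  int clip;       // c
  int del1, del2; // deleted ref positions (0 = none), del1 <= del2
  bool valid;
};

static inline bool better(const Cand &a, const Cand &b) {
  if (!b.valid) return true;
  if (!a.valid) return false;
  if (a.score != b.score) return a.score > b.score;
  if (a.read_end != b.read_end) return a.read_end > b.read_end;
  if (a.ref_end != b.ref_end) return a.ref_end < b.ref_end;
  if (a.ndel != b.ndel) return a.ndel < b.ndel;
  if (a.ref_start != b.ref_start) return a.ref_start < b.ref_start;
  if (a.clip != b.clip) return a.clip < b.clip;
  if (a.del1 != b.del1) return a.del1 < b.del1;
  return a.del2 < b.del2;
}

// [[Rcpp::export(name = ".align_core")]]
List align_core(std::string read, std::string ref,
                int match, int mismatch, int gap, int max_clip5,
                int min_match_len, double max_mismatch_frac,
                int max_tail_len) {
  const int m = (int)read.size(), n = (int)ref.size();
  if (m == 0 || n == 0) return List::create(_["aligned"] = false);

  const long fracnum = (long)std::lround(max_mismatch_frac * 1e6);
  Cand best; best.valid = false;

  std::vector<long> P0(m + 1), P1(m + 1), P2(m + 1);
  std::vector<long> M(m + 1), Q(m + 1);       // running maxima
  std::vector<int> Mk(m + 1), Qk1(m + 1), Qk2(m + 1);

  for (int c = 0; c <= max_clip5 && c < m; ++c) {
    const int mlen = m - c;                   // read bases available
    for (int s = 1; s <= n; ++s) {
      const int T0 = std::min(mlen, n - s + 1);
      if (T0 < 1) break;
      const int T1 = std::min(mlen, n - s);       // diagonal s+1
      const int T2 = std::min(mlen, n - s - 1);   // diagonal s+2
      // prefix sums of per-base scores along the three diagonals
      P0[0] = P1[0] = P2[0] = 0;
      for (int t = 1; t <= T0; ++t) {
        char rb = read[c + t - 1], fb = ref[s + t - 2];
        P0[t] = P0[t - 1] + ((rb == fb && rb != 'N') ? match : mismatch);
      }
      for (int t = 1; t <= T1; ++t) {
        char rb = read[c + t - 1], fb = ref[s + t - 1];
        P1[t] = P1[t - 1] + ((rb == fb && rb != 'N') ? match : mismatch);
      }
      for (int t = 1; t <= T2; ++t) {
        char rb = read[c + t - 1], fb = ref[s + t];
        P2[t] = P2[t - 1] + ((rb == fb && rb != 'N') ? match : mismatch);
      }
      // M[k]  = max_{1<=k1<=k} P0[k1] - P1[k1]          (first deletion)
      // Q[k2] = max_{k1<=k2}  M[k1..] + P1[k2] - P2[k2] (second deletion)
      for (int k = 1; k <= T1; ++k) {
        long v = P0[k] - P1[k];
        if (k == 1 || v > M[k - 1]) { M[k] = v; Mk[k] = k; }
        else { M[k] = M[k - 1]; Mk[k] = Mk[k - 1]; }
      }
      for (int k = 1; k <= T2; ++k) {
        long v = M[k] + P1[k] - P2[k];
        if (k == 1 || v > Q[k - 1]) { Q[k] = v; Qk1[k] = Mk[k]; Qk2[k] = k; }
        else { Q[k] = Q[k - 1]; Qk1[k] = Qk1[k - 1]; Qk2[k] = Qk2[k - 1]; }
      }
      for (int t = 1; t <= T0; ++t) {
        const int i = c + t;
        const int tail_len = m - i;
        if (tail_len > max_tail_len) continue;
        for (int d = 0; d <= 2; ++d) {
          const int span = t + d;
          if (span < min_match_len || s + span - 1 > n) continue;
          long score;
          int k1 = 0, k2 = 0;
          if (d == 0) {
            score = P0[t];
          } else if (d == 1) {
            if (t - 1 < 1 || t > T1) continue;
            int km = std::min(t - 1, T1);
            score = M[km] + P1[t] + gap;
            k1 = Mk[km];
          } else {
            if (t - 1 < 1 || t > T2) continue;
            int km = std::min(t - 1, T2);
            score = Q[km] + P2[t] + 2L * gap;
            k1 = Qk1[km]; k2 = Qk2[km];
          }
          // mismatch count from the score identity
          long x = ((long)match * t + (long)gap * d - score) /
                   (match - mismatch);
          if (x * 1000000L > (long)span * fracnum) continue;
          Cand cand;
          cand.valid = true;
          cand.score = score;
          cand.read_end = i;
          cand.ref_end = s + t - 1 + d;
          cand.ndel = d;
          cand.ref_start = s;
          cand.clip = c;
          cand.del1 = (d >= 1) ? s + k1 : 0;
          cand.del2 = (d == 2) ? s + k2 + 1 : 0;
          if (better(cand, best)) best = cand;
        }
      }
    }
  }
  if (!best.valid) return List::create(_["aligned"] = false);

  long x = ((long)match * (best.read_end - best.clip) +
            (long)gap * best.ndel - best.score) / (match - mismatch);
  IntegerVector dels;
  if (best.ndel == 1) dels = IntegerVector::create(best.del1);
  else if (best.ndel == 2) dels = IntegerVector::create(best.del1, best.del2);

  return List::create(
      _["aligned"] = true,
      _["score"] = (int)best.score,
      _["read_start"] = best.clip + 1,
      _["read_end"] = best.read_end,
      _["ref_start"] = best.ref_start,
      _["ref_end"] = best.ref_end,
      _["n_mismatch"] = (int)x,
      _["deletion_positions"] = dels);
}
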