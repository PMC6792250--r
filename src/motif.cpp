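#include <Rcpp.h>
#include <vector>
#include <string>

using namespace Rcpp;

static inline char comp(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default: return 0; // unknown base never matches
  }
}

// Dyad (inverted repeat) candidate enumeration: for every loop placement
// (c1 = index just after the left arm, loop length l) extend arms outward,
// allowing up to max_mm Hamming mismatches between the left arm and the
// reverse complement of the right arm. The reported arm is the longest
// extension whose outermost base pair matches and whose cumulative mismatch
// count is <= max_mm; the innermost pair (adjacent to the loop) must match
// for an arm to exist at all. Coordinates returned 0-based half-open.
//' @noRd
// [[Rcpp::export(name = ".dyad_candidates")]]
DataFrame dyad_candidates(const std::string& seq, int min_arm, int max_loop, int max_mm) {
  const int L = (int) seq.size();
  std::vector<int> start, end, arm, loop, mm;
  for (int c1 = 1; c1 < L; ++c1) {
    for (int l = 0; l <= max_loop; ++l) {
      const int c2 = c1 + l;
      if (c2 >= L) break;
      int cum = 0, besta = 0, bestmm = 0;
      for (int j = 0;; ++j) {
        const int li = c1 - 1 - j, ri = c2 + j;
        if (li < 0 || ri >= L) break;
        const char cc = comp(seq[ri]);
        const bool ok = (cc != 0) && (seq[li] == cc) &&
          (seq[li] == 'A' || seq[li] == 'C' || seq[li] == 'G' || seq[li] == 'T');
        if (j == 0 && !ok) break; // innermost pair must match
        if (!ok) ++cum;
        if (cum > max_mm) break;
        if (ok) { besta = j + 1; bestmm = cum; }
      }
      if (besta >= min_arm) {
        start.push_back(c1 - besta);
        end.push_back(c2 + besta);
        arm.push_back(besta);
        loop.push_back(l);
        mm.push_back(bestmm);
      }
    }
  }
  return DataFrame::create(_["start"] = start, _["end"] = end,
                           _["arm"] = arm, _["loop"] = loop,
                           _["mismatches"] = mm);
}
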