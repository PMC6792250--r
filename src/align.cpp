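#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
#include <string>

using namespace Rcpp;

static inline int baseCode(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

//' @noRd
// [[Rcpp::export(name = ".kmer_seed_hits")]]
IntegerMatrix kmer_seed_hits(const std::string& query, const std::string& read, int k) {
  // exact k-mer matches; k-mers containing non-ACGT never match
  const int nq = (int) query.size(), nr = (int) read.size();
  if (k < 1 || nq < k || nr < k) return IntegerMatrix(0, 2);
  if (k > 31) stop("k must be <= 31");
  std::unordered_map<uint64_t, std::vector<int> > index;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  uint64_t h = 0; int run = 0;
  for (int i = 0; i < nq; ++i) {
    int c = baseCode(query[i]);
    if (c < 0) { run = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t) c) & mask;
    if (++run >= k) index[h].push_back(i - k + 1);
  }
  std::vector<int> qpos, rpos;
  h = 0; run = 0;
  for (int i = 0; i < nr; ++i) {
    int c = baseCode(read[i]);
    if (c < 0) { run = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t) c) & mask;
    if (++run >= k) {
      auto it = index.find(h);
      if (it != index.end()) {
        for (int q : it->second) { qpos.push_back(q); rpos.push_back(i - k + 1); }
      }
    }
  }
  IntegerMatrix out((int) qpos.size(), 2);
  for (size_t i = 0; i < qpos.size(); ++i) { out(i, 0) = qpos[i]; out(i, 1) = rpos[i]; }
  return out;
}

// Banded affine-gap local alignment (Smith-Waterman / Gotoh).
// pattern = read (rows i), subject = query window (cols j). The band keeps
// j - i within [diag - band, diag + band]. Gap of length L costs
// gap_open + L * gap_ext. Any non-ACGT character mismatches everything,
// including itself.
//
// Returned coordinates are 0-based half-open on subject/pattern; the CIGAR
// is written pattern-wise with ops =, X, I (pattern only), D (subject only).
//' @noRd
// [[Rcpp::export(name = ".banded_local_align")]]
List banded_local_align(const std::string& subject, const std::string& pattern,
                        int diag, int band,
                        int match, int mismatch, int gap_open, int gap_ext) {
  const int m = (int) pattern.size(), n = (int) subject.size();
  if (m == 0 || n == 0) stop("empty sequence in alignment");
  if (band < 1) band = 1;
  const int w = 2 * band + 1;
  const int NEG = INT32_MIN / 4;
  const int gfirst = gap_open + gap_ext;

  std::vector<int> sc(m); // pattern base codes
  for (int i = 0; i < m; ++i) sc[i] = baseCode(pattern[i]);
  std::vector<int> qc(n);
  for (int j = 0; j < n; ++j) qc[j] = baseCode(subject[j]);

  // banded storage: row i (1..m), offset o = j - i - diag + band in [0, w)
  std::vector<int> H((size_t)(m + 1) * w, 0), E((size_t)(m + 1) * w, NEG), F((size_t)(m + 1) * w, NEG);
  // traceback: 0 stop, 1 diag, 2 from E (gap in pattern, consumes subject),
  // 3 from F (gap in subject, consumes pattern); extension bits for E/F
  std::vector<uint8_t> tb((size_t)(m + 1) * w, 0), te((size_t)(m + 1) * w, 0), tf((size_t)(m + 1) * w, 0);

  auto idx = [w](int i, int o) { return (size_t) i * w + o; };

  int best = 0, bi = -1, bo = -1;
  for (int i = 1; i <= m; ++i) {
    const int jlo = std::max(1, i + diag - band);
    const int jhi = std::min(n, i + diag + band);
    if (jlo > jhi) continue;
    const int pc = sc[i - 1];
    for (int j = jlo; j <= jhi; ++j) {
      const int o = j - i - diag + band;
      // E: gap in pattern, coming from (i, j-1) -> offset o-1 same row
      int e = NEG;
      uint8_t eext = 0;
      if (o - 1 >= 0) {
        const int hprev = H[idx(i, o - 1)];
        const int eprev = E[idx(i, o - 1)];
        const int eo = hprev + (hprev > NEG / 2 ? -gfirst : NEG);
        const int ee = eprev + (eprev > NEG / 2 ? -gap_ext : NEG);
        if (ee > eo) { e = ee; eext = 1; } else { e = eo; }
      }
      // F: gap in subject, from (i-1, j) -> offset o+1 previous row
      int f = NEG;
      uint8_t fext = 0;
      if (o + 1 < w) {
        const int hup = H[idx(i - 1, o + 1)];
        const int fup = F[idx(i - 1, o + 1)];
        const int fo = hup + (hup > NEG / 2 ? -gfirst : NEG);
        const int fe = fup + (fup > NEG / 2 ? -gap_ext : NEG);
        if (fe > fo) { f = fe; fext = 1; } else { f = fo; }
      }
      // diag: (i-1, j-1) -> same offset, previous row
      const int qcj = qc[j - 1];
      const int s = (pc >= 0 && qcj >= 0 && pc == qcj) ? match : mismatch;
      const int hdiag = H[idx(i - 1, o)];
      // cells outside the band on the previous row hold 0; that is safe
      // because the band is inclusive of the optimum by construction
      int d = ((i + 1 + diag - band <= j + 1) || true) ? hdiag + s : NEG;
      int h = 0; uint8_t dir = 0;
      if (d > h) { h = d; dir = 1; }
      if (e > h) { h = e; dir = 2; }
      if (f > h) { h = f; dir = 3; }
      const size_t id = idx(i, o);
      H[id] = h; E[id] = e; F[id] = f;
      tb[id] = dir; te[id] = eext; tf[id] = fext;
      if (h > best) { best = h; bi = i; bo = o; }
    }
    // invalidate band edges of this row so next row's out-of-band reads see 0/NEG
    // (cells outside jlo..jhi keep their initial values, which encode "empty")
  }

  if (best <= 0 || bi < 0) {
    return List::create(_["score"] = 0, _["sub_start"] = 0, _["sub_end"] = 0,
                        _["pat_start"] = 0, _["pat_end"] = 0,
                        _["matches"] = 0, _["mismatches"] = 0,
                        _["insertions"] = 0, _["deletions"] = 0,
                        _["cigar"] = "");
  }

  // traceback
  int i = bi, o = bo;
  int matches = 0, mismatches = 0, ins = 0, del = 0;
  std::string ops; // reversed
  int state = 0;   // 0 = H, 2 = E, 3 = F
  int endi = bi, endj = bi + (bo - band) + diag;
  while (true) {
    const size_t id = idx(i, o);
    if (state == 0) {
      const uint8_t dir = tb[id];
      if (dir == 0) break;
      if (dir == 1) {
        const int j = i + (o - band) + diag;
        const int pc2 = sc[i - 1], qc2 = qc[j - 1];
        if (pc2 >= 0 && qc2 >= 0 && pc2 == qc2) { ops.push_back('='); ++matches; }
        else { ops.push_back('X'); ++mismatches; }
        i -= 1; // o unchanged: j-1-(i-1) == j-i
      } else if (dir == 2) state = 2;
      else state = 3;
    } else if (state == 2) {
      // gap in pattern: consume subject, 'D'
      ops.push_back('D'); ++del;
      const uint8_t ext = te[id];
      o -= 1;
      state = ext ? 2 : 0;
    } else {
      ops.push_back('I'); ++ins;
      const uint8_t ext = tf[id];
      i -= 1; o += 1;
      state = ext ? 3 : 0;
    }
  }
  const int starti = i, startj = i + (o - band) + diag;

  // compress ops (reversed) into CIGAR
  std::string cigar;
  for (int p = (int) ops.size() - 1; p >= 0;) {
    const char c = ops[p];
    int run = 0;
    while (p >= 0 && ops[p] == c) { ++run; --p; }
    cigar += std::to_string(run);
    cigar.push_back(c);
  }

  return List::create(_["score"] = best,
                      _["sub_start"] = startj, _["sub_end"] = endj,
                      _["pat_start"] = starti, _["pat_end"] = endi,
                      _["matches"] = matches, _["mismatches"] = mismatches,
                      _["insertions"] = ins, _["deletions"] = del,
                      _["cigar"] = cigar);
}
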