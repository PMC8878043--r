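#include <Rcpp.h>
#include <vector>
#include <cstdint>

using namespace Rcpp;

// Full Smith-Waterman local alignment with affine gaps for protein pairs:
// substitution matrix passed from R (BLOSUM62), gap of length k costs
// gap_open + k * gap_extend. Returns, per subject, the optimal alignment's
// score, identical residues, alignment columns, and aligned span on both
// sequences (for identity/coverage threshold decisions).

// [[Rcpp::export(name = ".cpp_protein_batch")]]
DataFrame cpp_protein_batch(std::string pattern, CharacterVector subjects,
                            IntegerMatrix submat, IntegerVector lookup,
                            int gap_open, int gap_extend) {
  int ns = subjects.size();
  IntegerVector out_score(ns), out_ident(ns), out_cols(ns);
  IntegerVector out_span_p(ns), out_span_q(ns);

  int m = pattern.size();
  std::vector<int> pc(m);
  for (int i = 0; i < m; ++i) pc[i] = lookup[(unsigned char)pattern[i]];

  const int NEG = -1000000000;
  int goe = gap_open + gap_extend;

  for (int si = 0; si < ns; ++si) {
    std::string subj = as<std::string>(subjects[si]);
    int n = subj.size();
    std::vector<int> qc(n);
    for (int j = 0; j < n; ++j) qc[j] = lookup[(unsigned char)subj[j]];

    std::vector<int> H(n + 1, 0), E(n + 1, NEG);
    std::vector<int> Hprev(n + 1, 0);
    std::vector<int> Fcol(n + 1, NEG);
    // traceback bytes: bits 0-1 H-source (0 stop,1 diag,2 E,3 F),
    // bit 2 E from E, bit 3 F from F
    std::vector<uint8_t> tb((size_t)(m + 1) * (n + 1), 0);

    int best = 0, bi = 0, bj = 0;
    for (int i = 1; i <= m; ++i) {
      std::swap(Hprev, H);
      H[0] = 0;
      int e = NEG; // E for current row, running along j
      // column pc[i-1] is contiguous (column-major); BLOSUM62 is symmetric
      const int *srow = &submat(0, pc[i - 1]);
      uint8_t *tbrow = &tb[(size_t)i * (n + 1)];
      for (int j = 1; j <= n; ++j) {
        uint8_t byte = 0;
        int eo = H[j - 1] - goe;
        int ee = e - gap_extend;
        if (ee > eo) { e = ee; byte |= 4; } else e = eo;
        int fo = Hprev[j] - goe;
        int ff = Fcol[j] - gap_extend;
        int f;
        if (ff > fo) { f = ff; byte |= 8; } else f = fo;
        Fcol[j] = f;
        int d = Hprev[j - 1] + srow[qc[j - 1]];
        int h = 0; uint8_t hb = 0;
        if (d > h) { h = d; hb = 1; }
        if (e > h) { h = e; hb = 2; }
        if (f > h) { h = f; hb = 3; }
        H[j] = h;
        tbrow[j] = byte | hb;
        if (h > best) { best = h; bi = i; bj = j; }
      }
    }

    int ident = 0, cols = 0;
    int i = bi, j = bj, state = 0;
    int min_i = bi, min_j = bj;
    while (i > 0 && j > 0) {
      uint8_t b = tb[(size_t)i * (n + 1) + j];
      if (state == 0) {
        int hb = b & 3;
        if (hb == 0) break;
        if (hb == 1) {
          ++cols;
          if (pc[i - 1] == qc[j - 1] &&
              pattern[i - 1] == subj[j - 1]) ++ident;
          --i; --j;
          min_i = i + 1; min_j = j + 1;
        } else if (hb == 2) state = 1;
        else state = 2;
      } else if (state == 1) { // E: gap in pattern, consume subject
        ++cols; --j; min_j = j + 1;
        if (!(b & 4)) state = 0;
      } else { // F: gap in subject, consume pattern
        ++cols; --i; min_i = i + 1;
        if (!(b & 8)) state = 0;
      }
    }
    out_score[si] = best;
    out_ident[si] = ident;
    out_cols[si] = cols;
    out_span_p[si] = (best > 0) ? (bi - min_i + 1) : 0;
    out_span_q[si] = (best > 0) ? (bj - min_j + 1) : 0;
  }
  return DataFrame::create(_["score"] = out_score, _["identities"] = out_ident,
                           _["columns"] = out_cols, _["span_p"] = out_span_p,
                           _["span_q"] = out_span_q);
}
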