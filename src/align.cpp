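#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// Seed-and-extend local nucleotide alignment (blastn-style scoring):
// exact word seeds, ungapped X-drop extension, then banded affine-gap
// X-drop extension with traceback so identity counts are exact.
// Coordinates are 0-based half-open throughout; strand handling (reverse
// complement of the subject) is done by the R caller.

namespace {

struct Hsp {
  int qs, qe, ss, se;
  int score, ident, alen;
};

struct ExtRes {
  int dq = 0, ds = 0;       // consumed lengths on query/subject
  int score = 0, ident = 0, alen = 0;
};

const int NEG_INF = -1000000000;

// Banded adaptive X-drop extension with affine gaps, one direction.
// Sequence access is via base pointer and stride (+1 forward, -1 backward),
// so the same routine extends left and right of the anchor.
ExtRes xdrop_extend(const uint8_t *q, int qlen, int qstride,
                    const uint8_t *s, int slen, int sstride,
                    int reward, int penalty, int go, int ge, int xdrop,
                    long max_cells) {
  ExtRes res;
  if (qlen <= 0 || slen <= 0) return res;

  // Row i consumes q[0..i); column j consumes s[0..j).
  // H: best score, E: gap in query (consumes s), F: gap in subject.
  std::vector<int> H, E, F, Hn, En, Fn;
  std::vector<int> row_lo;             // lo of each row's band
  std::vector<std::vector<uint8_t>> tb; // traceback bytes per row

  int best = 0, bi = 0, bj = 0;
  long cells = 0;

  // Row 0: leading gaps in the subject direction.
  int lo = 0, hi = 1; // half-open band [lo, hi) for current row
  {
    std::vector<uint8_t> tb0;
    H.clear(); E.clear(); F.clear();
    int j = 0;
    while (true) {
      int h = (j == 0) ? 0 : -(go + ge * j);
      if (j > 0 && h < best - xdrop) break;
      H.push_back(h);
      E.push_back(j == 0 ? NEG_INF : h);
      F.push_back(NEG_INF);
      tb0.push_back(1); // from E (left)
      ++j;
      if (j > slen) break;
    }
    hi = lo + (int)H.size();
    row_lo.push_back(lo);
    tb.push_back(std::move(tb0));
  }

  for (int i = 1; i <= qlen; ++i) {
    int prev_lo = lo, prev_hi = hi;
    int new_lo = prev_lo;          // may advance past dead cells
    int new_hi = std::min(prev_hi + 1, slen + 1);
    if (new_lo >= new_hi) break;

    Hn.assign(new_hi - new_lo, NEG_INF);
    En.assign(new_hi - new_lo, NEG_INF);
    Fn.assign(new_hi - new_lo, NEG_INF);
    std::vector<uint8_t> tbr(new_hi - new_lo, 0);

    uint8_t qc = q[(long)(i - 1) * qstride];
    int row_best = NEG_INF;
    int first_alive = -1, last_alive = -1;

    for (int j = new_lo; j < new_hi; ++j) {
      int idx = j - new_lo;
      // E: gap in query (left move), needs j-1 in current row
      int e = NEG_INF; uint8_t ebit = 0;
      if (j - 1 >= new_lo) {
        int ho = Hn[idx - 1] == NEG_INF ? NEG_INF : Hn[idx - 1] - go - ge;
        int ee = En[idx - 1] == NEG_INF ? NEG_INF : En[idx - 1] - ge;
        if (ee > ho) { e = ee; ebit = 1; } else e = ho;
      }
      // F: gap in subject (up move), needs j in previous row
      int f = NEG_INF; uint8_t fbit = 0;
      if (j >= prev_lo && j < prev_hi) {
        int pidx = j - prev_lo;
        int ho = H[pidx] == NEG_INF ? NEG_INF : H[pidx] - go - ge;
        int ff = F[pidx] == NEG_INF ? NEG_INF : F[pidx] - ge;
        if (ff > ho) { f = ff; fbit = 1; } else f = ho;
      }
      // diagonal
      int d = NEG_INF;
      if (j - 1 >= prev_lo && j - 1 < prev_hi) {
        int pidx = j - 1 - prev_lo;
        if (H[pidx] != NEG_INF) {
          uint8_t sc = s[(long)(j - 1) * sstride];
          int sub = (qc < 4 && sc < 4 && qc == sc) ? reward : penalty;
          d = H[pidx] + sub;
        }
      }
      int h = d; uint8_t hbits = 0;
      if (e > h) { h = e; hbits = 1; }
      if (f > h) { h = f; hbits = 2; }
      if (h == NEG_INF || h < best - xdrop) {
        Hn[idx] = NEG_INF; En[idx] = NEG_INF; Fn[idx] = NEG_INF;
        continue;
      }
      Hn[idx] = h; En[idx] = e; Fn[idx] = f;
      tbr[idx] = (uint8_t)(hbits | (ebit << 2) | (fbit << 3));
      if (first_alive < 0) first_alive = j;
      last_alive = j;
      if (h > row_best) row_best = h;
      if (h > best || (h == best && i + j > bi + bj)) { best = h; bi = i; bj = j; }
    }
    cells += (new_hi - new_lo);
    if (first_alive < 0 || cells > max_cells) break;

    lo = first_alive;
    hi = last_alive + 1;
    int off = lo - new_lo;
    H.assign(Hn.begin() + off, Hn.begin() + (hi - new_lo));
    E.assign(En.begin() + off, En.begin() + (hi - new_lo));
    F.assign(Fn.begin() + off, Fn.begin() + (hi - new_lo));
    tbr.erase(tbr.begin(), tbr.begin() + off);
    tbr.resize(hi - lo);
    row_lo.push_back(lo);
    tb.push_back(std::move(tbr));
    if ((int)row_lo.size() != i + 1) break; // should not happen
  }

  if (bi + bj == 0) return res; // no extension (ties at zero still count)

  // Traceback from (bi, bj) in state H.
  int i = bi, j = bj, state = 0; // 0=H,1=E,2=F
  int ident = 0, alen = 0;
  while (i > 0 || j > 0) {
    if ((size_t)i >= tb.size()) break;
    int rl = row_lo[i];
    if (j < rl || j >= rl + (int)tb[i].size()) break;
    uint8_t b = tb[i][j - rl];
    if (state == 0) {
      int hb = b & 3;
      if (hb == 1) state = 1;
      else if (hb == 2) state = 2;
      else { // diagonal
        uint8_t qc = q[(long)(i - 1) * qstride];
        uint8_t sc = s[(long)(j - 1) * sstride];
        if (qc < 4 && sc < 4 && qc == sc) ++ident;
        ++alen; --i; --j;
      }
    } else if (state == 1) { // E: left move
      ++alen; --j;
      if (!((b >> 2) & 1)) state = 0;
      // note: bit describes source at the *consumed* cell; recompute below
      if (j >= 0 && i < (int)tb.size()) {
        // after moving, state source bit belongs to new cell when extending
      }
    } else { // F: up move
      ++alen; --i;
      if (!((b >> 3) & 1)) state = 0;
    }
  }
  res.dq = bi; res.ds = bj; res.score = best; res.ident = ident; res.alen = alen;
  return res;
}

} // namespace

// [[Rcpp::export(name = ".cpp_seed_extend")]]
DataFrame cpp_seed_extend(IntegerVector query, IntegerVector subject,
                          int reward, int penalty, int gap_open, int gap_extend,
                          int word_size, int min_score, int gap_trigger,
                          int xdrop_ungapped, int xdrop_gapped) {
  int qlen = query.size(), slen = subject.size();
  std::vector<uint8_t> q(qlen), s(slen);
  for (int i = 0; i < qlen; ++i) q[i] = (uint8_t)query[i];
  for (int i = 0; i < slen; ++i) s[i] = (uint8_t)subject[i];

  std::vector<Hsp> hsps;

  if (qlen >= word_size && slen >= word_size) {
    // Index subject words (2-bit packed; words containing N are skipped).
    uint32_t mask = (word_size >= 16) ? 0xFFFFFFFFu : ((1u << (2 * word_size)) - 1);
    std::unordered_map<uint32_t, std::vector<int>> index;
    {
      uint32_t w = 0; int run = 0;
      for (int i = 0; i < slen; ++i) {
        if (s[i] > 3) { run = 0; w = 0; continue; }
        w = ((w << 2) | s[i]) & mask;
        if (++run >= word_size) index[w].push_back(i - word_size + 1);
      }
    }
    // diag -> furthest query end already covered on that diagonal
    std::unordered_map<long, int> diag_cover;
    const long MAX_CELLS = 60000000L;

    uint32_t w = 0; int run = 0;
    for (int qi = 0; qi < qlen; ++qi) {
      if (q[qi] > 3) { run = 0; w = 0; continue; }
      w = ((w << 2) | q[qi]) & mask;
      if (++run < word_size) continue;
      int qpos = qi - word_size + 1;
      auto it = index.find(w);
      if (it == index.end()) continue;
      for (int spos : it->second) {
        long diag = (long)qpos - (long)spos;
        auto dc = diag_cover.find(diag);
        if (dc != diag_cover.end() && qpos < dc->second) continue;

        // ungapped X-drop extension around the seed
        int lscore = 0, lbest = 0, li = 0;
        {
          int i2 = qpos - 1, j2 = spos - 1, cur = 0, k = 0;
          while (i2 >= 0 && j2 >= 0) {
            cur += (q[i2] < 4 && q[i2] == s[j2]) ? reward : penalty;
            ++k;
            if (cur >= lbest) { lbest = cur; li = k; }
            if (cur < lbest - xdrop_ungapped) break;
            --i2; --j2;
          }
          lscore = lbest;
        }
        int rscore = 0, rbest = 0, ri = 0;
        {
          int i2 = qpos, j2 = spos, cur = 0, k = 0;
          while (i2 < qlen && j2 < slen) {
            cur += (q[i2] < 4 && q[i2] == s[j2]) ? reward : penalty;
            ++k;
            if (cur >= rbest) { rbest = cur; ri = k; }
            if (cur < rbest - xdrop_ungapped) break;
            ++i2; ++j2;
          }
          rscore = rbest;
        }
        int ungapped = lscore + rscore;
        if (ungapped < gap_trigger) {
          // still mark short coverage so repeated seeds on this diagonal
          // inside the examined window are not re-extended
          continue;
        }

        // gapped extension from the seed start anchor
        int aq = qpos, as = spos;
        ExtRes right = xdrop_extend(&q[aq], qlen - aq, +1,
                                    &s[as], slen - as, +1,
                                    reward, penalty, gap_open, gap_extend,
                                    xdrop_gapped, MAX_CELLS);
        ExtRes left;
        if (aq > 0 && as > 0) {
          left = xdrop_extend(&q[aq - 1], aq, -1,
                              &s[as - 1], as, -1,
                              reward, penalty, gap_open, gap_extend,
                              xdrop_gapped, MAX_CELLS);
        }
        int score = left.score + right.score;
        if (score < min_score) {
          (void)li; (void)ri;
          continue;
        }
        Hsp h;
        h.qs = aq - left.dq; h.qe = aq + right.dq;
        h.ss = as - left.ds; h.se = as + right.ds;
        h.score = score;
        h.ident = left.ident + right.ident;
        h.alen = left.alen + right.alen;
        if (h.qe > h.qs && h.se > h.ss) {
          hsps.push_back(h);
          // cover every diagonal the (possibly gapped) HSP touches, so
          // seeds on indel-shifted diagonals are not re-extended
          long d1 = (long)h.qs - (long)h.ss, d2 = (long)h.qe - (long)h.se;
          if (d1 > d2) std::swap(d1, d2);
          for (long d = d1 - 2; d <= d2 + 2; ++d) {
            int &cov = diag_cover[d];
            if (h.qe > cov) cov = h.qe;
          }
        }
      }
    }
  }

  // Containment dedupe: drop HSPs fully nested in a higher-scoring one.
  std::sort(hsps.begin(), hsps.end(), [](const Hsp &a, const Hsp &b) {
    if (a.score != b.score) return a.score > b.score;
    if (a.qs != b.qs) return a.qs < b.qs;
    return a.ss < b.ss;
  });
  std::vector<Hsp> kept;
  for (const Hsp &h : hsps) {
    bool nested = false;
    for (const Hsp &k : kept) {
      if (h.qs >= k.qs && h.qe <= k.qe && h.ss >= k.ss && h.se <= k.se) {
        nested = true; break;
      }
    }
    if (!nested) kept.push_back(h);
  }
  std::sort(kept.begin(), kept.end(), [](const Hsp &a, const Hsp &b) {
    if (a.qs != b.qs) return a.qs < b.qs;
    if (a.ss != b.ss) return a.ss < b.ss;
    return a.score > b.score;
  });

  int n = kept.size();
  IntegerVector qs(n), qe(n), ss(n), se(n), score(n), ident(n), alen(n);
  for (int i = 0; i < n; ++i) {
    qs[i] = kept[i].qs; qe[i] = kept[i].qe;
    ss[i] = kept[i].ss; se[i] = kept[i].se;
    score[i] = kept[i].score; ident[i] = kept[i].ident; alen[i] = kept[i].alen;
  }
  return DataFrame::create(_["q_start"] = qs, _["q_end"] = qe,
                           _["s_start"] = ss, _["s_end"] = se,
                           _["score"] = score, _["identities"] = ident,
                           _["aln_len"] = alen);
}
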