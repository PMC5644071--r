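#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <algorithm>
#include <random>
#include <cstdint>

using namespace Rcpp;

// Sequences arrive as integer codes: A=0, C=1, G=2, T=3, N=4.
// N never matches anything (scores as a mismatch) and never seeds a word.

namespace {

const int NEG_INF = -1000000000;

struct Anchor {
  int qs, qe, ss, se; // 0-based inclusive
  int score;
};

struct Hit {
  int qs, qe, ss, se; // 0-based inclusive
  int score;
};

inline int subst(int a, int b, int match, int mismatch) {
  return (a == b && a < 4) ? match : mismatch;
}

// Ungapped X-drop extension of an exact word seed at (qi, sj), length w.
Anchor xdrop_extend(const int* q, int m, const int* s, int n,
                    int qi, int sj, int w, int match, int mismatch, int x) {
  Anchor a;
  a.score = w * match;
  a.qs = qi; a.ss = sj;
  a.qe = qi + w - 1; a.se = sj + w - 1;
  // right
  {
    int cur = 0, best = 0, besti = 0;
    int i = a.qe + 1, j = a.se + 1, k = 1;
    while (i < m && j < n) {
      cur += subst(q[i], s[j], match, mismatch);
      if (cur > best) { best = cur; besti = k; }
      if (best - cur > x) break;
      ++i; ++j; ++k;
    }
    a.qe += besti; a.se += besti; a.score += best;
  }
  // left
  {
    int cur = 0, best = 0, besti = 0;
    int i = a.qs - 1, j = a.ss - 1, k = 1;
    while (i >= 0 && j >= 0) {
      cur += subst(q[i], s[j], match, mismatch);
      if (cur > best) { best = cur; besti = k; }
      if (best - cur > x) break;
      --i; --j; ++k;
    }
    a.qs -= besti; a.ss -= besti; a.score += best;
  }
  return a;
}

// Banded local affine-gap DP centred on the anchor diagonal, with origin
// tracking so hit start coordinates are exact.  Gap of length g costs
// gap_open + g * gap_extend.
Hit banded_sw(const int* q, int m, const int* s, int n,
              int d0, int hw, int match, int mismatch,
              int gap_open, int gap_extend) {
  int bw = 2 * hw + 1;
  std::vector<int> Hprev(bw, 0), Hcur(bw, 0);
  std::vector<int> Fprev(bw, NEG_INF), Fcur(bw, NEG_INF);
  std::vector<int64_t> HOprev(bw, -1), HOcur(bw, -1);
  std::vector<int64_t> FOprev(bw, -1), FOcur(bw, -1);

  Hit best; best.score = 0; best.qs = best.qe = best.ss = best.se = -1;
  int64_t best_origin = -1;

  // row i = 0: H over cells (i=-1 conceptually zero) -> initialise prev row
  // as all zeros with invalid origins (handled by loop for i from 0).
  // We iterate query rows 0..m-1; column j = i + d0 + (k - hw).
  for (int i = 0; i < m; ++i) {
    std::fill(Hcur.begin(), Hcur.end(), 0);
    std::fill(Fcur.begin(), Fcur.end(), NEG_INF);
    std::fill(HOcur.begin(), HOcur.end(), -1);
    std::fill(FOcur.begin(), FOcur.end(), -1);
    int Ecur = NEG_INF; int64_t EOcur = -1; // running E within the row
    for (int k = 0; k < bw; ++k) {
      int j = i + d0 + (k - hw);
      if (j < 0 || j >= n) { Ecur = NEG_INF; EOcur = -1; continue; }
      // E: gap in query (move along subject), from cell (i, j-1) = offset k-1
      int e_open = (k > 0) ? Hcur[k - 1] : NEG_INF;
      int e_ext  = Ecur;
      int E = std::max(e_open == NEG_INF ? NEG_INF : e_open - gap_open - gap_extend,
                       e_ext  == NEG_INF ? NEG_INF : e_ext - gap_extend);
      int64_t EO = -1;
      if (E > NEG_INF / 2) {
        if (e_open != NEG_INF && E == e_open - gap_open - gap_extend)
          EO = (k > 0) ? HOcur[k - 1] : -1;
        else EO = EOcur;
      }
      // F: gap in subject (move along query), from cell (i-1, j) = prev offset k+1
      int f_open = (k + 1 < bw) ? Hprev[k + 1] : NEG_INF;
      int f_ext  = (k + 1 < bw) ? Fprev[k + 1] : NEG_INF;
      int F = std::max(f_open == NEG_INF ? NEG_INF : f_open - gap_open - gap_extend,
                       f_ext  == NEG_INF ? NEG_INF : f_ext - gap_extend);
      int64_t FO = -1;
      if (F > NEG_INF / 2) {
        if (f_open != NEG_INF && F == f_open - gap_open - gap_extend)
          FO = (k + 1 < bw) ? HOprev[k + 1] : -1;
        else FO = (k + 1 < bw) ? FOprev[k + 1] : -1;
      }
      // diagonal
      int diag = Hprev[k]; // cell (i-1, j-1) keeps the same offset
      int64_t diagO = HOprev[k];
      int sc = subst(q[i], s[j], match, mismatch);
      int hdiag = diag + sc;
      int64_t hdiagO = (diag == 0 && diagO < 0)
        ? (static_cast<int64_t>(i) << 32 | static_cast<uint32_t>(j))
        : diagO;

      int H = 0; int64_t HO = -1;
      if (hdiag > H) { H = hdiag; HO = hdiagO; }
      if (E > H)     { H = E;     HO = EO; }
      if (F > H)     { H = F;     HO = FO; }

      Hcur[k] = H; HOcur[k] = HO;
      Fcur[k] = F; FOcur[k] = FO;
      Ecur = E; EOcur = EO;

      if (H > best.score && HO >= 0) {
        best.score = H; best.qe = i; best.se = j; best_origin = HO;
      }
    }
    std::swap(Hprev, Hcur); std::swap(HOprev, HOcur);
    std::swap(Fprev, Fcur); std::swap(FOprev, FOcur);
  }
  if (best.score > 0 && best_origin >= 0) {
    best.qs = static_cast<int>(best_origin >> 32);
    best.ss = static_cast<int>(best_origin & 0xffffffff);
  }
  return best;
}

} // namespace

// [[Rcpp::export(name = ".cpp_seed_extend")]]
DataFrame cpp_seed_extend(IntegerVector query, IntegerVector subject,
                          int match, int mismatch,
                          int gap_open, int gap_extend,
                          int word_size, int xdrop, int band,
                          int gapped_trigger, int min_score) {
  int m = query.size(), n = subject.size();
  std::vector<int> qsv, qev, ssv, sev, scv;
  if (m >= word_size && n >= word_size) {
    const int* q = INTEGER(query);
    const int* s = INTEGER(subject);
    int w = word_size;
    // index query words (base-4 codes; words containing N are skipped)
    std::unordered_map<uint64_t, std::vector<int> > index;
    {
      uint64_t code = 0, mask = (1ULL << (2 * w)) - 1;
      int run = 0; // length of current N-free run
      for (int i = 0; i < m; ++i) {
        if (q[i] >= 4) { run = 0; code = 0; continue; }
        code = ((code << 2) | static_cast<uint64_t>(q[i])) & mask;
        if (++run >= w) index[code].push_back(i - w + 1);
      }
    }
    // scan subject, collect anchors with per-diagonal coverage dedup
    std::vector<Anchor> anchors;
    std::unordered_map<int, int> covered; // diagonal -> subject pos covered through
    {
      uint64_t code = 0, mask = (1ULL << (2 * w)) - 1;
      int run = 0;
      for (int j = 0; j < n; ++j) {
        if (s[j] >= 4) { run = 0; code = 0; continue; }
        code = ((code << 2) | static_cast<uint64_t>(s[j])) & mask;
        if (++run < w) continue;
        auto it = index.find(code);
        if (it == index.end()) continue;
        int sj = j - w + 1;
        for (int qi : it->second) {
          int d = sj - qi;
          auto cit = covered.find(d);
          if (cit != covered.end() && sj <= cit->second) continue;
          Anchor a = xdrop_extend(q, m, s, n, qi, sj, w, match, mismatch, xdrop);
          covered[d] = a.se;
          if (a.score >= gapped_trigger) anchors.push_back(a);
        }
      }
    }
    // gapped extension of anchors, strongest first; skip anchors already
    // inside an accepted hit's band
    std::sort(anchors.begin(), anchors.end(),
              [](const Anchor& a, const Anchor& b) { return a.score > b.score; });
    int hw = (band - 1) / 2;
    std::vector<Hit> hits;
    for (const Anchor& a : anchors) {
      int d = a.ss - a.qs;
      bool dup = false;
      for (const Hit& h : hits) {
        int hd1 = h.ss - h.qs, hd2 = h.se - h.qe;
        int lo = std::min(hd1, hd2) - hw, hi = std::max(hd1, hd2) + hw;
        if (d >= lo && d <= hi && a.ss <= h.se && a.se >= h.ss) { dup = true; break; }
      }
      if (dup) continue;
      Hit h = banded_sw(q, m, s, n, d, hw, match, mismatch, gap_open, gap_extend);
      if (h.score >= std::max(min_score, 1) && h.qs >= 0) hits.push_back(h);
    }
    // merge overlapping hits (subject interval), keeping max score
    std::sort(hits.begin(), hits.end(),
              [](const Hit& a, const Hit& b) { return a.score > b.score; });
    std::vector<Hit> kept;
    for (const Hit& h : hits) {
      bool ovl = false;
      for (const Hit& k2 : kept)
        if (h.ss <= k2.se && h.se >= k2.ss) { ovl = true; break; }
      if (!ovl) kept.push_back(h);
    }
    for (const Hit& h : kept) {
      qsv.push_back(h.qs + 1); qev.push_back(h.qe + 1);
      ssv.push_back(h.ss + 1); sev.push_back(h.se + 1);
      scv.push_back(h.score);
    }
  }
  return DataFrame::create(_["qstart"] = qsv, _["qend"] = qev,
                           _["sstart"] = ssv, _["send"] = sev,
                           _["score"] = scv);
}

// Max ungapped local segment score per random sequence pair, for fitting the
// Karlin-Altschul K by simulation.  Kadane scan along every diagonal.
// [[Rcpp::export(name = ".cpp_sim_max_ungapped")]]
IntegerVector cpp_sim_max_ungapped(int n_pairs, int L,
                                   int match, int mismatch,
                                   NumericVector freqs, int seed) {
  std::mt19937 rng(static_cast<uint32_t>(seed));
  std::discrete_distribution<int> base({freqs[0], freqs[1], freqs[2], freqs[3]});
  IntegerVector out(n_pairs);
  std::vector<int> a(L), b(L);
  for (int p = 0; p < n_pairs; ++p) {
    for (int i = 0; i < L; ++i) { a[i] = base(rng); b[i] = base(rng); }
    int best = 0;
    for (int d = -(L - 1); d <= L - 1; ++d) {
      int i0 = std::max(0, -d), i1 = std::min(L, L - d);
      int cur = 0;
      for (int i = i0; i < i1; ++i) {
        cur += (a[i] == b[i + d]) ? match : mismatch;
        if (cur < 0) cur = 0;
        else if (cur > best) best = cur;
      }
    }
    out[p] = best;
  }
  return out;
}
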