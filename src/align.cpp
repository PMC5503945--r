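// Banded affine-gap (Gotoh) pairwise alignment, a semi-global
// edit-distance scan, and the balance-constrained run-length dynamic
// program: the compute kernels behind the consensus and polishing
// pipeline. Scores: match > mismatch, gap_open/gap_extend <= 0; a gap of
// length L costs gap_open + L * gap_extend.

#include <Rcpp.h>
#include <cstring>
#include <limits>
#include <string>
#include <vector>

using namespace Rcpp;

static const double NEG_INF = -1e30;

struct BandedResult {
  std::string a_gapped;
  std::string b_gapped;
  double score;
};

// Scores kept as two rolling rows; full traceback kept as 2-bit codes per
// state in byte arrays (reused across calls).
static BandedResult align_banded_core(const std::string& a,
                                      const std::string& b,
                                      double match, double mismatch,
                                      double gap_open, double gap_extend,
                                      int band) {
  const int n = (int)a.size();
  const int m = (int)b.size();
  int W = band + std::abs(n - m);
  if (W < 1) W = 1;
  if (W > std::max(n, m)) W = std::max(n, m);
  const int width = 2 * W + 1;

  static std::vector<double> Mprev, Xprev, Yprev, Mcur, Xcur, Ycur;
  static std::vector<unsigned char> tb; // 3 states packed per cell: 2 bits each
  Mprev.assign(width + 2, NEG_INF);
  Xprev.assign(width + 2, NEG_INF);
  Yprev.assign(width + 2, NEG_INF);
  Mcur.assign(width + 2, NEG_INF);
  Xcur.assign(width + 2, NEG_INF);
  Ycur.assign(width + 2, NEG_INF);
  tb.assign((size_t)(n + 1) * width, 0);

  // offset within a row: off = j - i + W, valid 0..2W; rows padded by one
  // sentinel cell on each side (index off+1 in the rolling arrays)
  auto row_tb = [&](int i) { return &tb[(size_t)i * width]; };

  // row 0
  Mprev[W + 1] = 0.0; // (0,0)
  for (int j = 1; j <= m && j <= W; ++j) {
    Yprev[j + W + 1] = gap_open + gap_extend * j;
    row_tb(0)[j + W] |= (1 << 4); // Y extend flag (code 1 in Y slot)
  }

  const double go_ge = gap_open + gap_extend;
  for (int i = 1; i <= n; ++i) {
    int jlo = i - W; if (jlo < 1) jlo = 1;
    int jhi = i + W; if (jhi > m) jhi = m;
    std::fill(Mcur.begin(), Mcur.end(), NEG_INF);
    std::fill(Xcur.begin(), Xcur.end(), NEG_INF);
    std::fill(Ycur.begin(), Ycur.end(), NEG_INF);
    if (jlo == 1 && i <= W) { // (i, 0) start gap in b
      Xcur[0 - i + W + 1] = gap_open + gap_extend * i;
      row_tb(i)[0 - i + W] |= (1 << 2); // X extend
    }
    unsigned char* trow = row_tb(i);
    const char ai = a[i - 1];
    for (int j = jlo; j <= jhi; ++j) {
      const int off = j - i + W;       // this row
      // prev row offsets: (i-1, j-1) -> off; (i-1, j) -> off + 1
      // cur row: (i, j-1) -> off - 1
      unsigned char code = 0;
      // M from diagonal (i-1, j-1)
      {
        double best = Mprev[off + 1];
        unsigned char t = 0;
        if (Xprev[off + 1] > best) { best = Xprev[off + 1]; t = 1; }
        if (Yprev[off + 1] > best) { best = Yprev[off + 1]; t = 2; }
        if (best > NEG_INF / 2) {
          Mcur[off + 1] = best + (ai == b[j - 1] ? match : mismatch);
          code |= t; // bits 0-1
        }
      }
      // X (gap in b) from (i-1, j)
      {
        double open_sc = Mprev[off + 2];
        open_sc = (open_sc > NEG_INF / 2) ? open_sc + go_ge : NEG_INF;
        double ext_sc = Xprev[off + 2];
        ext_sc = (ext_sc > NEG_INF / 2) ? ext_sc + gap_extend : NEG_INF;
        if (open_sc >= ext_sc) Xcur[off + 1] = open_sc;
        else { Xcur[off + 1] = ext_sc; code |= (1 << 2); }
      }
      // Y (gap in a) from (i, j-1)
      {
        double open_sc = Mcur[off];
        open_sc = (open_sc > NEG_INF / 2) ? open_sc + go_ge : NEG_INF;
        double ext_sc = Ycur[off];
        ext_sc = (ext_sc > NEG_INF / 2) ? ext_sc + gap_extend : NEG_INF;
        if (open_sc >= ext_sc) Ycur[off + 1] = open_sc;
        else { Ycur[off + 1] = ext_sc; code |= (1 << 4); }
      }
      trow[off] = code;
    }
    std::swap(Mprev, Mcur);
    std::swap(Xprev, Xcur);
    std::swap(Yprev, Ycur);
  }

  const int off_end = m - n + W;
  int state = 0;
  double best = Mprev[off_end + 1];
  if (Xprev[off_end + 1] > best) { best = Xprev[off_end + 1]; state = 1; }
  if (Yprev[off_end + 1] > best) { best = Yprev[off_end + 1]; state = 2; }

  std::string ag, bg;
  ag.reserve(n + m);
  bg.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const int off = j - i + W;
    const unsigned char code = row_tb(i)[off];
    if (state == 0) {
      ag.push_back(a[i - 1]);
      bg.push_back(b[j - 1]);
      state = code & 3;
      --i; --j;
    } else if (state == 1) {
      ag.push_back(a[i - 1]);
      bg.push_back('-');
      state = ((code >> 2) & 3) ? 1 : 0;
      --i;
    } else {
      ag.push_back('-');
      bg.push_back(b[j - 1]);
      state = ((code >> 4) & 3) ? 2 : 0;
      --j;
    }
  }
  std::reverse(ag.begin(), ag.end());
  std::reverse(bg.begin(), bg.end());
  BandedResult res;
  res.a_gapped = ag;
  res.b_gapped = bg;
  res.score = best;
  return res;
}

// [[Rcpp::export]]
List cpp_align_banded(std::string a, std::string b,
                      double match, double mismatch,
                      double gap_open, double gap_extend, int band) {
  if (a.empty() || b.empty())
    stop("cpp_align_banded: empty sequence");
  BandedResult r = align_banded_core(a, b, match, mismatch,
                                     gap_open, gap_extend, band);
  return List::create(_["a"] = r.a_gapped, _["b"] = r.b_gapped,
                      _["score"] = r.score);
}

// [[Rcpp::export]]
List cpp_align_many(CharacterVector reads, std::string ref,
                    double match, double mismatch,
                    double gap_open, double gap_extend, int band) {
  const int n = reads.size();
  List out(n);
  for (int k = 0; k < n; ++k) {
    std::string a = as<std::string>(reads[k]);
    BandedResult r = align_banded_core(a, ref, match, mismatch,
                                       gap_open, gap_extend, band);
    out[k] = List::create(_["a"] = r.a_gapped, _["b"] = r.b_gapped,
                          _["score"] = r.score);
  }
  return out;
}

static int infix_distance_core(const std::string& pattern,
                               const std::string& text) {
  const int n = (int)pattern.size();
  const int m = (int)text.size();
  if (n == 0) return 0;
  if (m == 0) return n;
  static std::vector<int> prev, cur;
  prev.assign(m + 1, 0);
  cur.assign(m + 1, 0);
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    const char pi = pattern[i - 1];
    for (int j = 1; j <= m; ++j) {
      int v = prev[j - 1] + (pi == text[j - 1] ? 0 : 1);
      const int del = prev[j] + 1;
      const int ins = cur[j - 1] + 1;
      if (del < v) v = del;
      if (ins < v) v = ins;
      cur[j] = v;
    }
    std::swap(prev, cur);
  }
  int best = prev[0];
  for (int j = 1; j <= m; ++j) if (prev[j] < best) best = prev[j];
  return best;
}

// Minimum unit-cost edit distance of `pattern` against any substring of
// `text` (free start and end in text).
// [[Rcpp::export]]
int cpp_infix_distance(std::string pattern, std::string text) {
  return infix_distance_core(pattern, text);
}

// Batched form: distance matrix of every pattern against every text.
// [[Rcpp::export]]
IntegerMatrix cpp_infix_distance_many(CharacterVector patterns,
                                      CharacterVector texts) {
  IntegerMatrix out(texts.size(), patterns.size());
  for (int p = 0; p < patterns.size(); ++p) {
    std::string pat = as<std::string>(patterns[p]);
    for (int t = 0; t < texts.size(); ++t) {
      out(t, p) = infix_distance_core(pat, as<std::string>(texts[t]));
    }
  }
  return out;
}

// Balance-constrained run-length assignment (see balance_dp in R):
// choose one candidate length per run maximising total weight, with
// penalty BIG per completed window whose GC count is not target_gc.
// State: pos_in_window * (window+1) + gc. Returns chosen candidate index
// (1-based) per run and the flag count at the optimum.
// [[Rcpp::export]]
List cpp_balance_dp(List cand, List weight, LogicalVector is_gc,
                    IntegerVector fixed, int window, int target_gc,
                    double big, int pos0, int gc0) {
  const int nruns = cand.size();
  const int nstate = window * (window + 1);
  std::vector<double> value(nstate, NEG_INF), value2(nstate);
  std::vector<int> flags(nstate, 0), flags2(nstate);
  std::vector<int> bp_state((size_t)nruns * nstate, -1);
  std::vector<int> bp_cand((size_t)nruns * nstate, -1);
  value[pos0 * (window + 1) + gc0] = 0.0;

  for (int k = 0; k < nruns; ++k) {
    IntegerVector ck = cand[k];
    NumericVector wk = weight[k];
    const int g = is_gc[k] ? 1 : 0;
    std::fill(value2.begin(), value2.end(), NEG_INF);
    std::fill(flags2.begin(), flags2.end(), 0);
    int* bps = &bp_state[(size_t)k * nstate];
    int* bpc = &bp_cand[(size_t)k * nstate];
    for (int s = 0; s < nstate; ++s) {
      if (value[s] <= NEG_INF / 2) continue;
      const int pos = s / (window + 1);
      const int gc = s % (window + 1);
      for (int ci = 0; ci < ck.size(); ++ci) {
        const int mlen = ck[ci] - fixed[k];
        int npos, ngc, pen = 0;
        if (mlen < window - pos) {
          npos = pos + mlen;
          ngc = gc + g * mlen;
        } else {
          pen = (gc + g * (window - pos) != target_gc) ? 1 : 0;
          const int m2 = mlen - (window - pos);
          pen += m2 / window; // full single-symbol windows: never balanced
          npos = m2 % window;
          ngc = g * npos;
        }
        const double val = value[s] + wk[ci] - big * pen;
        const int ns = npos * (window + 1) + ngc;
        bool better = val > value2[ns];
        if (!better && val == value2[ns] && bpc[ns] >= 0 &&
            ck[ci] > ck[bpc[ns]]) {
          better = true;
        }
        if (better) {
          value2[ns] = val;
          flags2[ns] = flags[s] + pen;
          bps[ns] = s;
          bpc[ns] = ci;
        }
      }
    }
    std::swap(value, value2);
    std::swap(flags, flags2);
  }
  int sbest = 0;
  for (int s = 1; s < nstate; ++s) if (value[s] > value[sbest]) sbest = s;
  IntegerVector lengths(nruns);
  int s = sbest;
  for (int k = nruns - 1; k >= 0; --k) {
    IntegerVector ck = cand[k];
    lengths[k] = ck[bp_cand[(size_t)k * nstate + s]];
    s = bp_state[(size_t)k * nstate + s];
  }
  return List::create(_["lengths"] = lengths, _["flags"] = flags[sbest]);
}
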