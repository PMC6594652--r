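#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Gotoh local alignment (affine gaps) with full traceback.
// Scores: match/mismatch per pair; a gap of length L costs
// gap_open + L * gap_extend (both supplied as negative numbers).
// Tie-break: the first maximal cell in row-major order is kept, which
// for equal-shape placements selects the smallest reference offset.

static inline int subst(char a, char b, int match, int mismatch) {
  if (a == 'N' || b == 'N') return mismatch;
  return (a == b) ? match : mismatch;
}

// [[Rcpp::export(name = ".sw_local")]]
List sw_local(std::string query, std::string subject,
              int match, int mismatch, int gap_open, int gap_extend) {
  const int n = (int) query.size();
  const int m = (int) subject.size();
  const int NEG = -1000000;
  // H, E (gap consuming subject), F (gap consuming query), row-major (n+1)x(m+1)
  std::vector<int> H((size_t)(n + 1) * (m + 1), 0);
  std::vector<int> E((size_t)(n + 1) * (m + 1), NEG);
  std::vector<int> F((size_t)(n + 1) * (m + 1), NEG);
  int best = 0, bi = 0, bj = 0, nbest = 0;
  const int goe = gap_open + gap_extend;
  for (int i = 1; i <= n; ++i) {
    int *Hr = &H[(size_t) i * (m + 1)];
    const int *Hp = &H[(size_t)(i - 1) * (m + 1)];
    int *Er = &E[(size_t) i * (m + 1)];
    int *Fr = &F[(size_t) i * (m + 1)];
    const int *Fp = &F[(size_t)(i - 1) * (m + 1)];
    const char qc = query[i - 1];
    for (int j = 1; j <= m; ++j) {
      int e = Hr[j - 1] + goe;
      const int e2 = Er[j - 1] + gap_extend;
      if (e2 > e) e = e2;
      int f = Hp[j] + goe;
      const int f2 = Fp[j] + gap_extend;
      if (f2 > f) f = f2;
      const char sc = subject[j - 1];
      int h = Hp[j - 1] +
        ((qc == sc && qc != 'N') ? match : mismatch);
      if (e > h) h = e;
      if (f > h) h = f;
      if (h < 0) h = 0;
      Er[j] = e; Fr[j] = f; Hr[j] = h;
      if (h > best) { best = h; bi = i; bj = j; nbest = 1; }
      else if (h == best && best > 0) { ++nbest; }
    }
  }
  if (best <= 0) {
    return List::create(_["score"] = 0, _["q_start"] = 0, _["q_end"] = 0,
                        _["s_start"] = 0, _["s_end"] = 0, _["matches"] = 0,
                        _["mismatches"] = 0, _["ins"] = 0, _["del"] = 0,
                        _["cigar"] = "", _["n_best"] = 0);
  }
  // traceback
  int i = bi, j = bj, matches = 0, mism = 0, ins = 0, del = 0;
  std::string ops;  // reversed ops, one char per column: M/X/I/D
  int state = 0;    // 0 = H, 1 = E, 2 = F
  while (i > 0 || j > 0) {
    const size_t r = (size_t) i * (m + 1), p = (size_t)(i - 1) * (m + 1);
    if (state == 0) {
      int h = H[r + j];
      if (h == 0) break;
      int d = (i > 0 && j > 0)
        ? H[p + j - 1] + subst(query[i - 1], subject[j - 1], match, mismatch)
        : NEG;
      if (i > 0 && j > 0 && h == d) {
        bool eq = (query[i - 1] == subject[j - 1] &&
                   query[i - 1] != 'N' && subject[j - 1] != 'N');
        ops.push_back(eq ? 'M' : 'X');
        if (eq) ++matches; else ++mism;
        --i; --j;
      } else if (h == E[r + j]) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {   // gap consuming subject: deletion from read
      ops.push_back('D'); ++del;
      int e = E[(size_t) i * (m + 1) + j];
      int fromH = H[(size_t) i * (m + 1) + j - 1] + gap_open + gap_extend;
      --j;
      if (e == fromH) state = 0;
    } else {                   // gap consuming query: insertion in read
      ops.push_back('I'); ++ins;
      int f = F[(size_t) i * (m + 1) + j];
      int fromH = H[p + j] + gap_open + gap_extend;
      --i;
      if (f == fromH) state = 0;
    }
  }
  // compress reversed ops into a cigar string
  std::string cigar;
  int runlen = 0; char runop = 0;
  for (int k = (int) ops.size() - 1; k >= 0; --k) {
    char op = ops[k];
    if (op == 'X') op = 'M';
    if (op == runop) { ++runlen; }
    else {
      if (runlen > 0) { cigar += std::to_string(runlen); cigar.push_back(runop); }
      runop = op; runlen = 1;
    }
  }
  if (runlen > 0) { cigar += std::to_string(runlen); cigar.push_back(runop); }
  return List::create(_["score"] = best,
                      _["q_start"] = i, _["q_end"] = bi,
                      _["s_start"] = j, _["s_end"] = bj,
                      _["matches"] = matches, _["mismatches"] = mism,
                      _["ins"] = ins, _["del"] = del,
                      _["cigar"] = cigar, _["n_best"] = nbest);
}

// Gapless diagonal repeat scan between two sequences.  For every diagonal,
// windows of length `window` with >= min_identity matching positions (and no
// N) qualify; overlapping qualifying windows on a diagonal are merged into
// one hit.  Returns a matrix with columns
// a_start, a_end, b_start, b_end, matches, length (0-based half-open).
// [[Rcpp::export(name = ".diag_repeats")]]
IntegerMatrix diag_repeats(std::string a, std::string b,
                           int window, double min_identity,
                           bool exclude_main_diagonal) {
  const int la = (int) a.size(), lb = (int) b.size();
  const int need = (int) std::ceil(min_identity * window);
  std::vector<int> out;
  for (int d = -(la - 1); d <= lb - 1; ++d) {
    if (exclude_main_diagonal && d == 0) continue;
    int ai0 = std::max(0, -d);          // a index where diagonal starts
    int bi0 = ai0 + d;
    int len = std::min(la - ai0, lb - bi0);
    if (len < window) continue;
    // match / N indicator along the diagonal
    std::vector<int> mt(len), nn(len);
    for (int k = 0; k < len; ++k) {
      char ca = a[ai0 + k], cb = b[bi0 + k];
      nn[k] = (ca == 'N' || cb == 'N') ? 1 : 0;
      mt[k] = (!nn[k] && ca == cb) ? 1 : 0;
    }
    // sliding sums
    int ms = 0, ns = 0;
    int cur_s = -1, cur_e = -1;   // current merged hit (diagonal offsets)
    for (int k = 0; k < len - window + 1; ++k) {
      if (k == 0) {
        for (int t = 0; t < window; ++t) { ms += mt[t]; ns += nn[t]; }
      } else {
        ms += mt[k + window - 1] - mt[k - 1];
        ns += nn[k + window - 1] - nn[k - 1];
      }
      bool ok = (ms >= need && ns == 0);
      if (ok) {
        if (cur_s < 0) { cur_s = k; cur_e = k + window; }
        else if (k <= cur_e) { cur_e = k + window; }   // overlaps/abuts: extend
        else {
          int mm = 0; for (int t = cur_s; t < cur_e; ++t) mm += mt[t];
          out.push_back(ai0 + cur_s); out.push_back(ai0 + cur_e);
          out.push_back(bi0 + cur_s); out.push_back(bi0 + cur_e);
          out.push_back(mm); out.push_back(cur_e - cur_s);
          cur_s = k; cur_e = k + window;
        }
      }
    }
    if (cur_s >= 0) {
      int mm = 0; for (int t = cur_s; t < cur_e; ++t) mm += mt[t];
      out.push_back(ai0 + cur_s); out.push_back(ai0 + cur_e);
      out.push_back(bi0 + cur_s); out.push_back(bi0 + cur_e);
      out.push_back(mm); out.push_back(cur_e - cur_s);
    }
  }
  int nh = (int) out.size() / 6;
  IntegerMatrix res(nh, 6);
  for (int r = 0; r < nh; ++r)
    for (int c = 0; c < 6; ++c) res(r, c) = out[(size_t) r * 6 + c];
  colnames(res) = CharacterVector::create("a_start", "a_end", "b_start",
                                          "b_end", "matches", "length");
  return res;
}
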