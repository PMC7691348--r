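#include <Rcpp.h>
#include <climits>
#include <vector>
#include <string>
using namespace Rcpp;

// Affine-gap scoring convention used throughout: match > 0; mismatch, gap_open,
// gap_extend <= 0; a gap of length g scores gap_open + g * gap_extend.

static const int NEG = INT_MIN / 4;

// Smith-Waterman local alignment score (score only, rolling rows).
static int sw_score_pair(const char* a, int la, const char* b, int lb,
                         int match, int mismatch, int gap_open, int gap_extend) {
  if (la == 0 || lb == 0) return 0;
  std::vector<int> H(lb + 1, 0), E(lb + 1, NEG);
  int best = 0;
  for (int i = 1; i <= la; ++i) {
    int Hdiag = 0;   // H[i-1][j-1]
    int F = NEG;     // gap in b, running along the row
    int Hleft = 0;   // H[i][j-1]
    for (int j = 1; j <= lb; ++j) {
      E[j] = std::max(E[j] + gap_extend, H[j] + gap_open + gap_extend);
      F = std::max(F + gap_extend, Hleft + gap_open + gap_extend);
      int s = Hdiag + ((a[i - 1] == b[j - 1]) ? match : mismatch);
      int h = std::max(0, std::max(s, std::max(E[j], F)));
      Hdiag = H[j];
      H[j] = h;
      Hleft = h;
      if (h > best) best = h;
    }
  }
  return best;
}

// [[Rcpp::export]]
int cpp_sw_score(std::string a, std::string b, int match, int mismatch,
                 int gap_open, int gap_extend) {
  return sw_score_pair(a.c_str(), a.size(), b.c_str(), b.size(),
                       match, mismatch, gap_open, gap_extend);
}

// One seed against many candidates (the inner loop of greedy clustering).
// [[Rcpp::export]]
IntegerVector cpp_sw_scores(std::string seed, CharacterVector others, int match,
                            int mismatch, int gap_open, int gap_extend) {
  int n = others.size();
  IntegerVector out(n);
  const char* s = seed.c_str();
  int ls = seed.size();
  for (int k = 0; k < n; ++k) {
    const char* o = CHAR(STRING_ELT(others, k));
    out[k] = sw_score_pair(s, ls, o, LENGTH(STRING_ELT(others, k)),
                           match, mismatch, gap_open, gap_extend);
  }
  return out;
}

// Symmetric all-vs-all score matrix (used for threshold scans on a sample).
// [[Rcpp::export]]
IntegerMatrix cpp_sw_matrix(CharacterVector seqs, int match, int mismatch,
                            int gap_open, int gap_extend) {
  int n = seqs.size();
  IntegerMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    const char* a = CHAR(STRING_ELT(seqs, i));
    int la = LENGTH(STRING_ELT(seqs, i));
    out(i, i) = sw_score_pair(a, la, a, la, match, mismatch, gap_open, gap_extend);
    for (int j = i + 1; j < n; ++j) {
      const char* b = CHAR(STRING_ELT(seqs, j));
      int s = sw_score_pair(a, la, b, LENGTH(STRING_ELT(seqs, j)),
                            match, mismatch, gap_open, gap_extend);
      out(i, j) = s;
      out(j, i) = s;
    }
  }
  return out;
}

// Locate the best local hit of `pattern` in `subject`; returns the score and
// the 0-based exclusive end positions of the hit on both sequences. The
// first-found maximum is kept, giving the leftmost optimal end
// deterministically. pattern_end < pattern length means the hit clipped the
// pattern tail (e.g. read errors in the last probe bases).
// [[Rcpp::export]]
List cpp_sw_locate(std::string pattern, std::string subject, int match,
                   int mismatch, int gap_open, int gap_extend) {
  int la = pattern.size(), lb = subject.size();
  const char* a = pattern.c_str();
  const char* b = subject.c_str();
  std::vector<int> H(lb + 1, 0), E(lb + 1, NEG);
  int best = 0, best_end = 0, best_pat_end = 0;
  for (int i = 1; i <= la; ++i) {
    int Hdiag = 0, F = NEG, Hleft = 0;
    for (int j = 1; j <= lb; ++j) {
      E[j] = std::max(E[j] + gap_extend, H[j] + gap_open + gap_extend);
      F = std::max(F + gap_extend, Hleft + gap_open + gap_extend);
      int s = Hdiag + ((a[i - 1] == b[j - 1]) ? match : mismatch);
      int h = std::max(0, std::max(s, std::max(E[j], F)));
      Hdiag = H[j];
      H[j] = h;
      Hleft = h;
      if (h > best) { best = h; best_end = j; best_pat_end = i; }
    }
  }
  return List::create(_["score"] = best, _["subject_end"] = best_end,
                      _["pattern_end"] = best_pat_end);
}

// Overlap (end-gap-free, "glocal") alignment of a read against a reference with
// affine gaps and full traceback. End gaps on both sequences are free, so
// construct flanks (barcode / probe / UMI) that are absent from the reference
// are clipped rather than forced into the alignment. Returns the covered
// reference span and an edit list in 0-based reference coordinates:
//   op 1 = substitution (ref allele, alt allele, both length 1)
//   op 2 = insertion before reference position pos (ref "", alt = inserted seq)
//   op 3 = deletion of ref bases starting at pos (alt "")
// Indels are reported as traced; left-normalisation happens on the R side.
// [[Rcpp::export]]
List cpp_align_overlap(std::string read, std::string ref, int match,
                       int mismatch, int gap_open, int gap_extend) {
  int la = read.size(), lb = ref.size();
  if (la == 0 || lb == 0)
    stop("empty sequence in alignment");
  const char* a = read.c_str();
  const char* b = ref.c_str();

  size_t ncell = (size_t)(la + 1) * (size_t)(lb + 1);
  // traceback: tbH 0=diag 1=fromE 2=fromF ; tbE/tbF 1=extension 0=opened from H
  // buffers persist across calls to avoid reallocating megabytes per read
  static std::vector<unsigned char> tbH, tbE, tbF;
  if (tbH.size() < ncell) {
    tbH.resize(ncell); tbE.resize(ncell); tbF.resize(ncell);
  }
  std::vector<int> Hprev(lb + 1, 0), Hcur(lb + 1, 0), E(lb + 1, NEG);
  std::vector<int> lastcol(la + 1, 0);  // H[i][lb]

  for (int i = 1; i <= la; ++i) {
    Hcur[0] = 0;  // free leading gap on the read
    int F = NEG;
    for (int j = 1; j <= lb; ++j) {
      size_t c = (size_t)i * (lb + 1) + j;
      int e_ext = E[j] + gap_extend;
      int e_open = Hprev[j] + gap_open + gap_extend;
      if (e_ext > e_open) { E[j] = e_ext; tbE[c] = 1; } else { E[j] = e_open; tbE[c] = 0; }
      int f_ext = F + gap_extend;
      int f_open = Hcur[j - 1] + gap_open + gap_extend;
      if (f_ext > f_open) { F = f_ext; tbF[c] = 1; } else { F = f_open; tbF[c] = 0; }
      int s = Hprev[j - 1] + ((a[i - 1] == b[j - 1]) ? match : mismatch);
      int h = s; unsigned char t = 0;
      if (E[j] > h) { h = E[j]; t = 1; }
      if (F > h)    { h = F;    t = 2; }
      Hcur[j] = h;
      tbH[c] = t;
    }
    lastcol[i] = Hcur[lb];
    std::swap(Hprev, Hcur);
  }
  // after the loop Hprev holds row la
  int best = NEG, bi = la, bj = 0;
  for (int j = 0; j <= lb; ++j)
    if (Hprev[j] > best) { best = Hprev[j]; bi = la; bj = j; }
  for (int i = 0; i <= la; ++i)
    if (lastcol[i] > best) { best = lastcol[i]; bi = i; bj = lb; }

  // traceback
  std::vector<int> pos_r, op_r;
  std::vector<std::string> ref_r, alt_r;
  int i = bi, j = bj, state = 0;  // 0=H 1=E 2=F
  while (true) {
    size_t c = (size_t)i * (lb + 1) + j;
    if (state == 0) {
      if (i == 0 || j == 0) break;
      unsigned char t = tbH[c];
      if (t == 0) {
        if (a[i - 1] != b[j - 1]) {
          pos_r.push_back(j - 1); op_r.push_back(1);
          ref_r.push_back(std::string(1, b[j - 1]));
          alt_r.push_back(std::string(1, a[i - 1]));
        }
        --i; --j;
      } else {
        state = t;  // enter E or F at the same cell
      }
    } else if (state == 1) {  // insertion: consumes read base
      pos_r.push_back(j); op_r.push_back(2);
      ref_r.push_back("");
      alt_r.push_back(std::string(1, a[i - 1]));
      unsigned char t = tbE[c];
      --i;
      if (t == 0) state = 0;
    } else {  // deletion: consumes ref base
      pos_r.push_back(j - 1); op_r.push_back(3);
      ref_r.push_back(std::string(1, b[j - 1]));
      alt_r.push_back("");
      unsigned char t = tbF[c];
      --j;
      if (t == 0) state = 0;
    }
  }
  int ref_start = j, read_start = i;

  // reverse and merge runs of identical ops into events
  std::vector<int> pos_m, op_m;
  std::vector<std::string> ref_m, alt_m;
  for (int k = (int)pos_r.size() - 1; k >= 0; --k) {
    int p = pos_r[k], o = op_r[k];
    bool merged = false;
    if (!pos_m.empty() && o != 1 && op_m.back() == o) {
      if (o == 2 && pos_m.back() == p) {  // same insertion point
        alt_m.back() += alt_r[k];
        merged = true;
      } else if (o == 3 && pos_m.back() + (int)ref_m.back().size() == p) {
        ref_m.back() += ref_r[k];
        merged = true;
      }
    }
    if (!merged) {
      pos_m.push_back(p); op_m.push_back(o);
      ref_m.push_back(ref_r[k]); alt_m.push_back(alt_r[k]);
    }
  }

  return List::create(
    _["score"] = best,
    _["ref_start"] = ref_start, _["ref_end"] = bj,
    _["read_start"] = read_start, _["read_end"] = bi,
    _["pos"] = wrap(pos_m), _["op"] = wrap(op_m),
    _["ref"] = wrap(ref_m), _["alt"] = wrap(alt_m));
}
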