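#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Shared helpers for the alignment kernels. Ambiguity symbols (N for DNA,
// X for peptides) and gap characters never match anything, themselves
// included, so every "matches" count is a count of unambiguous identities.

static inline bool is_ambig(char c, const std::string &ambig) {
  return ambig.find(c) != std::string::npos;
}

static inline bool chr_match(char a, char b, const std::string &ambig) {
  if (a != b) return false;
  return !is_ambig(a, ambig);
}

// Needleman-Wunsch global alignment with linear gap cost and a fully
// deterministic traceback (diagonal preferred over up (gap in b) over left
// (gap in a)). Returns the aligned strings plus match/column counts.
// [[Rcpp::export]]
List cpp_nw_align(std::string a, std::string b,
                  double match = 1.0, double mismatch = -1.0,
                  double gap = -2.0, std::string ambig = "NX-") {
  const int n = a.size(), m = b.size();
  NumericMatrix F(n + 1, m + 1);
  // trace: 0 diag, 1 up (consume a), 2 left (consume b)
  IntegerMatrix T(n + 1, m + 1);
  for (int i = 1; i <= n; ++i) { F(i, 0) = i * gap; T(i, 0) = 1; }
  for (int j = 1; j <= m; ++j) { F(0, j) = j * gap; T(0, j) = 2; }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = chr_match(a[i - 1], b[j - 1], ambig) ? match : mismatch;
      double diag = F(i - 1, j - 1) + s;
      double up   = F(i - 1, j) + gap;
      double left = F(i, j - 1) + gap;
      double best = diag; int t = 0;
      if (up > best)   { best = up;   t = 1; }
      if (left > best) { best = left; t = 2; }
      F(i, j) = best; T(i, j) = t;
    }
  }
  std::string aa, bb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int t = T(i, j);
    if (i > 0 && j > 0 && t == 0) {
      aa.push_back(a[i - 1]); bb.push_back(b[j - 1]); --i; --j;
    } else if (i > 0 && (t == 1 || j == 0)) {
      aa.push_back(a[i - 1]); bb.push_back('-'); --i;
    } else {
      aa.push_back('-'); bb.push_back(b[j - 1]); --j;
    }
  }
  std::reverse(aa.begin(), aa.end());
  std::reverse(bb.begin(), bb.end());
  int matches = 0;
  for (size_t k = 0; k < aa.size(); ++k)
    if (chr_match(aa[k], bb[k], ambig)) ++matches;
  return List::create(_["a"] = aa, _["b"] = bb,
                      _["score"] = F(n, m), _["matches"] = matches,
                      _["columns"] = (int) aa.size());
}

// Highest-scoring ungapped local segment pair under +match/-mismatch
// scoring, subject to a minimum segment length. Ties resolved by longer
// segment, then smaller a_start, then smaller b_start. Returns integer
// vector c(a_start, a_end, b_start, b_end, matches) 1-based, or empty if no
// positive-scoring segment of the required length exists.
// [[Rcpp::export]]
IntegerVector cpp_best_local_match(std::string a, std::string b,
                                   int min_len = 1,
                                   double match = 1.0, double mismatch = -1.0,
                                   std::string ambig = "NX-") {
  const int n = a.size(), m = b.size();
  double best_score = 0.0;          // must be strictly positive
  int best_len = 0, best_as = 0, best_bs = 0;
  bool found = false;
  std::vector<double> pref;
  for (int d = -(n - 1); d <= m - 1; ++d) {
    // diagonal: positions i in a, j = i + d in b
    int i0 = std::max(1, 1 - d);          // 1-based start index in a
    int i1 = std::min(n, m - d);
    int L = i1 - i0 + 1;
    if (L < min_len) continue;
    pref.assign(L + 1, 0.0);
    for (int t = 1; t <= L; ++t) {
      int i = i0 + t - 1, j = i + d;
      double v = chr_match(a[i - 1], b[j - 1], ambig) ? match : mismatch;
      pref[t] = pref[t - 1] + v;
    }
    // sliding minimum prefix over allowed starts (length >= min_len)
    double min_pref = pref[0]; int min_idx = 0;
    for (int e = min_len; e <= L; ++e) {
      int allowed = e - min_len;          // prefix indices 0..allowed usable
      if (allowed >= 1 && pref[allowed] < min_pref) {
        min_pref = pref[allowed]; min_idx = allowed;
      }
      double sc = pref[e] - min_pref;
      if (sc <= 0) continue;
      int len = e - min_idx;
      int as = i0 + min_idx, bs = as + d;
      bool better = false;
      if (!found || sc > best_score) better = true;
      else if (sc == best_score) {
        if (len > best_len) better = true;
        else if (len == best_len && as < best_as) better = true;
        else if (len == best_len && as == best_as && bs < best_bs) better = true;
      }
      if (better) {
        found = true; best_score = sc; best_len = len;
        best_as = as; best_bs = bs;
      }
    }
  }
  if (!found) return IntegerVector(0);
  // recompute matches on the winning segment
  int matches = 0;
  for (int t = 0; t < best_len; ++t)
    if (chr_match(a[best_as - 1 + t], b[best_bs - 1 + t], ambig)) ++matches;
  return IntegerVector::create(best_as, best_as + best_len - 1,
                               best_bs, best_bs + best_len - 1, matches);
}

static inline char dna_comp(char c) {
  switch (c) {
    case 'A': return 'T'; case 'T': return 'A';
    case 'C': return 'G'; case 'G': return 'C';
    default:  return 0;   // ambiguity never complements
  }
}

// All maximal inverted-repeat arm pairs with <= max_mismatch mismatches and
// arm length >= min_arm. Arms never overlap (loop >= 0). Equivalent to the
// anti-diagonal runs of a self dot-plot against the reverse complement.
// Returns a 6-column matrix: left_start, left_end, right_start, right_end,
// arm_length, mismatches (1-based inclusive).
// [[Rcpp::export]]
IntegerMatrix cpp_inverted_repeats(std::string s, int min_arm = 3,
                                   int max_mismatch = 0) {
  const int n = s.size();
  std::vector<int> out;
  std::vector<int> mism; // per-pair mismatch indicator along one anti-diagonal
  for (int c = 3; c <= 2 * n - 1; ++c) {  // a + b = c, a < b
    int t_lo = std::max(1, c - n);
    int t_hi = (c - 1) / 2;               // ensures left arm ends before right
    int len = t_hi - t_lo + 1;
    if (len < min_arm) continue;
    mism.assign(len, 0);
    for (int t = 0; t < len; ++t) {
      int aP = t_lo + t, bP = c - aP;
      char comp = dna_comp(s[aP - 1]);
      mism[t] = (comp != 0 && comp == s[bP - 1]) ? 0 : 1;
    }
    // two-pointer maximal windows with <= max_mismatch mismatches
    int l = 0, bad = 0, prev_l = -1;
    for (int r = 0; r < len; ++r) {
      bad += mism[r];
      while (bad > max_mismatch) { bad -= mism[l]; ++l; }
      // window [l, r] is left-maximal; right-maximal iff r == len-1 or
      // extending to r+1 forces l to move
      bool right_max = (r == len - 1);
      if (!right_max) {
        int nb = bad + mism[r + 1];
        if (nb > max_mismatch) right_max = true;
      }
      if (right_max && l != prev_l) {
        int wlen = r - l + 1;
        if (wlen >= min_arm) {
          int aP = t_lo + l, bP = t_lo + r; // pair indices
          int ls = aP, le = bP;             // left arm [aP .. bP]
          int rs = c - bP, re = c - aP;     // right arm
          int mm = 0;
          for (int t = l; t <= r; ++t) mm += mism[t];
          out.push_back(ls); out.push_back(le);
          out.push_back(rs); out.push_back(re);
          out.push_back(wlen); out.push_back(mm);
        }
        prev_l = l;
      }
    }
  }
  int nh = out.size() / 6;
  IntegerMatrix M(nh, 6);
  for (int h = 0; h < nh; ++h)
    for (int k = 0; k < 6; ++k) M(h, k) = out[6 * h + k];
  colnames(M) = CharacterVector::create("left_start", "left_end",
                                        "right_start", "right_end",
                                        "arm_length", "mismatches");
  return M;
}

// For every split point b of `chimera` (0..n), the maximum number of
// identical columns achievable by a global alignment of chimera[1..b]
// against all of `d` -- i.e. the longest common subsequence. One DP pass
// yields the whole prefix profile.
// [[Rcpp::export]]
IntegerVector cpp_lcs_prefix(std::string chimera, std::string d,
                             std::string ambig = "NX-") {
  const int n = chimera.size(), m = d.size();
  IntegerVector out(n + 1);
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  out[0] = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int v = prev[j - 1] + (chr_match(chimera[i - 1], d[j - 1], ambig) ? 1 : 0);
      if (prev[j] > v) v = prev[j];
      if (cur[j - 1] > v) v = cur[j - 1];
      cur[j] = v;
    }
    out[i] = cur[m];
    std::swap(prev, cur);
  }
  return out;
}

// Best ungapped local segment score only (fast path for null scans).
// [[Rcpp::export]]
double cpp_best_local_score(std::string a, std::string b,
                            int min_len = 1,
                            double match = 1.0, double mismatch = -1.0,
                            std::string ambig = "NX-") {
  IntegerVector h = cpp_best_local_match(a, b, min_len, match, mismatch, ambig);
  if (h.size() == 0) return 0.0;
  int len = h[1] - h[0] + 1;
  return h[4] * match + (len - h[4]) * mismatch;
}
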