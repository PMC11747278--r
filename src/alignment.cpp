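#include <Rcpp.h>
#include <climits>
using namespace Rcpp;

// Ends-free (semi-global) affine-gap alignment, Gotoh's three-state
// dynamic program.  Scoring (scaled to integers): match +10, mismatch -20,
// gap open -100, gap extension -1 per base; leading and trailing gaps on
// either sequence are free.  A long internal deletion (an isoform
// difference) is cheap while scattered gaps are punished, so identity over
// the shorter sequence behaves like the CD-HIT-EST convention.  Among
// co-optimal alignments the one with the most matched bases is taken, so
// the returned match count is well defined.  O(min(n,m)) memory.
static const int MATCH = 10, MISMATCH = -20, GAP_OPEN = 100, GAP_EXT = 1;

// [[Rcpp::export]]
List align_ends_free_cpp(std::string a, std::string b) {
  const int n = (int) a.size(), m = (int) b.size();
  if (n == 0 || m == 0) stop("empty sequence");
  const int NEG = INT_MIN / 4;
  // per-row arrays over j for states M (diagonal), X (gap in b, consumes a),
  // Y (gap in a, consumes b); S* = score, C* = matches
  std::vector<int> Mp(m + 1), Xp(m + 1), Yp(m + 1),
                   MCp(m + 1), XCp(m + 1), YCp(m + 1),
                   Mc(m + 1), Xc(m + 1), Yc(m + 1),
                   MCc(m + 1), XCc(m + 1), YCc(m + 1);
  for (int j = 0; j <= m; ++j) {
    Mp[j] = 0; Xp[j] = NEG; Yp[j] = NEG;   // free leading gaps: start anywhere
    MCp[j] = XCp[j] = YCp[j] = 0;
  }
  int bestS = NEG, bestM = 0;
  auto consider = [&](int S, int C) {
    if (S > bestS || (S == bestS && C > bestM)) { bestS = S; bestM = C; }
  };
  // ends-free: answer may end anywhere on the last row or last column
  consider(0, 0);
  for (int i = 1; i <= n; ++i) {
    Mc[0] = 0; Xc[0] = NEG; Yc[0] = NEG;
    MCc[0] = XCc[0] = YCc[0] = 0;
    const char ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      // M: best of previous diagonal states plus substitution score
      int S = Mp[j - 1], C = MCp[j - 1];
      if (Xp[j - 1] > S || (Xp[j - 1] == S && XCp[j - 1] > C)) {
        S = Xp[j - 1]; C = XCp[j - 1];
      }
      if (Yp[j - 1] > S || (Yp[j - 1] == S && YCp[j - 1] > C)) {
        S = Yp[j - 1]; C = YCp[j - 1];
      }
      const bool mt = (ai == b[j - 1]);
      Mc[j] = S + (mt ? MATCH : MISMATCH);
      MCc[j] = C + (mt ? 1 : 0);
      // X: gap in b (vertical)
      int so = Mp[j] - GAP_OPEN - GAP_EXT, sc = MCp[j];
      int se = Xp[j] - GAP_EXT;
      if (se > so || (se == so && XCp[j] > sc)) { so = se; sc = XCp[j]; }
      Xc[j] = so; XCc[j] = sc;
      // Y: gap in a (horizontal)
      so = Mc[j - 1] - GAP_OPEN - GAP_EXT; sc = MCc[j - 1];
      se = Yc[j - 1] - GAP_EXT;
      if (se > so || (se == so && YCc[j - 1] > sc)) { so = se; sc = YCc[j - 1]; }
      Yc[j] = so; YCc[j] = sc;
      if (j == m || i == n) {
        consider(Mc[j], MCc[j]);
        consider(Xc[j], XCc[j]);
        consider(Yc[j], YCc[j]);
      }
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
    std::swap(MCp, MCc); std::swap(XCp, XCc); std::swap(YCp, YCc);
  }
  return List::create(_["score"] = bestS, _["matches"] = bestM);
}

// Integer codes of all k-mers of s (base-4 over A,C,G,T), NA where the
// window contains any other character.  k <= 15 so codes fit in an int.
// [[Rcpp::export]]
IntegerVector kmer_codes_cpp(std::string s, int k) {
  const int n = (int) s.size();
  if (k < 1 || k > 15) stop("k must be in 1..15");
  if (n < k) return IntegerVector(0);
  IntegerVector out(n - k + 1);
  long mod = 1; for (int i = 0; i < k; ++i) mod *= 4;
  long code = 0; int run = 0;
  for (int i = 0; i < n; ++i) {
    int v;
    switch (s[i]) {
      case 'A': v = 0; break; case 'C': v = 1; break;
      case 'G': v = 2; break; case 'T': v = 3; break;
      default: v = -1;
    }
    if (v < 0) { run = 0; code = 0; }
    else { code = (code * 4 + v) % mod; ++run; }
    if (i >= k - 1) out[i - k + 1] = (run >= k) ? (int) code : NA_INTEGER;
  }
  return out;
}
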