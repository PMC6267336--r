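#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Glocal affine-gap alignment: the whole pattern is aligned to a substring
// of the subject (free subject start/end).  Optionally banded around the
// corridor j in [i - band, i + (n - m) + band], which is where the optimum
// lives when the pattern is anchored inside the subject with bounded indel
// drift.  Alongside the score the DP carries the number of matches, the
// number of alignment columns and the subject start of the optimal path,
// so identity = matches / columns without a traceback.
//
// Returns score, matches, aln_len (columns), sub_start, sub_end (0-based
// half-open on the subject).
// [[Rcpp::export]]
List banded_glocal(std::string pattern, std::string subject,
                   int match = 1, int mismatch = -1,
                   int gap_open = -2, int gap_ext = -1, int band = -1) {
  const int m = (int)pattern.size(), n = (int)subject.size();
  if (m == 0 || n == 0) stop("empty sequence in banded_glocal");
  const int NEG = -1000000000;

  struct Cell { int s, mt, cl, st; };
  std::vector<Cell> Hp(n + 1), Ep(n + 1), Fp(n + 1);
  std::vector<Cell> H(n + 1), E(n + 1), F(n + 1);

  for (int j = 0; j <= n; ++j) {
    Hp[j] = {0, 0, 0, j};          // free start anywhere in the subject
    Ep[j] = {NEG, 0, 0, j};
    Fp[j] = {NEG, 0, 0, j};
  }

  for (int i = 1; i <= m; ++i) {
    int lo = 1, hi = n;
    if (band >= 0) {
      lo = std::max(1, i - band);
      hi = std::min(n, i + (n - m) + band);
      if (hi < lo) stop("band too narrow for these sequence lengths");
    }
    for (int j = 0; j <= n; ++j) { H[j].s = NEG; E[j].s = NEG; F[j].s = NEG; }
    // leading gap in the subject (pattern consumed before subject starts)
    F[0] = {gap_open + (i - 1) * gap_ext, 0, i, 0};
    for (int j = lo; j <= hi; ++j) {
      const int sc = (pattern[i - 1] == subject[j - 1]) ? match : mismatch;
      const int mm = (pattern[i - 1] == subject[j - 1]) ? 1 : 0;
      // H: diagonal step from best state at (i-1, j-1)
      Cell d = Hp[j - 1];
      if (Ep[j - 1].s > d.s) d = Ep[j - 1];
      if (Fp[j - 1].s > d.s) d = Fp[j - 1];
      if (d.s > NEG / 2)
        H[j] = {d.s + sc, d.mt + mm, d.cl + 1, d.st};
      // E: gap in the pattern (consume subject char j)
      Cell eo = H[j - 1], ee = E[j - 1];
      bool use_open = (eo.s > NEG / 2) &&
                      (eo.s + gap_open >= ee.s + gap_ext || ee.s <= NEG / 2);
      if (use_open)
        E[j] = {eo.s + gap_open, eo.mt, eo.cl + 1, eo.st};
      else if (ee.s > NEG / 2)
        E[j] = {ee.s + gap_ext, ee.mt, ee.cl + 1, ee.st};
      // F: gap in the subject (consume pattern char i)
      Cell fo = Hp[j], fe = Fp[j];
      use_open = (fo.s > NEG / 2) &&
                 (fo.s + gap_open >= fe.s + gap_ext || fe.s <= NEG / 2);
      if (use_open)
        F[j] = {fo.s + gap_open, fo.mt, fo.cl + 1, fo.st};
      else if (fe.s > NEG / 2)
        F[j] = {fe.s + gap_ext, fe.mt, fe.cl + 1, fe.st};
    }
    std::swap(H, Hp); std::swap(E, Ep); std::swap(F, Fp);
  }

  Cell best = {NEG, 0, 0, 0};
  int jbest = 0;
  for (int j = 0; j <= n; ++j) {
    if (Hp[j].s > best.s) { best = Hp[j]; jbest = j; }
    if (Fp[j].s > best.s) { best = Fp[j]; jbest = j; }
  }
  if (best.s <= NEG / 2) stop("no feasible alignment within the band");
  return List::create(_["score"] = best.s, _["matches"] = best.mt,
                      _["aln_len"] = best.cl, _["sub_start"] = best.st,
                      _["sub_end"] = jbest);
}
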