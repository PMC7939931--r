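#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Global Needleman-Wunsch with linear gap penalty over integer-coded
// sequences (1-based indices into the scoring matrix). Tie preference at
// each cell: diagonal, then up (gap in b), then left (gap in a), which
// makes the traceback deterministic.
// [[Rcpp::export]]
List nw_align_idx(IntegerVector a, IntegerVector b, NumericMatrix S, double gap) {
  int n = a.size(), m = b.size();
  NumericMatrix F(n + 1, m + 1);
  IntegerMatrix P(n + 1, m + 1); // 1 diag, 2 up, 3 left
  for (int i = 1; i <= n; i++) { F(i, 0) = i * gap; P(i, 0) = 2; }
  for (int j = 1; j <= m; j++) { F(0, j) = j * gap; P(0, j) = 3; }
  for (int i = 1; i <= n; i++) {
    for (int j = 1; j <= m; j++) {
      double d = F(i - 1, j - 1) + S(a[i - 1] - 1, b[j - 1] - 1);
      double u = F(i - 1, j) + gap;
      double l = F(i, j - 1) + gap;
      double best = d; int mv = 1;
      if (u > best) { best = u; mv = 2; }
      if (l > best) { best = l; mv = 3; }
      F(i, j) = best; P(i, j) = mv;
    }
  }
  std::vector<int> ai, bi;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int mv = P(i, j);
    if (mv == 1) { ai.push_back(i); bi.push_back(j); i--; j--; }
    else if (mv == 2) { ai.push_back(i); bi.push_back(0); i--; }
    else { ai.push_back(0); bi.push_back(j); j--; }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
  return List::create(_["a_idx"] = wrap(ai), _["b_idx"] = wrap(bi),
                      _["score"] = F(n, m));
}

// Profile-profile Needleman-Wunsch for progressive multiple alignment.
// pa, pb: (K+1) x L frequency matrices; rows 1..K are alphabet symbols
// matching the K x K scoring matrix S, row K+1 is the gap frequency;
// columns sum to 1. Base-vs-gap pairs score `gap`; gap-vs-gap scores 0.
// Opening a new gap column against an existing column costs gap times the
// column's non-gap fraction. Same tie preference as nw_align_idx.
// [[Rcpp::export]]
List nw_profile_idx(NumericMatrix pa, NumericMatrix pb, NumericMatrix S, double gap) {
  int K = S.nrow();
  int La = pa.ncol(), Lb = pb.ncol();
  std::vector<double> gapA(La), gapB(Lb);
  for (int x = 0; x < La; x++) gapA[x] = gap * (1.0 - pa(K, x));
  for (int y = 0; y < Lb; y++) gapB[y] = gap * (1.0 - pb(K, y));
  NumericMatrix CS(La > 0 ? La : 1, Lb > 0 ? Lb : 1);
  for (int x = 0; x < La; x++) {
    for (int y = 0; y < Lb; y++) {
      double s = 0.0;
      for (int u = 0; u < K; u++) {
        double fu = pa(u, x);
        if (fu == 0.0) continue;
        for (int v = 0; v < K; v++) {
          double fv = pb(v, y);
          if (fv == 0.0) continue;
          s += fu * fv * S(u, v);
        }
      }
      s += gap * (pa(K, x) * (1.0 - pb(K, y)) + pb(K, y) * (1.0 - pa(K, x)));
      CS(x, y) = s;
    }
  }
  NumericMatrix F(La + 1, Lb + 1);
  IntegerMatrix P(La + 1, Lb + 1);
  for (int i = 1; i <= La; i++) { F(i, 0) = F(i - 1, 0) + gapA[i - 1]; P(i, 0) = 2; }
  for (int j = 1; j <= Lb; j++) { F(0, j) = F(0, j - 1) + gapB[j - 1]; P(0, j) = 3; }
  for (int i = 1; i <= La; i++) {
    for (int j = 1; j <= Lb; j++) {
      double d = F(i - 1, j - 1) + CS(i - 1, j - 1);
      double u = F(i - 1, j) + gapA[i - 1];
      double l = F(i, j - 1) + gapB[j - 1];
      double best = d; int mv = 1;
      if (u > best) { best = u; mv = 2; }
      if (l > best) { best = l; mv = 3; }
      F(i, j) = best; P(i, j) = mv;
    }
  }
  std::vector<int> ai, bi;
  int i = La, j = Lb;
  while (i > 0 || j > 0) {
    int mv = P(i, j);
    if (mv == 1) { ai.push_back(i); bi.push_back(j); i--; j--; }
    else if (mv == 2) { ai.push_back(i); bi.push_back(0); i--; }
    else { ai.push_back(0); bi.push_back(j); j--; }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
  return List::create(_["a_idx"] = wrap(ai), _["b_idx"] = wrap(bi),
                      _["score"] = F(La, Lb));
}

// Codon-aware overlap alignment of a nucleotide sequence against an
// amino-acid reference. nt codes: 1..4 = ACGT, 0 = other; aa: 1-based rows
// of `blosum`; codon2aa: length-125 lookup, index b1*25 + b2*5 + b3 + 1
// (0-based access here), giving the blosum row of the translated codon.
// Moves consume (nt, aa): 1:(3,1) codon match, 2:(3,0) codon insertion,
// 3:(0,1) codon deletion, 4:(2,1)/5:(1,1) frameshift deletions,
// 6:(2,0)/7:(1,0) frameshift insertions. End gaps on both sequences are
// free (overlap alignment), so the reading-frame offset of the read is
// found by the DP itself. Ties prefer the lowest move number.
// [[Rcpp::export]]
List codon_align_cpp(IntegerVector nt, IntegerVector aa, NumericMatrix blosum,
                     IntegerVector codon2aa, double fs_pen, double gap3_pen) {
  const int dnt[8] = {0, 3, 3, 0, 2, 1, 2, 1};
  const int daa[8] = {0, 1, 0, 1, 1, 1, 0, 0};
  int n = nt.size(), m = aa.size();
  NumericMatrix F(n + 1, m + 1);
  IntegerMatrix P(n + 1, m + 1); // 0 none, 1..7 moves, 8 free nt skip, 9 free aa skip
  for (int i = 0; i <= n; i++) { F(i, 0) = 0.0; P(i, 0) = 8; }
  for (int j = 0; j <= m; j++) { F(0, j) = 0.0; P(0, j) = 9; }
  P(0, 0) = 0;
  for (int i = 1; i <= n; i++) {
    for (int j = 1; j <= m; j++) {
      double best = -1e300; int bm = 0;
      for (int mv = 1; mv <= 7; mv++) {
        int pi = i - dnt[mv], pj = j - daa[mv];
        if (pi < 0 || pj < 0) continue;
        double sc = F(pi, pj);
        if (mv == 1) {
          int c = codon2aa[nt[i - 3] * 25 + nt[i - 2] * 5 + nt[i - 1]];
          sc += blosum(c - 1, aa[j - 1] - 1);
        } else if (mv == 2 || mv == 3) {
          sc += gap3_pen;
        } else {
          sc += fs_pen;
        }
        if (sc > best) { best = sc; bm = mv; }
      }
      F(i, j) = best;
      P(i, j) = bm;
    }
  }
  // best end on last row/column; prefer the corner, then larger indices
  int ei = n, ej = m;
  double best = F(n, m);
  for (int j = m; j >= 0; j--) if (F(n, j) > best) { best = F(n, j); ei = n; ej = j; }
  for (int i = n; i >= 0; i--) if (F(i, m) > best) { best = F(i, m); ei = i; ej = m; }
  std::vector<int> moves;
  int i = ei, j = ej;
  while (i > 0 && j > 0) {
    int mv = P(i, j);
    if (mv < 1 || mv > 7) break;
    moves.push_back(mv);
    i -= dnt[mv];
    j -= daa[mv];
  }
  std::reverse(moves.begin(), moves.end());
  return List::create(_["moves"] = wrap(moves),
                      _["start_nt"] = i, _["start_aa"] = j,
                      _["end_nt"] = ei, _["end_aa"] = ej,
                      _["score"] = best);
}
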