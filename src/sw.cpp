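// Smith-Waterman local alignment with affine gaps (gap of length L costs
// open + L * ext), score + traceback statistics (matches, alignment
// columns). One query set against one subject per call.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <string>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export]]
List cpp_sw_batch(CharacterVector queries, std::string subject,
                  IntegerMatrix scoreMat, std::string alphabet,
                  int gapOpen, int gapExt) {
  const int A = (int)alphabet.size();
  int lut[256];
  std::fill(lut, lut + 256, -1);
  for (int i = 0; i < A; ++i) lut[(unsigned char)alphabet[i]] = i;

  const int n2 = (int)subject.size();
  std::vector<int> sIdx(n2);
  for (int j = 0; j < n2; ++j) {
    sIdx[j] = lut[(unsigned char)subject[j]];
    if (sIdx[j] < 0) stop("subject contains a character outside the alphabet");
  }

  const int NQ = queries.size();
  NumericVector score(NQ);
  IntegerVector matches(NQ), alnCols(NQ);

  const int GO = gapOpen + gapExt;  // cost of the first gap position
  const int GE = gapExt;
  const int NEG = -100000000;

  for (int q = 0; q < NQ; ++q) {
    std::string qs = as<std::string>(queries[q]);
    const int n1 = (int)qs.size();
    std::vector<int> qIdx(n1);
    for (int i = 0; i < n1; ++i) {
      qIdx[i] = lut[(unsigned char)qs[i]];
      if (qIdx[i] < 0) stop("query contains a character outside the alphabet");
    }
    // H, E (gap in query / consume subject), F (gap in subject)
    std::vector<int> H((size_t)(n1 + 1) * (n2 + 1), 0);
    std::vector<int> E((size_t)(n1 + 1) * (n2 + 1), NEG);
    std::vector<int> F((size_t)(n1 + 1) * (n2 + 1), NEG);
    // traceback: 0 none (H==0), 1 diag, 2 from E, 3 from F
    std::vector<uint8_t> TB((size_t)(n1 + 1) * (n2 + 1), 0);
    std::vector<uint8_t> TE((size_t)(n1 + 1) * (n2 + 1), 0);  // 1=open,0=ext
    std::vector<uint8_t> TF((size_t)(n1 + 1) * (n2 + 1), 0);
    auto ix = [&](int i, int j) { return (size_t)i * (n2 + 1) + j; };
    int best = 0, bi = 0, bj = 0;
    for (int i = 1; i <= n1; ++i) {
      for (int j = 1; j <= n2; ++j) {
        int e1 = H[ix(i, j - 1)] - GO, e2 = E[ix(i, j - 1)] - GE;
        int e = std::max(e1, e2);
        E[ix(i, j)] = e;
        TE[ix(i, j)] = e1 >= e2 ? 1 : 0;
        int f1 = H[ix(i - 1, j)] - GO, f2 = F[ix(i - 1, j)] - GE;
        int f = std::max(f1, f2);
        F[ix(i, j)] = f;
        TF[ix(i, j)] = f1 >= f2 ? 1 : 0;
        int d = H[ix(i - 1, j - 1)] +
          scoreMat(qIdx[i - 1], sIdx[j - 1]);
        int h = 0; uint8_t tb = 0;
        if (d > h) { h = d; tb = 1; }
        if (e > h) { h = e; tb = 2; }
        if (f > h) { h = f; tb = 3; }
        H[ix(i, j)] = h;
        TB[ix(i, j)] = tb;
        if (h > best) { best = h; bi = i; bj = j; }
      }
    }
    int m = 0, cols = 0;
    int i = bi, j = bj, state = 0;  // 0=H, 1=E, 2=F
    while (i > 0 && j > 0) {
      if (state == 0) {
        uint8_t tb = TB[ix(i, j)];
        if (tb == 0) break;
        if (tb == 1) {
          if (qIdx[i - 1] == sIdx[j - 1]) ++m;
          ++cols; --i; --j;
        } else if (tb == 2) state = 1;
        else state = 2;
      } else if (state == 1) {
        ++cols;
        uint8_t te = TE[ix(i, j)];
        --j;
        if (te == 1) state = 0;
      } else {
        ++cols;
        uint8_t tf = TF[ix(i, j)];
        --i;
        if (tf == 1) state = 0;
      }
    }
    score[q] = best;
    matches[q] = m;
    alnCols[q] = cols;
  }
  return List::create(_["score"] = score, _["matches"] = matches,
                      _["alnCols"] = alnCols);
}
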