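#include <Rcpp.h>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps over a precomputed
// position-pair score matrix S (query rows x target columns, any units).
// Gap of length g costs open + (g-1) * extend on either side.
// Ties break deterministically: diagonal (match) over gap-in-target over
// gap-in-query over local restart; the best cell is the first maximum in
// row-major order.  Returns the optimal score, the matched index pairs
// (1-based, ascending) and the aligned spans.
// [[Rcpp::export(name = ".sw_affine")]]
List sw_affine(NumericMatrix S, double open, double extend) {
  const int n = S.nrow(), m = S.ncol();
  const double NEG = -1e300;
  NumericMatrix M(n + 1, m + 1), Ix(n + 1, m + 1), Iy(n + 1, m + 1);
  IntegerMatrix ptrM(n + 1, m + 1), ptrX(n + 1, m + 1), ptrY(n + 1, m + 1);
  for (int j = 0; j <= m; ++j) { M(0, j) = NEG; Ix(0, j) = NEG; Iy(0, j) = NEG; }
  for (int i = 0; i <= n; ++i) { M(i, 0) = NEG; Ix(i, 0) = NEG; Iy(i, 0) = NEG; }

  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // M: i aligned to j
      double dM = M(i - 1, j - 1), dX = Ix(i - 1, j - 1), dY = Iy(i - 1, j - 1);
      double pre = 0.0; int ptr = 0;            // 0 = restart
      if (dM >= pre && dM >= dX && dM >= dY) { pre = dM; ptr = 1; }
      else if (dX >= pre && dX >= dY)        { pre = dX; ptr = 2; }
      else if (dY >= pre)                    { pre = dY; ptr = 3; }
      if (pre < 0.0) { pre = 0.0; ptr = 0; }
      M(i, j) = pre + S(i - 1, j - 1);
      ptrM(i, j) = ptr;
      // Ix: gap in target (query advances)
      double oM = M(i - 1, j) - open, oX = Ix(i - 1, j) - extend;
      if (oM >= oX) { Ix(i, j) = oM; ptrX(i, j) = 1; }
      else          { Ix(i, j) = oX; ptrX(i, j) = 2; }
      // Iy: gap in query (target advances)
      double pM = M(i, j - 1) - open, pY = Iy(i, j - 1) - extend;
      if (pM >= pY) { Iy(i, j) = pM; ptrY(i, j) = 1; }
      else          { Iy(i, j) = pY; ptrY(i, j) = 3; }
      if (M(i, j) > best) { best = M(i, j); bi = i; bj = j; }
    }
  }

  if (best <= 0.0 || bi == 0) {
    return List::create(_["score"] = 0.0,
                        _["pairs"] = IntegerMatrix(0, 2),
                        _["qstart"] = NA_INTEGER, _["qend"] = NA_INTEGER,
                        _["tstart"] = NA_INTEGER, _["tend"] = NA_INTEGER);
  }

  std::vector<int> qi, tj;
  int i = bi, j = bj, state = 1;  // start in M at the best cell
  while (i > 0 && j > 0) {
    if (state == 1) {
      qi.push_back(i); tj.push_back(j);
      int p = ptrM(i, j);
      --i; --j;
      if (p == 0) break;
      state = p;
    } else if (state == 2) {
      int p = ptrX(i, j);
      --i;
      state = p;
    } else {
      int p = ptrY(i, j);
      --j;
      state = p;
    }
  }
  const int k = qi.size();
  IntegerMatrix pairs(k, 2);
  for (int r = 0; r < k; ++r) {
    pairs(r, 0) = qi[k - 1 - r];
    pairs(r, 1) = tj[k - 1 - r];
  }
  return List::create(_["score"] = best, _["pairs"] = pairs,
                      _["qstart"] = pairs(0, 0), _["qend"] = pairs(k - 1, 0),
                      _["tstart"] = pairs(0, 1), _["tend"] = pairs(k - 1, 1));
}
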