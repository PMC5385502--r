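#include <Rcpp.h>
using namespace Rcpp;

// Global affine-gap alignment (Gotoh) over a precomputed column-score
// matrix. Rows index positions of sequence/profile A, columns of B, so the
// same core serves residue-residue and profile-profile alignment. A gap run
// of length k costs gap_open + (k - 1) * gap_extend. Traceback prefers the
// diagonal (match) state, then up (gap in B), then left (gap in A), which
// makes the reported alignment deterministic.
// [[Rcpp::export]]
List affine_dp(NumericMatrix scores, double gap_open, double gap_extend) {
  const int n = scores.nrow(), m = scores.ncol();
  const double NINF = -1e18;
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);

  M(0, 0) = 0.0; X(0, 0) = NINF; Y(0, 0) = NINF;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NINF; Y(i, 0) = NINF;
    X(i, 0) = -gap_open - (i - 1) * gap_extend;
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NINF; X(0, j) = NINF;
    Y(0, j) = -gap_open - (j - 1) * gap_extend;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double best = M(i - 1, j - 1);
      if (X(i - 1, j - 1) > best) best = X(i - 1, j - 1);
      if (Y(i - 1, j - 1) > best) best = Y(i - 1, j - 1);
      M(i, j) = scores(i - 1, j - 1) + best;

      double xo = M(i - 1, j) - gap_open;
      double xe = X(i - 1, j) - gap_extend;
      double xs = Y(i - 1, j) - gap_open;
      X(i, j) = std::max(xo, std::max(xe, xs));

      double yo = M(i, j - 1) - gap_open;
      double ys = X(i, j - 1) - gap_open;
      double ye = Y(i, j - 1) - gap_extend;
      Y(i, j) = std::max(yo, std::max(ys, ye));
    }
  }

  // traceback; state 0 = M (diag), 1 = X (up), 2 = Y (left)
  int i = n, j = m, state = 0;
  double fin = M(n, m);
  if (X(n, m) > fin) { fin = X(n, m); state = 1; }
  if (Y(n, m) > fin) { fin = Y(n, m); state = 2; }

  std::vector<int> ai, bi;
  const double eps = 1e-9;
  while (i > 0 || j > 0) {
    if (state == 0) {
      double need = M(i, j) - scores(i - 1, j - 1);
      ai.push_back(i); bi.push_back(j);
      if (i == 1 && j == 1) { i = 0; j = 0; break; }
      if (std::abs(M(i - 1, j - 1) - need) < eps) state = 0;
      else if (std::abs(X(i - 1, j - 1) - need) < eps) state = 1;
      else state = 2;
      --i; --j;
    } else if (state == 1) {
      ai.push_back(i); bi.push_back(0);
      double v = X(i, j);
      if (std::abs(M(i - 1, j) - gap_open - v) < eps) state = 0;
      else if (std::abs(X(i - 1, j) - gap_extend - v) < eps) state = 1;
      else state = 2;
      --i;
      if (i == 0 && j == 0) break;
      if (i == 0) state = 2;  // only left moves remain
    } else {
      ai.push_back(0); bi.push_back(j);
      double v = Y(i, j);
      if (std::abs(M(i, j - 1) - gap_open - v) < eps) state = 0;
      else if (std::abs(X(i, j - 1) - gap_open - v) < eps) state = 1;
      else state = 2;
      --j;
      if (i == 0 && j == 0) break;
      if (j == 0) state = 1;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());

  return List::create(_["score"] = fin,
                      _["a_index"] = wrap(ai),
                      _["b_index"] = wrap(bi));
}

// 3x3 median filter with nearest-neighbour (replicate) edge padding.
// [[Rcpp::export]]
NumericMatrix median_filter3(NumericMatrix img) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  double w[9];
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int k = 0;
      for (int dj = -1; dj <= 1; ++dj) {
        int jj = j + dj; if (jj < 0) jj = 0; if (jj >= nc) jj = nc - 1;
        for (int di = -1; di <= 1; ++di) {
          int ii = i + di; if (ii < 0) ii = 0; if (ii >= nr) ii = nr - 1;
          w[k++] = img(ii, jj);
        }
      }
      std::nth_element(w, w + 4, w + 9);
      out(i, j) = w[4];
    }
  }
  return out;
}

// 8-connected component labeling of a logical mask (flood fill).
// Returns an integer matrix of labels, 0 = background.
// [[Rcpp::export]]
IntegerMatrix label_components8(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  int next = 0;
  for (int j0 = 0; j0 < nc; ++j0) {
    for (int i0 = 0; i0 < nr; ++i0) {
      if (!mask(i0, j0) || lab(i0, j0) != 0) continue;
      ++next;
      stack.push_back(i0 + j0 * nr);
      lab(i0, j0) = next;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pi = p % nr, pj = p / nr;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            int ii = pi + di, jj = pj + dj;
            if (ii < 0 || jj < 0 || ii >= nr || jj >= nc) continue;
            if (mask(ii, jj) && lab(ii, jj) == 0) {
              lab(ii, jj) = next;
              stack.push_back(ii + jj * nr);
            }
          }
        }
      }
    }
  }
  return lab;
}
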