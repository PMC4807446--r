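#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap dynamic programming over two alignment profiles (Gotoh).
// Profiles are alphabet-by-column relative-frequency matrices; gap mass is
// simply absent from a column, so column-column scores scale with occupancy
// while gap penalties stay constant. free_ends = TRUE gives semi-global
// alignment (leading and trailing gaps cost nothing).
//
// Tie-breaking is fixed: diagonal > up (gap in B) > left (gap in A), both
// for the final state and for predecessor states, so the traceback is
// deterministic.

static const double NEG_INF = -1e30;

// [[Rcpp::export]]
List profile_align_cpp(NumericMatrix fa, NumericMatrix fb, NumericMatrix S,
                       double gap_open, double gap_extend, bool free_ends) {
  const int A = fa.nrow();
  const int La = fa.ncol(), Lb = fb.ncol();
  if (fb.nrow() != A || S.nrow() != A || S.ncol() != A)
    stop("profile/substitution dimensions disagree");

  // Sb(a, j) = sum_b S(a, b) * fb(b, j)
  NumericMatrix Sb(A, Lb);
  for (int j = 0; j < Lb; ++j)
    for (int a = 0; a < A; ++a) {
      double acc = 0.0;
      for (int b = 0; b < A; ++b) acc += S(a, b) * fb(b, j);
      Sb(a, j) = acc;
    }

  const int nr = La + 1, nc = Lb + 1;
  std::vector<double> M(nr * nc, NEG_INF), X(nr * nc, NEG_INF), Y(nr * nc, NEG_INF);
  // predecessor state per cell and matrix: 0 = M, 1 = X, 2 = Y
  std::vector<signed char> pM(nr * nc, -1), pX(nr * nc, -1), pY(nr * nc, -1);
  auto at = [nc](int i, int j) { return i * nc + j; };

  M[at(0, 0)] = 0.0;
  for (int i = 1; i < nr; ++i) {
    X[at(i, 0)] = free_ends ? 0.0 : gap_open + (i - 1) * gap_extend;
    pX[at(i, 0)] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j < nc; ++j) {
    Y[at(0, j)] = free_ends ? 0.0 : gap_open + (j - 1) * gap_extend;
    pY[at(0, j)] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i < nr; ++i) {
    for (int j = 1; j < nc; ++j) {
      double s = 0.0;
      for (int a = 0; a < A; ++a) s += fa(a, i - 1) * Sb(a, j - 1);
      // M: preference M > X > Y on ties
      double m0 = M[at(i - 1, j - 1)], m1 = X[at(i - 1, j - 1)], m2 = Y[at(i - 1, j - 1)];
      double best = m0; signed char arg = 0;
      if (m1 > best) { best = m1; arg = 1; }
      if (m2 > best) { best = m2; arg = 2; }
      M[at(i, j)] = best + s; pM[at(i, j)] = arg;
      // X: consume column of A against gap
      double x0 = M[at(i - 1, j)] + gap_open;
      double x1 = X[at(i - 1, j)] + gap_extend;
      double x2 = Y[at(i - 1, j)] + gap_open;
      best = x0; arg = 0;
      if (x1 > best) { best = x1; arg = 1; }
      if (x2 > best) { best = x2; arg = 2; }
      X[at(i, j)] = best; pX[at(i, j)] = arg;
      // Y: consume column of B against gap; predecessor preference M > X > Y
      double y0 = M[at(i, j - 1)] + gap_open;
      double y1 = X[at(i, j - 1)] + gap_open;
      double y2 = Y[at(i, j - 1)] + gap_extend;
      best = y0; arg = 0;
      if (y1 > best) { best = y1; arg = 1; }
      if (y2 > best) { best = y2; arg = 2; }
      Y[at(i, j)] = best; pY[at(i, j)] = arg;
    }
  }

  // choose end cell/state
  int ei = La, ej = Lb; int estate; double score;
  auto best3 = [&](int i, int j, int &st) {
    double m = M[at(i, j)], x = X[at(i, j)], y = Y[at(i, j)];
    double b = m; st = 0;
    if (x > b) { b = x; st = 1; }
    if (y > b) { b = y; st = 2; }
    return b;
  };
  if (!free_ends) {
    score = best3(La, Lb, estate);
  } else {
    int st;
    score = best3(La, Lb, st); estate = st; ei = La; ej = Lb;
    for (int i = La - 1; i >= 0; --i) {       // trailing gap in A-side
      double v = best3(i, Lb, st);
      if (v > score) { score = v; estate = st; ei = i; ej = Lb; }
    }
    for (int j = Lb - 1; j >= 0; --j) {
      double v = best3(La, j, st);
      if (v > score) { score = v; estate = st; ei = La; ej = j; }
    }
  }

  // traceback: moves 1 = diagonal, 2 = up (A column), 3 = left (B column)
  std::vector<int> trail;   // trailing free gaps, in forward order
  for (int j = Lb; j > ej; --j) trail.push_back(3);
  for (int i = La; i > ei; --i) trail.push_back(2);
  std::vector<int> rev;
  int i = ei, j = ej, st = estate;
  while (i > 0 || j > 0) {
    if (st == 0) {
      signed char p = pM[at(i, j)];
      rev.push_back(1); --i; --j; st = p;
    } else if (st == 1) {
      signed char p = pX[at(i, j)];
      rev.push_back(2); --i; st = p;
    } else {
      signed char p = pY[at(i, j)];
      rev.push_back(3); --j; st = p;
    }
  }
  std::vector<int> path;
  path.reserve(rev.size() + trail.size());
  for (auto it = rev.rbegin(); it != rev.rend(); ++it) path.push_back(*it);
  for (size_t k = 0; k < trail.size(); ++k) path.push_back(trail[k]);

  return List::create(_["score"] = score, _["path"] = wrap(path));
}

// Longest exact common substring length between two residue strings.
// [[Rcpp::export]]
int lcs_substring_cpp(std::string a, std::string b) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) return 0;
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      if (a[i - 1] == b[j - 1]) {
        cur[j] = prev[j - 1] + 1;
        if (cur[j] > best) best = cur[j];
      } else cur[j] = 0;
    }
    std::swap(prev, cur);
  }
  return best;
}

// Pairwise identity distances on an integer-coded alignment matrix
// (rows = sequences, 0 = gap). Columns where either row is gapped are
// dropped from both numerator and denominator; no shared residue
// columns gives distance 1.
// [[Rcpp::export]]
NumericMatrix identity_dist_cpp(IntegerMatrix m) {
  const int n = m.nrow(), L = m.ncol();
  NumericMatrix d(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int shared = 0, match = 0;
      for (int k = 0; k < L; ++k) {
        int a = m(i, k), b = m(j, k);
        if (a > 0 && b > 0) {
          ++shared;
          if (a == b) ++match;
        }
      }
      double dij = (shared == 0) ? 1.0 : 1.0 - (double)match / shared;
      d(i, j) = dij;
      d(j, i) = dij;
    }
  }
  return d;
}
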