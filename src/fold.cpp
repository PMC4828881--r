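// Simplified thermodynamic-weighted Nussinov-style partition function with
// inside-outside base-pair probabilities (McCaskill-type), plus a maximum-
// weight structure traceback rendered as a dot-bracket string.
//
// Pair weights default to GC=3, AU=2, GU=1 (relative Boltzmann factors per
// pair; no stacking or loop terms).  Intended for sequences up to a few
// hundred nt; the double-precision partition function overflows on much
// longer, highly paired sequences.

#include <Rcpp.h>
#include <string>
#include <vector>

using namespace Rcpp;

static inline double pair_weight(char a, char b, double wgc, double wau,
                                 double wgu) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return wgc;
  if ((a == 'A' && b == 'T') || (a == 'T' && b == 'A') ||
      (a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return wau;
  if ((a == 'G' && b == 'T') || (a == 'T' && b == 'G') ||
      (a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return wgu;
  return 0.0;
}

// [[Rcpp::export]]
NumericVector fold_bpp_cpp(std::string seq, int min_loop = 3,
                           double wgc = 3.0, double wau = 2.0,
                           double wgu = 1.0) {
  const int n = static_cast<int>(seq.size());
  NumericVector paired(n);
  if (n < 2) return paired;
  for (auto &c : seq) c = static_cast<char>(toupper(c));

  // inside: Z[i][j] over 1-based-inclusive segments stored 0-based
  std::vector<std::vector<double>> Z(n, std::vector<double>(n + 1, 1.0));
  // Z(i,j) with j < i means empty segment = 1; use helper lambda
  auto Zat = [&](int i, int j) -> double {
    if (j < i) return 1.0;
    return Z[i][j];
  };
  for (int len = 1; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      double z = Zat(i, j - 1);  // j unpaired
      for (int k = i; k <= j - min_loop - 1; ++k) {
        double w = pair_weight(seq[k], seq[j], wgc, wau, wgu);
        if (w > 0.0) z += w * Zat(i, k - 1) * Zat(k + 1, j - 1);
      }
      Z[i][j] = z;
    }
  }
  const double Ztot = Zat(0, n - 1);
  if (!R_finite(Ztot))
    stop("partition function overflow; sequence too long for this engine");

  // outside values O(i,j) for segments generated by the same decomposition
  std::vector<std::vector<double>> O(n, std::vector<double>(n, 0.0));
  O[0][n - 1] = 1.0;
  std::vector<std::vector<double>> P(n, std::vector<double>(n, 0.0));
  for (int len = n; len >= 1; --len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      double o = O[i][j];
      if (o == 0.0) continue;
      if (j - 1 >= i) O[i][j - 1] += o;  // j unpaired
      for (int k = i; k <= j - min_loop - 1; ++k) {
        double w = pair_weight(seq[k], seq[j], wgc, wau, wgu);
        if (w <= 0.0) continue;
        double zl = Zat(i, k - 1), zr = Zat(k + 1, j - 1);
        P[k][j] += o * w * zl * zr;
        if (k - 1 >= i) O[i][k - 1] += o * w * zr;
        if (j - 1 >= k + 1) O[k + 1][j - 1] += o * w * zl;
      }
    }
  }
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double p = P[i][j] / Ztot;
      paired[i] += p;
      paired[j] += p;
    }
  }
  for (int i = 0; i < n; ++i) {
    if (paired[i] > 1.0) paired[i] = 1.0;  // guard rounding
  }
  return paired;
}

// [[Rcpp::export]]
std::string fold_mfe_dotbracket_cpp(std::string seq, int min_loop = 3,
                                    double wgc = 3.0, double wau = 2.0,
                                    double wgu = 1.0) {
  const int n = static_cast<int>(seq.size());
  std::string db(n, '.');
  if (n < 2) return db;
  for (auto &c : seq) c = static_cast<char>(toupper(c));
  // maximum total pair weight (Nussinov DP)
  std::vector<std::vector<double>> M(n, std::vector<double>(n, 0.0));
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      double best = M[i][j - 1];
      for (int k = i; k <= j - min_loop - 1; ++k) {
        double w = pair_weight(seq[k], seq[j], wgc, wau, wgu);
        if (w <= 0.0) continue;
        double v = w + (k > i ? M[i][k - 1] : 0.0) +
                   (k + 1 <= j - 1 ? M[k + 1][j - 1] : 0.0);
        if (v > best) best = v;
      }
      M[i][j] = best;
    }
  }
  // iterative traceback
  std::vector<std::pair<int, int>> stack;
  stack.push_back({0, n - 1});
  while (!stack.empty()) {
    auto seg = stack.back();
    stack.pop_back();
    int i = seg.first, j = seg.second;
    if (j - i < min_loop + 1) continue;
    if (M[i][j] == M[i][j - 1]) {
      stack.push_back({i, j - 1});
      continue;
    }
    for (int k = i; k <= j - min_loop - 1; ++k) {
      double w = pair_weight(seq[k], seq[j], wgc, wau, wgu);
      if (w <= 0.0) continue;
      double v = w + (k > i ? M[i][k - 1] : 0.0) +
                 (k + 1 <= j - 1 ? M[k + 1][j - 1] : 0.0);
      if (v == M[i][j]) {
        db[k] = '(';
        db[j] = ')';
        if (k > i) stack.push_back({i, k - 1});
        if (k + 1 <= j - 1) stack.push_back({k + 1, j - 1});
        break;
      }
    }
  }
  return db;
}
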