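#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// 5-state pair-HMM forward-backward in log space.
//
// States: M (match, consumes one column of each profile), X1/X2 (insert in
// A: consume a column of A only; short and long gap flavours), Y1/Y2
// (insert in B). Insert states transition only to themselves or back to M
// (ProbCons bi-phasic topology). Begin and end are treated as the match
// state (Durbin convention): entry uses M's outgoing transitions, exit uses
// each state's transition to M.
//
// Emissions are expected likelihood ratios (insert emissions cancel against
// the background), supplied as a precomputed log-odds matrix, so the total
// is a log-odds score and posteriors are proper probabilities.

static inline double lse2(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  double m = a > b ? a : b;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

// [[Rcpp::export(name = ".fb_pairhmm_cpp")]]
List fb_pairhmm_cpp(NumericMatrix logemit, double delta1, double delta2,
                    double eps1, double eps2) {
  const int L1 = logemit.nrow(), L2 = logemit.ncol();
  const double lMM = std::log(1.0 - 2.0 * delta1 - 2.0 * delta2);
  const double lMX1 = std::log(delta1), lMX2 = std::log(delta2);
  const double lX1X1 = std::log(eps1), lX1M = std::log(1.0 - eps1);
  const double lX2X2 = std::log(eps2), lX2M = std::log(1.0 - eps2);
  const double NEG = R_NegInf;

  const int R = L1 + 1, C = L2 + 1;
  auto idx = [C](int i, int j) { return i * C + j; };
  // state order: M, X1, X2, Y1, Y2 (X consume A rows, Y consume B cols)
  std::vector<std::vector<double>> f(5, std::vector<double>(R * C, NEG));
  f[0][idx(0, 0)] = 0.0;  // virtual start in M before any emission

  for (int i = 0; i <= L1; ++i) {
    for (int j = 0; j <= L2; ++j) {
      if (i == 0 && j == 0) continue;
      const int c = idx(i, j);
      if (i > 0 && j > 0) {
        const int p = idx(i - 1, j - 1);
        double acc = f[0][p] + lMM;
        acc = lse2(acc, f[1][p] + lX1M);
        acc = lse2(acc, f[2][p] + lX2M);
        acc = lse2(acc, f[3][p] + lX1M);
        acc = lse2(acc, f[4][p] + lX2M);
        f[0][c] = logemit(i - 1, j - 1) + acc;
      }
      if (i > 0) {
        const int p = idx(i - 1, j);
        f[1][c] = lse2(f[0][p] + lMX1, f[1][p] + lX1X1);
        f[2][c] = lse2(f[0][p] + lMX2, f[2][p] + lX2X2);
      }
      if (j > 0) {
        const int p = idx(i, j - 1);
        f[3][c] = lse2(f[0][p] + lMX1, f[3][p] + lX1X1);
        f[4][c] = lse2(f[0][p] + lMX2, f[4][p] + lX2X2);
      }
    }
  }
  const int e = idx(L1, L2);
  double total_f = f[0][e] + lMM;
  total_f = lse2(total_f, f[1][e] + lX1M);
  total_f = lse2(total_f, f[2][e] + lX2M);
  total_f = lse2(total_f, f[3][e] + lX1M);
  total_f = lse2(total_f, f[4][e] + lX2M);

  std::vector<std::vector<double>> b(5, std::vector<double>(R * C, NEG));
  b[0][e] = lMM;  // exit to virtual end treated as M
  b[1][e] = lX1M;
  b[2][e] = lX2M;
  b[3][e] = lX1M;
  b[4][e] = lX2M;

  for (int i = L1; i >= 0; --i) {
    for (int j = L2; j >= 0; --j) {
      if (i == L1 && j == L2) continue;
      const int c = idx(i, j);
      const double toM = (i < L1 && j < L2)
        ? logemit(i, j) + b[0][idx(i + 1, j + 1)] : NEG;
      double bm = (toM == NEG) ? NEG : lMM + toM;
      if (i < L1) {
        bm = lse2(bm, lMX1 + b[1][idx(i + 1, j)]);
        bm = lse2(bm, lMX2 + b[2][idx(i + 1, j)]);
      }
      if (j < L2) {
        bm = lse2(bm, lMX1 + b[3][idx(i, j + 1)]);
        bm = lse2(bm, lMX2 + b[4][idx(i, j + 1)]);
      }
      b[0][c] = bm;
      double bx1 = (toM == NEG) ? NEG : lX1M + toM;
      double bx2 = (toM == NEG) ? NEG : lX2M + toM;
      if (i < L1) {
        bx1 = lse2(bx1, lX1X1 + b[1][idx(i + 1, j)]);
        bx2 = lse2(bx2, lX2X2 + b[2][idx(i + 1, j)]);
      }
      b[1][c] = bx1;
      b[2][c] = bx2;
      double by1 = (toM == NEG) ? NEG : lX1M + toM;
      double by2 = (toM == NEG) ? NEG : lX2M + toM;
      if (j < L2) {
        by1 = lse2(by1, lX1X1 + b[3][idx(i, j + 1)]);
        by2 = lse2(by2, lX2X2 + b[4][idx(i, j + 1)]);
      }
      b[3][c] = by1;
      b[4][c] = by2;
    }
  }
  const double total_b = b[0][idx(0, 0)];

  NumericMatrix post(L1, L2);
  for (int i = 1; i <= L1; ++i) {
    for (int j = 1; j <= L2; ++j) {
      const double lp = f[0][idx(i, j)] + b[0][idx(i, j)] - total_f;
      double p = std::exp(lp);
      if (p > 1.0) p = 1.0;  // clip fp jitter at machine precision
      post(i - 1, j - 1) = p;
    }
  }
  return List::create(_["posterior"] = post, _["loglik_forward"] = total_f,
                      _["loglik_backward"] = total_b);
}
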