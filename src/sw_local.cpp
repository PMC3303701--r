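#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Affine-gap local alignment (Gotoh) with exact state-machine traceback,
// used by the built-in search backend. Sequences arrive as 0-based integer
// codes into the score matrix; a gap of length k costs open + k * extend.
// Returns the best local alignment with 1-based coordinates and aligned
// index paths (0 denotes a gap).

// [[Rcpp::export(name = ".sw_local_cpp")]]
List sw_local_cpp(IntegerVector q, IntegerVector s, NumericMatrix mat,
                  double open, double extend) {
  const int n = q.size(), m = s.size();
  const double NEG = -1e30;
  std::vector<double> H((n + 1) * (m + 1), 0.0), E((n + 1) * (m + 1), NEG),
      F((n + 1) * (m + 1), NEG);
  // per-cell decisions: tb 0 stop / 1 diag / 2 from-F / 3 from-E;
  // eOpen, fOpen: the gap state was entered (not extended) at this cell
  std::vector<unsigned char> tb((n + 1) * (m + 1), 0),
      eOpen((n + 1) * (m + 1), 1), fOpen((n + 1) * (m + 1), 1);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int c = at(i, j);
      const double e1 = H[at(i, j - 1)] - open - extend;
      const double e2 = E[at(i, j - 1)] - extend;
      if (e1 >= e2) { E[c] = e1; eOpen[c] = 1; } else { E[c] = e2; eOpen[c] = 0; }
      const double f1 = H[at(i - 1, j)] - open - extend;
      const double f2 = F[at(i - 1, j)] - extend;
      if (f1 >= f2) { F[c] = f1; fOpen[c] = 1; } else { F[c] = f2; fOpen[c] = 0; }
      const double diag = H[at(i - 1, j - 1)] + mat(q[i - 1], s[j - 1]);
      double h = diag;
      unsigned char t = 1;
      if (F[c] > h) { h = F[c]; t = 2; }
      if (E[c] > h) { h = E[c]; t = 3; }
      if (h <= 0.0) { h = 0.0; t = 0; }
      H[c] = h;
      tb[c] = t;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (best <= 0.0) {
    return List::create(_["score"] = 0.0, _["qstart"] = 0, _["qend"] = 0,
                        _["sstart"] = 0, _["send"] = 0,
                        _["qpath"] = IntegerVector(0),
                        _["spath"] = IntegerVector(0));
  }
  std::vector<int> qp, sp;
  int i = bi, j = bj;
  int state = 0;  // 0 = H, 1 = F (gap in subject), 2 = E (gap in query)
  while (i > 0 || j > 0) {
    if (state == 0) {
      const unsigned char t = tb[at(i, j)];
      if (t == 0) break;
      if (t == 1) { qp.push_back(i); sp.push_back(j); --i; --j; }
      else if (t == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      qp.push_back(i); sp.push_back(0);
      state = fOpen[at(i, j)] ? 0 : 1;
      --i;
    } else {
      qp.push_back(0); sp.push_back(j);
      state = eOpen[at(i, j)] ? 0 : 2;
      --j;
    }
  }
  std::reverse(qp.begin(), qp.end());
  std::reverse(sp.begin(), sp.end());
  // trim leading/trailing gap columns (local alignments end on matches, but
  // guard anyway) and derive spans from the path
  int lo = 0, hi = (int) qp.size();
  while (lo < hi && (qp[lo] == 0 || sp[lo] == 0)) ++lo;
  while (hi > lo && (qp[hi - 1] == 0 || sp[hi - 1] == 0)) --hi;
  std::vector<int> qp2(qp.begin() + lo, qp.begin() + hi);
  std::vector<int> sp2(sp.begin() + lo, sp.begin() + hi);
  int qstart = 0, qend = 0, sstart = 0, send = 0;
  for (size_t k = 0; k < qp2.size(); ++k) {
    if (qp2[k] > 0) { if (qstart == 0) qstart = qp2[k]; qend = qp2[k]; }
    if (sp2[k] > 0) { if (sstart == 0) sstart = sp2[k]; send = sp2[k]; }
  }
  return List::create(_["score"] = best, _["qstart"] = qstart,
                      _["qend"] = qend, _["sstart"] = sstart,
                      _["send"] = send,
                      _["qpath"] = IntegerVector(qp2.begin(), qp2.end()),
                      _["spath"] = IntegerVector(sp2.begin(), sp2.end()));
}
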