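// Smith-Waterman local alignment with affine gaps. A gap of length L costs
// gap_open + L * gap_extend (the Biostrings convention). Traceback is
// deterministic: the best cell is the first maximum in row-major order and
// ties between moves prefer diagonal, then up (gap in subject), then left
// (gap in query).

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
List cpp_smith_waterman(IntegerVector q, IntegerVector s, IntegerMatrix score,
                        double gap_open, double gap_extend) {
  int n = q.size(), m = s.size();
  double NEG = -1e18;
  double gi = gap_open + gap_extend; // cost of starting a gap of length 1
  std::vector<double> H((n + 1) * (m + 1), 0.0), Ee((n + 1) * (m + 1), NEG),
      F((n + 1) * (m + 1), NEG);
  std::vector<unsigned char> ptr((n + 1) * (m + 1), 0); // 0 stop,1 diag,2 up,3 left
  std::vector<unsigned char> pe((n + 1) * (m + 1), 0);  // E from: 0 open,1 extend
  std::vector<unsigned char> pf((n + 1) * (m + 1), 0);
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int id = i * (m + 1) + j;
      int up = (i - 1) * (m + 1) + j, lf = id - 1, dg = up - 1;
      // F: gap in subject (consume query residue)
      double fo = H[up] - gi, fe = F[up] - gap_extend;
      F[id] = fo >= fe ? (pf[id] = 0, fo) : (pf[id] = 1, fe);
      // E: gap in query (consume subject residue)
      double eo = H[lf] - gi, ee = Ee[lf] - gap_extend;
      Ee[id] = eo >= ee ? (pe[id] = 0, eo) : (pe[id] = 1, ee);
      double dia = H[dg] + score(q[i - 1] - 1, s[j - 1] - 1);
      double h = 0.0;
      unsigned char p = 0;
      if (dia >= h) { h = dia; p = 1; }
      if (F[id] > h) { h = F[id]; p = 2; }
      if (Ee[id] > h) { h = Ee[id]; p = 3; }
      if (h <= 0.0) { h = 0.0; p = 0; }
      H[id] = h;
      ptr[id] = p;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  // traceback
  std::vector<int> qa, sa; // aligned pairs, 0 = gap
  int i = bi, j = bj;
  int state = 0; // 0 in H, 1 in F(up), 2 in E(left)
  while (i > 0 && j > 0) {
    int id = i * (m + 1) + j;
    if (state == 0) {
      if (ptr[id] == 0) break;
      if (ptr[id] == 1) {
        qa.push_back(q[i - 1]); sa.push_back(s[j - 1]); --i; --j;
      } else if (ptr[id] == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      qa.push_back(q[i - 1]); sa.push_back(0);
      state = pf[id] == 0 ? 0 : 1;
      --i;
    } else {
      qa.push_back(0); sa.push_back(s[j - 1]);
      state = pe[id] == 0 ? 0 : 2;
      --j;
    }
  }
  std::reverse(qa.begin(), qa.end());
  std::reverse(sa.begin(), sa.end());
  int len = qa.size(), matches = 0;
  for (int t = 0; t < len; ++t)
    if (qa[t] != 0 && sa[t] != 0 && qa[t] == sa[t]) ++matches;
  return List::create(_["score"] = best,
                      _["q_start"] = best > 0 ? i : 0, _["q_end"] = bi,
                      _["s_start"] = best > 0 ? j : 0, _["s_end"] = bj,
                      _["aligned_q"] = IntegerVector(qa.begin(), qa.end()),
                      _["aligned_s"] = IntegerVector(sa.begin(), sa.end()),
                      _["matches"] = matches);
}
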