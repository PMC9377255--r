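#include <Rcpp.h>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gap penalties.
//
// Scoring: substitution matrix `submat` indexed by 0-based residue codes;
// a gap of length k costs gap_open + k * gap_ext (BLAST "existence 11,
// extension 1" convention).
//
// Determinism: the traceback starts at the highest-scoring cell with the
// smallest (row, col) pair in lexicographic order (row = query index), and
// at each step prefers diagonal over up (gap in target) over left (gap in
// query).
//
// Returns 1-based alignment column indices: q_idx[k] / t_idx[k] give the
// query / target residue in column k, or 0 for a gap.
// [[Rcpp::export]]
List sw_align_cpp(IntegerVector q, IntegerVector t, NumericMatrix submat,
                  double gap_open, double gap_ext) {
  const int n = q.size(), m = t.size();
  if (n == 0 || m == 0) stop("empty sequence");

  // H: best score ending at (i,j); E: ending with gap in query (left move);
  // F: ending with gap in target (up move). Row-major (n+1) x (m+1).
  std::vector<double> H((size_t)(n + 1) * (m + 1), 0.0);
  std::vector<double> E((size_t)(n + 1) * (m + 1), R_NegInf);
  std::vector<double> F((size_t)(n + 1) * (m + 1), R_NegInf);
  const double gapfirst = gap_open + gap_ext;

  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const size_t row = (size_t)i * (m + 1), prow = (size_t)(i - 1) * (m + 1);
    const int qi = q[i - 1];
    for (int j = 1; j <= m; ++j) {
      double e = std::max(H[row + j - 1] - gapfirst, E[row + j - 1] - gap_ext);
      double f = std::max(H[prow + j] - gapfirst, F[prow + j] - gap_ext);
      double d = H[prow + j - 1] + submat(qi, t[j - 1]);
      double h = std::max(0.0, std::max(d, std::max(e, f)));
      E[row + j] = e;
      F[row + j] = f;
      H[row + j] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  std::vector<int> qa, ta;  // reversed alignment columns (0 = gap)
  if (best > 0.0) {
    int i = bi, j = bj;
    int state = 0;  // 0 = H, 1 = F (up), 2 = E (left)
    while (i > 0 && j > 0) {
      const size_t row = (size_t)i * (m + 1), prow = (size_t)(i - 1) * (m + 1);
      if (state == 0) {
        double h = H[row + j];
        if (h == 0.0) break;
        double d = H[prow + j - 1] + submat(q[i - 1], t[j - 1]);
        if (h == d) {
          qa.push_back(i); ta.push_back(j); --i; --j;
        } else if (h == F[row + j]) {
          state = 1;
        } else {
          state = 2;
        }
      } else if (state == 1) {  // gap in target, consume query residue
        qa.push_back(i); ta.push_back(0);
        double f = F[row + j];
        bool open_here = (f == H[prow + j] - gapfirst);
        --i;
        if (open_here) state = 0;
      } else {  // gap in query, consume target residue
        qa.push_back(0); ta.push_back(j);
        double e = E[row + j];
        bool open_here = (e == H[row + j - 1] - gapfirst);
        --j;
        if (open_here) state = 0;
      }
    }
  }

  const int L = qa.size();
  IntegerVector q_idx(L), t_idx(L);
  for (int k = 0; k < L; ++k) {
    q_idx[k] = qa[L - 1 - k];
    t_idx[k] = ta[L - 1 - k];
  }
  return List::create(_["score"] = best, _["q_idx"] = q_idx,
                      _["t_idx"] = t_idx);
}
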