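#include <Rcpp.h>
using namespace Rcpp;

// Best-match selection between the unique k-mers of two sequences.
//
// A, B: n_a x k and n_b x k integer matrices of 1-based residue indices
// into D (the 20 x 20 per-residue similarity matrix). qa, qb: occurrence
// frequencies. lexa, lexb: alphabetical ranks of the k-mer strings.
//
// For each row i of the implicit similarity matrix W (w = mean of
// position-wise D) the best column is the one maximizing w, ties broken
// by the lowest LD(q_i, t_j) = 2(q_i^2 + t_j^2)/(q_i + t_j), then by the
// lexicographically smallest target k-mer; symmetrically for columns.
// Arithmetic (sum over positions in order, then divide by k) matches the
// pure-R path bit for bit so ties resolve identically.
//
// Returns 1-based best indices and the attained w for both directions.
// [[Rcpp::export(name = ".Call_best_match")]]
List best_match_cpp(IntegerMatrix A, IntegerMatrix B, NumericMatrix D,
                    IntegerVector qa, IntegerVector qb,
                    IntegerVector lexa, IntegerVector lexb) {
  const int na = A.nrow(), nb = B.nrow(), k = A.ncol();
  NumericMatrix W(na, nb);
  for (int p = 0; p < k; ++p) {
    for (int j = 0; j < nb; ++j) {
      const int bj = B(j, p) - 1;
      for (int i = 0; i < na; ++i)
        W(i, j) += D(A(i, p) - 1, bj);
    }
  }
  for (int j = 0; j < nb; ++j)
    for (int i = 0; i < na; ++i)
      W(i, j) /= k;

  IntegerVector rowBest(na), colBest(nb);
  NumericVector rowW(na), colW(nb);

  for (int i = 0; i < na; ++i) {
    int best = 0;
    double bw = W(i, 0);
    double bld = 2.0 * ((double)qa[i] * qa[i] + (double)qb[0] * qb[0]) /
                 (qa[i] + qb[0]);
    for (int j = 1; j < nb; ++j) {
      const double w = W(i, j);
      if (w < bw) continue;
      const double ld = 2.0 * ((double)qa[i] * qa[i] + (double)qb[j] * qb[j]) /
                        (qa[i] + qb[j]);
      if (w > bw || ld < bld || (ld == bld && lexb[j] < lexb[best])) {
        best = j; bw = w; bld = ld;
      }
    }
    rowBest[i] = best + 1;
    rowW[i] = bw;
  }
  for (int j = 0; j < nb; ++j) {
    int best = 0;
    double bw = W(0, j);
    double bld = 2.0 * ((double)qb[j] * qb[j] + (double)qa[0] * qa[0]) /
                 (qb[j] + qa[0]);
    for (int i = 1; i < na; ++i) {
      const double w = W(i, j);
      if (w < bw) continue;
      const double ld = 2.0 * ((double)qb[j] * qb[j] + (double)qa[i] * qa[i]) /
                        (qb[j] + qa[i]);
      if (w > bw || ld < bld || (ld == bld && lexa[i] < lexa[best])) {
        best = i; bw = w; bld = ld;
      }
    }
    colBest[j] = best + 1;
    colW[j] = bw;
  }
  return List::create(_["rowBest"] = rowBest, _["rowW"] = rowW,
                      _["colBest"] = colBest, _["colW"] = colW);
}
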