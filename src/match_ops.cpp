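// Offset search and permutation null for the Tomtom-style motif
// comparison. M is the (Wq x Wt) matrix of column-wise Pearson
// correlations between a query PPM and a target PWM (computed in R from
// standardized columns). The alignment score at offset o is
// sum_i M(i, i + o) over overlapping columns, maximized over all offsets
// with at least `min_ov` overlapping columns.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
List match_best_cpp(const arma::mat& M, int min_ov) {
  const int Wq = M.n_rows, Wt = M.n_cols;
  double best = -std::numeric_limits<double>::infinity();
  int best_off = 0, best_ov = 0;
  for (int o = -(Wq - min_ov); o <= Wt - min_ov; ++o) {
    const int i0 = std::max(0, -o);
    const int i1 = std::min(Wq, Wt - o);  // exclusive
    if (i1 - i0 < min_ov) continue;
    double s = 0.0;
    for (int i = i0; i < i1; ++i) s += M(i, i + o);
    if (s > best) { best = s; best_off = o; best_ov = i1 - i0; }
  }
  return List::create(_["score"] = best, _["offset"] = best_off,
                      _["overlap"] = best_ov);
}

// perms: n_shuffle x Wq matrix of 0-based row indices into M defining
// each null query's columns (a permutation of the query's own columns,
// or draws from a pooled column collection). Returns the
// best-over-offsets score for each null query.
// [[Rcpp::export]]
arma::vec match_null_cpp(const arma::mat& M, const arma::imat& perms,
                         int min_ov) {
  const int Wq = perms.n_cols, Wt = M.n_cols;
  const int n = perms.n_rows;
  arma::vec out(n);
  for (int r = 0; r < n; ++r) {
    double best = -std::numeric_limits<double>::infinity();
    for (int o = -(Wq - min_ov); o <= Wt - min_ov; ++o) {
      const int i0 = std::max(0, -o);
      const int i1 = std::min(Wq, Wt - o);
      if (i1 - i0 < min_ov) continue;
      double s = 0.0;
      for (int i = i0; i < i1; ++i) s += M(perms(r, i), i + o);
      if (s > best) best = s;
    }
    out(r) = best;
  }
  return out;
}
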