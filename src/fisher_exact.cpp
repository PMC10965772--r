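#include <Rcpp.h>
#include <vector>
#include <cmath>

// Exact two-sided Fisher test for an r x c table: sum, over all tables
// with the observed margins, of the hypergeometric probabilities that do
// not exceed the observed table's probability.  Depth-first enumeration
// row by row with column-remainder bounds; probabilities in log space.

namespace {

struct Enumerator {
  int R, C;
  std::vector<int> colrem;     // remaining column margins
  std::vector<int> rowsum;     // row margins
  double log_const;            // sum lgamma(r_i+1)+lgamma(c_j+1)-lgamma(N+1)
  double logp_obs;             // observed table log-probability
  double psum;                 // accumulated two-sided p

  // suffix sums of colrem are recomputed per cell from colrem directly;
  // tables are small so the O(C) inner cost is irrelevant.
  void run_row(int row, double partial) {
    if (row == R - 1) {
      double lp = partial;
      for (int j = 0; j < C; ++j) lp -= std::lgamma(colrem[j] + 1.0);
      lp += log_const;
      if (lp <= logp_obs + 1e-7) psum += std::exp(lp);
      return;
    }
    run_cell(row, 0, rowsum[row], partial);
  }

  void run_cell(int row, int col, int rem, double partial) {
    if (col == C - 1) {
      if (rem <= colrem[col]) {
        colrem[col] -= rem;
        run_row(row + 1, partial - std::lgamma(rem + 1.0));
        colrem[col] += rem;
      }
      return;
    }
    int later = 0;
    for (int j = col + 1; j < C; ++j) later += colrem[j];
    int lo = rem - later; if (lo < 0) lo = 0;
    int hi = rem < colrem[col] ? rem : colrem[col];
    for (int x = lo; x <= hi; ++x) {
      colrem[col] -= x;
      run_cell(row, col + 1, rem - x, partial - std::lgamma(x + 1.0));
      colrem[col] += x;
    }
  }
};

} // namespace

// [[Rcpp::export]]
double fisher_exact_rxc_cpp(Rcpp::IntegerMatrix counts) {
  Enumerator e;
  e.R = counts.nrow();
  e.C = counts.ncol();
  e.rowsum.assign(e.R, 0);
  e.colrem.assign(e.C, 0);
  int N = 0;
  for (int i = 0; i < e.R; ++i)
    for (int j = 0; j < e.C; ++j) {
      int x = counts(i, j);
      if (x < 0) Rcpp::stop("negative count in contingency table");
      e.rowsum[i] += x;
      e.colrem[j] += x;
      N += x;
    }
  if (N == 0) Rcpp::stop("empty contingency table");

  e.log_const = -std::lgamma(N + 1.0);
  for (int i = 0; i < e.R; ++i) e.log_const += std::lgamma(e.rowsum[i] + 1.0);
  for (int j = 0; j < e.C; ++j) e.log_const += std::lgamma(e.colrem[j] + 1.0);

  double lp_obs = e.log_const;
  for (int i = 0; i < e.R; ++i)
    for (int j = 0; j < e.C; ++j)
      lp_obs -= std::lgamma(counts(i, j) + 1.0);
  e.logp_obs = lp_obs;
  e.psum = 0.0;
  e.run_row(0, 0.0);
  return e.psum > 1.0 ? 1.0 : e.psum;
}

// Log-probability of each table in a list under the fixed-margin
// hypergeometric model, used by the Monte-Carlo method.
// [[Rcpp::export]]
Rcpp::NumericVector table_log_prob_cpp(Rcpp::List tables, double log_const) {
  int n = tables.size();
  Rcpp::NumericVector out(n);
  for (int k = 0; k < n; ++k) {
    Rcpp::IntegerMatrix t = tables[k];
    double lp = log_const;
    for (int i = 0; i < t.nrow(); ++i)
      for (int j = 0; j < t.ncol(); ++j)
        lp -= std::lgamma(t(i, j) + 1.0);
    out[k] = lp;
  }
  return out;
}
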