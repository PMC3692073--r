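#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Mutual information between every pair of columns of an integer-coded
// alignment. code(s, c) is 1..20 for standard residues, 0 for gap/unknown
// (skipped). For each pair, weighted joint counts over sequences where both
// residues are standard get the pseudocount lambda added to every cell of
// the 20x20 table before normalization; MI is in nats. Pairs with fewer
// than two contributing sequences are degenerate and returned as NA.
// [[Rcpp::export]]
NumericMatrix mi_matrix_cpp(IntegerMatrix code, NumericVector w,
                            double lambda) {
  const int n = code.nrow(), m = code.ncol();
  NumericMatrix out(m, m);
  std::fill(out.begin(), out.end(), NA_REAL);
  std::vector<double> joint(400);
  std::vector<double> pi(20), pj(20);

  for (int i = 0; i < m; ++i) {
    for (int j = i + 1; j < m; ++j) {
      std::fill(joint.begin(), joint.end(), 0.0);
      int contrib = 0;
      for (int s = 0; s < n; ++s) {
        const int a = code(s, i), b = code(s, j);
        if (a > 0 && b > 0) {
          joint[(a - 1) * 20 + (b - 1)] += w[s];
          ++contrib;
        }
      }
      if (contrib < 2) continue;  // degenerate pair -> NA

      double tot = 400.0 * lambda;
      for (int k = 0; k < 400; ++k) tot += joint[k];
      std::fill(pi.begin(), pi.end(), 0.0);
      std::fill(pj.begin(), pj.end(), 0.0);
      for (int a = 0; a < 20; ++a)
        for (int b = 0; b < 20; ++b) {
          const double p = (joint[a * 20 + b] + lambda) / tot;
          joint[a * 20 + b] = p;
          pi[a] += p;
          pj[b] += p;
        }
      double mi = 0.0;
      for (int a = 0; a < 20; ++a)
        for (int b = 0; b < 20; ++b) {
          const double p = joint[a * 20 + b];
          if (p > 0.0) mi += p * std::log(p / (pi[a] * pj[b]));
        }
      out(i, j) = mi;
      out(j, i) = mi;
    }
  }
  return out;
}
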