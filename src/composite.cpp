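// Composite log-likelihood evaluation over a grid of (rho0, rho1) rate
// pairs.  Each SNP pair contributes the interpolated log two-locus sampling
// probability at the scaled rate rho = rho0 * d_out + rho1 * d_in, where
// d_in / d_out are the kb of the inter-SNP span inside / outside the test
// interval.  logp_t is the table of log-probabilities laid out grid-major
// (G rows, one column per canonical configuration) so each pair's grid
// values are contiguous.  Rates above the grid maximum clamp to the last
// grid column.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector cl_eval_cpp(IntegerVector cfg_col, NumericVector d_in,
                          NumericVector d_out, NumericMatrix logp_t,
                          NumericVector grid, NumericVector r0,
                          NumericVector r1) {
  const int P = cfg_col.size();
  const int C = r0.size();
  const int G = grid.size();
  if (d_in.size() != P || d_out.size() != P) stop("pair vectors differ in length");
  if (r1.size() != C) stop("r0 and r1 differ in length");
  if (logp_t.nrow() != G) stop("logp_t must have one row per grid point");

  const double* gp = REAL(grid);
  const double* lp = REAL(logp_t);
  const double gmax = gp[G - 1];

  std::vector<const double*> base(P);
  for (int p = 0; p < P; ++p) {
    int c = cfg_col[p];
    if (c < 0 || c >= logp_t.ncol()) stop("configuration column out of range");
    base[p] = lp + (size_t)c * G;
  }

  // hinted bracketing: cell c of a uniform lookup stores the first grid
  // index exceeding the cell start, so locating rho is O(1) + a short walk
  const int NL = 4096;
  const double step = gmax > 0 ? gmax / NL : 1.0;
  std::vector<int> hint(NL + 1);
  {
    int j = 0;
    for (int c = 0; c <= NL; ++c) {
      double x = c * step;
      while (j < G && gp[j] <= x) ++j;
      hint[c] = j; // first grid index with gp[j] > c*step (G if none)
    }
  }

  auto interp = [&](const double* row, double rho) -> double {
    if (rho >= gmax) return row[G - 1];
    if (rho <= gp[0]) return row[0];
    int j = hint[(int)(rho / step)];
    while (j < G && gp[j] <= rho) ++j; // j = first grid point > rho
    double w = (rho - gp[j - 1]) / (gp[j] - gp[j - 1]);
    return row[j - 1] + w * (row[j] - row[j - 1]);
  };

  // pairs with d_in == 0 depend on rho0 only: compute their sum once per
  // distinct rho0 and share it across all combos with that rho0
  std::vector<int> span, nospan;
  span.reserve(P); nospan.reserve(P);
  for (int p = 0; p < P; ++p)
    (d_in[p] > 0.0 ? span : nospan).push_back(p);

  std::vector<double> r0_seen;
  std::vector<double> sum0;
  std::vector<int> combo_r0(C);
  for (int c = 0; c < C; ++c) {
    int u = -1;
    for (size_t k = 0; k < r0_seen.size(); ++k)
      if (r0_seen[k] == r0[c]) { u = (int)k; break; }
    if (u < 0) {
      u = (int)r0_seen.size();
      r0_seen.push_back(r0[c]);
      double s = 0.0;
      for (int p : nospan) s += interp(base[p], r0[c] * d_out[p]);
      sum0.push_back(s);
    }
    combo_r0[c] = u;
  }

  NumericVector out(C);
  for (int c = 0; c < C; ++c) {
    const double a = r0[c], b = r1[c];
    double s = sum0[combo_r0[c]];
    for (int p : span)
      s += interp(base[p], a * d_out[p] + b * d_in[p]);
    out[c] = s;
  }
  return out;
}
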