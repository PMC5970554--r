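#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sample-entropy pair counts, Richman-Moorman convention: N - m template
// vectors for both dimension m (count B) and dimension m+1 (count A),
// Chebyshev distance, self-matches excluded. Counts unordered pairs; the
// ratio A/B is unaffected by the factor of two.
// [[Rcpp::export(name = ".cpp_sampen_counts")]]
List cpp_sampen_counts(NumericVector x, int m, double r) {
  int N = x.size();
  int nt = N - m; // templates of length m and of length m+1
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      bool close_m = true;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(x[i + k] - x[j + k]) > r) { close_m = false; break; }
      }
      if (!close_m) continue;
      B += 1.0;
      if (std::fabs(x[i + m] - x[j + m]) <= r) A += 1.0;
    }
  }
  return List::create(_["A"] = A, _["B"] = B);
}

// Recurrence rate and determinism of a delay-embedded window without
// materialising the full recurrence matrix: scans each diagonal offset for
// runs of recurrent points (Euclidean norm, threshold eps, line of identity
// excluded). Returns raw counts so the caller can form RR and DET.
// [[Rcpp::export(name = ".cpp_rqa_measures")]]
List cpp_rqa_measures(NumericMatrix pts, double eps, int lmin) {
  int n = pts.nrow(), d = pts.ncol();
  double eps2 = eps * eps;
  double rec = 0.0, det_pts = 0.0;
  for (int off = 1; off < n; ++off) {
    int run = 0;
    for (int i = 0; i + off < n; ++i) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        double dd = pts(i, k) - pts(i + off, k);
        s += dd * dd;
      }
      if (s <= eps2) {
        rec += 1.0; ++run;
      } else {
        if (run >= lmin) det_pts += run;
        run = 0;
      }
    }
    if (run >= lmin) det_pts += run;
  }
  // upper triangle scanned; symmetric matrix doubles both counts
  double n_off = (double)n * (n - 1);
  double rr = (2.0 * rec) / n_off;
  double det = rec > 0.0 ? det_pts / rec : 0.0;
  return List::create(_["rr"] = rr, _["det"] = det,
                      _["recurrences"] = 2.0 * rec,
                      _["det_points"] = 2.0 * det_pts);
}
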