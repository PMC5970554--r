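#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Natural cubic spline through (t, y), evaluated at xout.
// Knots must be strictly increasing. Natural boundary (zero second
// derivative) is the conventional choice for EMD envelopes.
static std::vector<double> spline_eval(const std::vector<double>& t,
                                       const std::vector<double>& y,
                                       const std::vector<double>& xout) {
  int n = t.size();
  std::vector<double> out(xout.size());
  if (n == 1) {
    for (size_t k = 0; k < xout.size(); ++k) out[k] = y[0];
    return out;
  }
  if (n == 2) { // linear
    double slope = (y[1] - y[0]) / (t[1] - t[0]);
    for (size_t k = 0; k < xout.size(); ++k)
      out[k] = y[0] + slope * (xout[k] - t[0]);
    return out;
  }
  // second derivatives M via tridiagonal solve (natural BC: M0 = Mn-1 = 0)
  std::vector<double> h(n - 1), alpha(n, 0.0), l(n), mu(n), z(n), M(n);
  for (int i = 0; i < n - 1; ++i) h[i] = t[i + 1] - t[i];
  for (int i = 1; i < n - 1; ++i)
    alpha[i] = 3.0 * ((y[i + 1] - y[i]) / h[i] - (y[i] - y[i - 1]) / h[i - 1]);
  l[0] = 1.0; mu[0] = 0.0; z[0] = 0.0;
  for (int i = 1; i < n - 1; ++i) {
    l[i] = 2.0 * (t[i + 1] - t[i - 1]) - h[i - 1] * mu[i - 1];
    mu[i] = h[i] / l[i];
    z[i] = (alpha[i] - h[i - 1] * z[i - 1]) / l[i];
  }
  M[n - 1] = 0.0;
  for (int i = n - 2; i >= 0; --i) M[i] = z[i] - mu[i] * M[i + 1];
  M[0] = 0.0;

  int seg = 0;
  for (size_t k = 0; k < xout.size(); ++k) {
    double x = xout[k];
    while (seg < n - 2 && x > t[seg + 1]) ++seg;
    while (seg > 0 && x < t[seg]) --seg;
    double hh = h[seg];
    double a = (t[seg + 1] - x) / hh, b = (x - t[seg]) / hh;
    out[k] = a * y[seg] + b * y[seg + 1] +
      ((a * a * a - a) * M[seg] + (b * b * b - b) * M[seg + 1]) * hh * hh / 6.0;
  }
  return out;
}

// Strict local extrema; plateaus contribute their midpoint index (0-based).
static void extrema_scan(const std::vector<double>& x,
                         std::vector<int>& imax, std::vector<int>& imin) {
  int n = x.size();
  imax.clear(); imin.clear();
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && x[j + 1] == x[i]) ++j;
    if (i > 0 && j < n - 1) {
      if (x[i - 1] < x[i] && x[j + 1] < x[i]) imax.push_back((i + j) / 2);
      if (x[i - 1] > x[i] && x[j + 1] > x[i]) imin.push_back((i + j) / 2);
    }
    i = j + 1;
  }
}

// [[Rcpp::export(name = ".cpp_find_extrema")]]
List cpp_find_extrema(NumericVector x) {
  std::vector<double> xv(x.begin(), x.end());
  std::vector<int> imax, imin;
  extrema_scan(xv, imax, imin);
  IntegerVector mx(imax.begin(), imax.end()), mn(imin.begin(), imin.end());
  return List::create(_["maxima"] = mx + 1, _["minima"] = mn + 1);
}

// Mirror-extend extrema knots (indices idx, values val) about 0 and n-1.
// Uses up to two extrema at each end so the spline covers [0, n-1].
static void mirror_knots(const std::vector<int>& idx,
                         const std::vector<double>& val, int n,
                         std::vector<double>& t, std::vector<double>& y) {
  int ne = idx.size();
  t.clear(); y.clear();
  int nl = std::min(2, ne);
  for (int k = nl - 1; k >= 0; --k) {
    if (idx[k] > 0) { t.push_back(-(double)idx[k]); y.push_back(val[k]); }
  }
  // reverse the left extension so knots are ascending
  std::reverse(t.begin(), t.end());
  std::reverse(y.begin(), y.end());
  for (int k = 0; k < ne; ++k) { t.push_back(idx[k]); y.push_back(val[k]); }
  int nr = std::min(2, ne);
  for (int k = 0; k < nr; ++k) {
    int src = ne - 1 - k;
    if (idx[src] < n - 1) {
      t.push_back(2.0 * (n - 1) - idx[src]); y.push_back(val[src]);
    }
  }
  // drop any duplicated knot positions (can arise from plateaus at ends)
  std::vector<double> tt, yy;
  for (size_t k = 0; k < t.size(); ++k) {
    if (tt.empty() || t[k] > tt.back() + 1e-9) { tt.push_back(t[k]); yy.push_back(y[k]); }
  }
  t = tt; y = yy;
}

// Mean of upper/lower cubic-spline envelopes; ok=false when < 2 maxima or
// < 2 minima (signals the caller to stop sifting).
static bool envelope_mean_1d(const std::vector<double>& x,
                             std::vector<double>& mean_env) {
  int n = x.size();
  std::vector<int> imax, imin;
  extrema_scan(x, imax, imin);
  if ((int)imax.size() < 2 || (int)imin.size() < 2) return false;
  std::vector<double> vmax(imax.size()), vmin(imin.size());
  for (size_t k = 0; k < imax.size(); ++k) vmax[k] = x[imax[k]];
  for (size_t k = 0; k < imin.size(); ++k) vmin[k] = x[imin[k]];
  std::vector<double> grid(n);
  for (int k = 0; k < n; ++k) grid[k] = k;
  std::vector<double> tu, yu, tl, yl;
  mirror_knots(imax, vmax, n, tu, yu);
  mirror_knots(imin, vmin, n, tl, yl);
  std::vector<double> up = spline_eval(tu, yu, grid);
  std::vector<double> lo = spline_eval(tl, yl, grid);
  mean_env.resize(n);
  for (int k = 0; k < n; ++k) mean_env[k] = 0.5 * (up[k] + lo[k]);
  return true;
}

// [[Rcpp::export(name = ".cpp_envelope_mean")]]
NumericVector cpp_envelope_mean(NumericVector x) {
  std::vector<double> xv(x.begin(), x.end()), m;
  if (!envelope_mean_1d(xv, m)) return NumericVector(0);
  return NumericVector(m.begin(), m.end());
}

// sign changes, exact zeros skipped
static int count_zero_crossings(const std::vector<double>& x) {
  int zc = 0, prev = 0;
  for (size_t k = 0; k < x.size(); ++k) {
    int s = (x[k] > 0) - (x[k] < 0);
    if (s == 0) continue;
    if (prev != 0 && s != prev) ++zc;
    prev = s;
  }
  return zc;
}

// true when |#extrema - #zero-crossings| <= 1 (the IMF property)
static bool imf_property(const std::vector<double>& h) {
  std::vector<int> imax, imin;
  extrema_scan(h, imax, imin);
  int ne = imax.size() + imin.size();
  return std::abs(ne - count_zero_crossings(h)) <= 1;
}

// Classic univariate EMD. Sifting stops once the Cauchy-type SD criterion
// is met AND the proto-IMF has |#extrema - #zero-crossings| <= 1 (or at
// max_sift iterations); each IMF is subtracted from the running residual;
// decomposition stops when the residual is monotone (< 2 maxima or
// < 2 minima) or max_imfs is reached.
// [[Rcpp::export(name = ".cpp_emd")]]
List cpp_emd(NumericVector x, int max_imfs, int max_sift, double sd_thresh) {
  int n = x.size();
  std::vector<double> r(x.begin(), x.end());
  std::vector< std::vector<double> > imfs;
  while ((int)imfs.size() < max_imfs) {
    std::vector<int> imax, imin;
    extrema_scan(r, imax, imin);
    if ((int)imax.size() < 2 || (int)imin.size() < 2) break;
    std::vector<double> h = r, m;
    for (int it = 0; it < max_sift; ++it) {
      if (!envelope_mean_1d(h, m)) break;
      double num = 0.0, den = 0.0;
      for (int k = 0; k < n; ++k) {
        num += m[k] * m[k];          // (h_prev - h_new) = m
        den += h[k] * h[k];
        h[k] -= m[k];
      }
      if (den > 0.0 && num / den < sd_thresh && imf_property(h)) break;
    }
    imfs.push_back(h);
    for (int k = 0; k < n; ++k) r[k] -= h[k];
  }
  List li(imfs.size());
  for (size_t j = 0; j < imfs.size(); ++j)
    li[j] = NumericVector(imfs[j].begin(), imfs[j].end());
  return List::create(_["imfs"] = li,
                      _["residual"] = NumericVector(r.begin(), r.end()));
}

// Multivariate local mean: project onto each direction, spline-interpolate
// every channel at the projection maxima, average the envelopes over
// directions. Directions with < 2 projection maxima are skipped and counted.
static int multivar_mean(const std::vector< std::vector<double> >& H,
                         const NumericMatrix& dirs,
                         std::vector< std::vector<double> >& M) {
  int p = H.size(), n = H[0].size(), K = dirs.nrow();
  M.assign(p, std::vector<double>(n, 0.0));
  std::vector<double> proj(n), grid(n);
  for (int k = 0; k < n; ++k) grid[k] = k;
  int used = 0;
  for (int d = 0; d < K; ++d) {
    for (int k = 0; k < n; ++k) {
      double s = 0.0;
      for (int c = 0; c < p; ++c) s += dirs(d, c) * H[c][k];
      proj[k] = s;
    }
    std::vector<int> imax, imin;
    extrema_scan(proj, imax, imin);
    if ((int)imax.size() < 2) continue;
    ++used;
    for (int c = 0; c < p; ++c) {
      std::vector<double> vals(imax.size());
      for (size_t k = 0; k < imax.size(); ++k) vals[k] = H[c][imax[k]];
      std::vector<double> t, y;
      mirror_knots(imax, vals, n, t, y);
      std::vector<double> env = spline_eval(t, y, grid);
      for (int k = 0; k < n; ++k) M[c][k] += env[k];
    }
  }
  if (used > 0)
    for (int c = 0; c < p; ++c)
      for (int k = 0; k < n; ++k) M[c][k] /= used;
  return used;
}

// Multivariate EMD core (MEMD). X: n x p (channels in columns),
// dirs: K x p unit direction vectors. Returns per-channel IMF stacks.
// [[Rcpp::export(name = ".cpp_memd")]]
List cpp_memd(NumericMatrix X, NumericMatrix dirs, int max_imfs,
              int max_sift, double sd_thresh) {
  int n = X.nrow(), p = X.ncol(), K = dirs.nrow();
  std::vector< std::vector<double> > R(p, std::vector<double>(n));
  for (int c = 0; c < p; ++c)
    for (int k = 0; k < n; ++k) R[c][k] = X(k, c);
  std::vector< std::vector< std::vector<double> > > imfs; // [imf][channel][t]

  while ((int)imfs.size() < max_imfs) {
    std::vector< std::vector<double> > H = R, M;
    bool extracted = false;
    for (int it = 0; it < max_sift; ++it) {
      int used = multivar_mean(H, dirs, M);
      if (used < (K + 1) / 2) break; // too few usable directions: stop sifting
      extracted = true;
      double num = 0.0, den = 0.0;
      for (int c = 0; c < p; ++c)
        for (int k = 0; k < n; ++k) {
          num += M[c][k] * M[c][k];
          den += H[c][k] * H[c][k];
          H[c][k] -= M[c][k];
        }
      if (den > 0.0 && num / den < sd_thresh) break;
    }
    if (!extracted) break; // residual has too few projection extrema
    imfs.push_back(H);
    for (int c = 0; c < p; ++c)
      for (int k = 0; k < n; ++k) R[c][k] -= H[c][k];
  }

  int q = imfs.size();
  List per_channel(p);
  for (int c = 0; c < p; ++c) {
    List li(q);
    for (int j = 0; j < q; ++j)
      li[j] = NumericVector(imfs[j][c].begin(), imfs[j][c].end());
    per_channel[c] = List::create(
      _["imfs"] = li,
      _["residual"] = NumericVector(R[c].begin(), R[c].end()));
  }
  return per_channel;
}
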