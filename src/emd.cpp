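#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Strict local extrema of x (interior points only).
static void find_extrema(const std::vector<double> &x,
                         std::vector<int> &maxima, std::vector<int> &minima) {
  const int n = (int)x.size();
  maxima.clear(); minima.clear();
  for (int i = 1; i + 1 < n; ++i) {
    if (x[i] > x[i - 1] && x[i] > x[i + 1]) maxima.push_back(i);
    else if (x[i] < x[i - 1] && x[i] < x[i + 1]) minima.push_back(i);
  }
}

static int zero_crossings(const std::vector<double> &x) {
  int count = 0, prev = 0;
  for (size_t i = 0; i < x.size(); ++i) {
    int s = (x[i] > 0.0) - (x[i] < 0.0);
    if (s == 0) continue;
    if (prev != 0 && s != prev) ++count;
    prev = s;
  }
  return count;
}

// Natural cubic spline through (xs, ys), evaluated at 0, 1, ..., n-1.
// Linear extrapolation outside the knot range (matches stats::splinefun
// method = "natural").
static void natural_spline_eval(const std::vector<double> &xs,
                                const std::vector<double> &ys,
                                int n, std::vector<double> &out) {
  const int m = (int)xs.size();
  out.assign(n, 0.0);
  if (m == 2) {
    double slope = (ys[1] - ys[0]) / (xs[1] - xs[0]);
    for (int t = 0; t < n; ++t) out[t] = ys[0] + slope * (t - xs[0]);
    return;
  }
  // second derivatives M, natural boundary (M[0] = M[m-1] = 0)
  std::vector<double> M(m, 0.0), diag(m, 0.0), rhs(m, 0.0), sub(m, 0.0);
  for (int i = 1; i + 1 < m; ++i) {
    double h0 = xs[i] - xs[i - 1], h1 = xs[i + 1] - xs[i];
    diag[i] = 2.0 * (h0 + h1);
    rhs[i]  = 6.0 * ((ys[i + 1] - ys[i]) / h1 - (ys[i] - ys[i - 1]) / h0);
    sub[i]  = h0;
  }
  // Thomas algorithm on rows 1..m-2
  for (int i = 2; i + 1 < m; ++i) {
    double h0 = xs[i] - xs[i - 1];
    double w = sub[i] / diag[i - 1];
    diag[i] -= w * h0;  // upper diag of row i-1 equals h0
    rhs[i]  -= w * rhs[i - 1];
  }
  for (int i = m - 2; i >= 1; --i) {
    double h1 = xs[i + 1] - xs[i];
    double up = (i + 2 < m) ? h1 * M[i + 1] : 0.0;
    M[i] = (rhs[i] - up) / diag[i];
  }
  double h_first = xs[1] - xs[0];
  double slope_first = (ys[1] - ys[0]) / h_first - h_first * M[1] / 6.0;
  double h_last = xs[m - 1] - xs[m - 2];
  double slope_last = (ys[m - 1] - ys[m - 2]) / h_last + h_last * M[m - 2] / 6.0;

  int seg = 0;
  for (int t = 0; t < n; ++t) {
    double tt = (double)t;
    if (tt <= xs[0]) { out[t] = ys[0] + slope_first * (tt - xs[0]); continue; }
    if (tt >= xs[m - 1]) { out[t] = ys[m - 1] + slope_last * (tt - xs[m - 1]); continue; }
    while (seg + 2 < m && xs[seg + 1] < tt) ++seg;
    double h = xs[seg + 1] - xs[seg];
    double A = (xs[seg + 1] - tt) / h, B = (tt - xs[seg]) / h;
    out[t] = A * ys[seg] + B * ys[seg + 1] +
      ((A * A * A - A) * M[seg] + (B * B * B - B) * M[seg + 1]) * h * h / 6.0;
  }
}

// Mirror up to two extrema across each signal end before spline fitting.
static void mirrored_knots(const std::vector<int> &idx,
                           const std::vector<double> &x, int n,
                           std::vector<double> &xs, std::vector<double> &ys) {
  xs.clear(); ys.clear();
  int m = (int)idx.size();
  // left mirror: reflect about sample 0
  std::vector<std::pair<double,double> > left;
  for (int k = 0; k < m && (int)left.size() < 2; ++k)
    if (idx[k] > 0) left.push_back(std::make_pair(-(double)idx[k], x[idx[k]]));
  for (int k = (int)left.size() - 1; k >= 0; --k) {
    xs.push_back(left[k].first); ys.push_back(left[k].second);
  }
  for (int k = 0; k < m; ++k) { xs.push_back((double)idx[k]); ys.push_back(x[idx[k]]); }
  // right mirror: reflect about sample n-1
  int added = 0;
  for (int k = m - 1; k >= 0 && added < 2; --k)
    if (idx[k] < n - 1) {
      xs.push_back(2.0 * (n - 1) - idx[k]); ys.push_back(x[idx[k]]); ++added;
    }
}

// Mean of the cubic-spline upper and lower envelopes; ok = FALSE when the
// series has fewer than two maxima or two minima (not siftable).
static bool envelope_mean_core(const std::vector<double> &x,
                               std::vector<double> &mean_env) {
  const int n = (int)x.size();
  std::vector<int> maxima, minima;
  find_extrema(x, maxima, minima);
  if (maxima.size() < 2 || minima.size() < 2) return false;
  std::vector<double> xs, ys, up, low;
  mirrored_knots(maxima, x, n, xs, ys);
  natural_spline_eval(xs, ys, n, up);
  mirrored_knots(minima, x, n, xs, ys);
  natural_spline_eval(xs, ys, n, low);
  mean_env.assign(n, 0.0);
  for (int t = 0; t < n; ++t) mean_env[t] = 0.5 * (up[t] + low[t]);
  return true;
}

// [[Rcpp::export(name = ".envelope_mean_cpp")]]
List envelope_mean_cpp(NumericVector x) {
  std::vector<double> xv(x.begin(), x.end()), m;
  bool ok = envelope_mean_core(xv, m);
  if (!ok) return List::create(_["ok"] = false, _["mean"] = R_NilValue);
  return List::create(_["ok"] = true, _["mean"] = NumericVector(m.begin(), m.end()));
}

// Empirical mode decomposition by repeated sifting. Stops an IMF when the
// Cauchy criterion sum((d_prev - d)^2)/sum(d_prev^2) < sd_tol together with
// the extrema/zero-crossing condition (counts differ by at most one), or at
// max_sift iterations. Extraction ends when the remainder has fewer than two
// maxima or minima (monotonic residual) or max_imf is reached.
// [[Rcpp::export(name = ".emd_cpp")]]
List emd_cpp(NumericVector x, int max_imf = 12, double sd_tol = 0.2,
             int max_sift = 100) {
  const int n = x.size();
  std::vector<double> h(x.begin(), x.end());
  std::vector<std::vector<double> > imfs;
  std::vector<int> maxima, minima;

  while ((int)imfs.size() < max_imf) {
    find_extrema(h, maxima, minima);
    if (maxima.size() < 2 || minima.size() < 2) break;
    std::vector<double> d(h), m;
    bool accepted = false;
    for (int it = 0; it < max_sift; ++it) {
      if (!envelope_mean_core(d, m)) { accepted = (it > 0); break; }
      double num = 0.0, den = 0.0;
      for (int t = 0; t < n; ++t) { num += m[t] * m[t]; den += d[t] * d[t]; }
      for (int t = 0; t < n; ++t) d[t] -= m[t];
      accepted = true;
      if (den > 0.0 && num / den < sd_tol) {
        find_extrema(d, maxima, minima);
        int next = (int)(maxima.size() + minima.size());
        if (std::abs(next - zero_crossings(d)) <= 1) break;
      }
    }
    if (!accepted) break;
    imfs.push_back(d);
    for (int t = 0; t < n; ++t) h[t] -= d[t];
  }

  NumericMatrix out(n, (int)imfs.size());
  for (int j = 0; j < (int)imfs.size(); ++j)
    std::copy(imfs[j].begin(), imfs[j].end(), out.column(j).begin());
  return List::create(_["imfs"] = out,
                      _["residual"] = NumericVector(h.begin(), h.end()));
}
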