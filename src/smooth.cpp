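#include <Rcpp.h>
using namespace Rcpp;

// Kernel-weighted local regression of per-site methylation levels along a
// chromosome. For each evaluation position the base window is
// [c - half_window, c + half_window]; if it holds fewer than min_sites
// covered sites it is expanded symmetrically, nearest site first, until
// min_sites are included or the chromosome is exhausted. Weights are
// coverage x tricube of scaled distance; the bandwidth is the larger of
// half_window and the farthest included site (+1 bp so it keeps positive
// weight). degree 0 fits a weighted mean, degree 1 a weighted line
// evaluated at the centre. Values are clamped to [0, 1].
//
// pos, level, wt: covered sites, sorted by position.
// eval_pos: sorted positions at which to evaluate (need not be covered).
// [[Rcpp::export]]
NumericVector smooth_sites_cpp(NumericVector pos, NumericVector level,
                               NumericVector wt, NumericVector eval_pos,
                               double half_window, int min_sites,
                               int degree) {
  const int n = pos.size();
  const int m = eval_pos.size();
  NumericVector out(m, NA_REAL);
  if (n == 0) return out;

  int lo = 0, hi = -1;
  for (int k = 0; k < m; ++k) {
    const double c = eval_pos[k];
    while (lo < n && pos[lo] < c - half_window) ++lo;
    if (hi < lo - 1) hi = lo - 1;
    while (hi + 1 < n && pos[hi + 1] <= c + half_window) ++hi;

    int l = lo, h = hi;
    while (h - l + 1 < min_sites && (l > 0 || h < n - 1)) {
      const double dl = (l > 0) ? c - pos[l - 1] : R_PosInf;
      const double dr = (h < n - 1) ? pos[h + 1] - c : R_PosInf;
      if (dl <= dr) --l; else ++h;
    }
    const int cnt = h - l + 1;
    if (cnt <= 0) continue;

    const double maxd = std::max(std::fabs(c - pos[l]),
                                 std::fabs(pos[h] - c));
    const double band = std::max(half_window, maxd + 1.0);

    double sw = 0, swx = 0, swy = 0, swxx = 0, swxy = 0;
    for (int i = l; i <= h; ++i) {
      const double u = std::fabs(pos[i] - c) / band;
      if (u >= 1.0) continue;
      const double a = 1.0 - u * u * u;
      const double w = wt[i] * a * a * a;
      if (w <= 0) continue;
      const double x = pos[i] - c;
      sw += w; swx += w * x; swy += w * level[i];
      swxx += w * x * x; swxy += w * x * level[i];
    }
    if (sw <= 0) continue;

    double val;
    if (degree == 0) {
      val = swy / sw;
    } else {
      const double det = sw * swxx - swx * swx;
      if (det <= 1e-10 * std::max(1.0, sw * swxx)) {
        val = swy / sw;
      } else {
        const double slope = (sw * swxy - swx * swy) / det;
        val = (swy - slope * swx) / sw;  // intercept = fit at the centre
      }
    }
    if (val < 0) val = 0;
    if (val > 1) val = 1;
    out[k] = val;
  }
  return out;
}
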