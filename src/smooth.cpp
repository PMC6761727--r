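#include <Rcpp.h>
using namespace Rcpp;

// Weighted local polynomial smoothing of methylation levels.
//
// For each site, the smallest symmetric window containing at least
// `min_sites` sites and spanning at least `min_width` bp is selected; a
// weighted quadratic in position is fit with tricube(distance) x coverage
// weights and evaluated at the site. Falls back to a weighted line / mean
// when fewer than 3 / 2 covered sites carry weight, and returns NA when the
// window holds no covered site.
//
// pos:   sorted site positions (one chromosome)
// beta:  n x S methylation levels, NA where coverage is zero
// cov:   n x S total read counts (weight multipliers)
// [[Rcpp::export(name = ".smooth_tracks_cpp")]]
NumericMatrix smooth_tracks_cpp(IntegerVector pos, NumericMatrix beta,
                                NumericMatrix cov, int min_sites,
                                double min_width) {
  const int n = pos.size(), S = beta.ncol();
  NumericMatrix out(n, S);

  for (int i = 0; i < n; ++i) {
    // grow a symmetric window: half-width = max(min_width/2, distance to
    // the min_sites-th nearest site)
    int lo = i, hi = i, count = 1;
    while (count < min_sites && (lo > 0 || hi < n - 1)) {
      double dl = lo > 0 ? (double)(pos[i] - pos[lo - 1]) : R_PosInf;
      double dr = hi < n - 1 ? (double)(pos[hi + 1] - pos[i]) : R_PosInf;
      if (dl <= dr) { --lo; } else { ++hi; }
      ++count;
    }
    double h = min_width / 2.0;
    if (lo > 0 || hi < n - 1 || count >= min_sites) {
      double dmax = std::max((double)(pos[i] - pos[lo]),
                             (double)(pos[hi] - pos[i]));
      if (dmax > h) h = dmax;
    }
    // include every site inside the final half-width
    while (lo > 0 && pos[i] - pos[lo - 1] <= h) --lo;
    while (hi < n - 1 && pos[hi + 1] - pos[i] <= h) ++hi;
    double hs = h * 1.0001 + 1e-9; // keep boundary weights positive

    for (int s = 0; s < S; ++s) {
      // accumulate weighted design moments for x = (pos_j - pos_i) / hs
      double S0 = 0, S1 = 0, S2 = 0, S3 = 0, S4 = 0;
      double T0 = 0, T1 = 0, T2 = 0;
      int used = 0;
      double lone = NA_REAL;
      for (int j = lo; j <= hi; ++j) {
        double b = beta(j, s), c = cov(j, s);
        if (ISNAN(b) || c <= 0) continue;
        double x = (double)(pos[j] - pos[i]) / hs;
        double a = 1.0 - std::abs(x) * std::abs(x) * std::abs(x);
        double w = a * a * a * c;
        if (w <= 0) continue;
        ++used; lone = b;
        double wx = w * x;
        S0 += w;  S1 += wx;  S2 += wx * x;  S3 += wx * x * x;
        S4 += wx * x * x * x;
        T0 += w * b; T1 += wx * b; T2 += wx * x * b;
      }
      double val;
      if (used == 0) {
        val = NA_REAL;
      } else if (used == 1) {
        val = lone;
      } else if (used == 2) {
        double det = S0 * S2 - S1 * S1;
        val = det != 0 ? (S2 * T0 - S1 * T1) / det : T0 / S0;
      } else {
        // 3x3 normal equations, value at x = 0 is the intercept
        double a11 = S0, a12 = S1, a13 = S2;
        double a22 = S2, a23 = S3, a33 = S4;
        double det = a11 * (a22 * a33 - a23 * a23)
                   - a12 * (a12 * a33 - a23 * a13)
                   + a13 * (a12 * a23 - a22 * a13);
        if (std::abs(det) > 1e-12) {
          double c11 = a22 * a33 - a23 * a23;
          double c12 = a13 * a23 - a12 * a33;
          double c13 = a12 * a23 - a13 * a22;
          val = (c11 * T0 + c12 * T1 + c13 * T2) / det;
        } else {
          double d2 = S0 * S2 - S1 * S1;
          val = d2 != 0 ? (S2 * T0 - S1 * T1) / d2 : T0 / S0;
        }
      }
      if (!ISNAN(val)) {
        if (val < 0) val = 0; else if (val > 1) val = 1;
      }
      out(i, s) = val;
    }
  }
  return out;
}
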