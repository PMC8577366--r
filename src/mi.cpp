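#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sliding-window mutual information between a small map (`tmpl`, may contain
// NA) and every fully-contained placement of it inside `img`. For each
// displacement the joint histogram uses `nbins` equal-width bins per variable
// spanning the min-max range of the finite pairs in the overlap window.
// Displacements with fewer than `min_pairs` finite pairs are NA. MI in bits.
// [[Rcpp::export(name = ".mi_map_cpp")]]
NumericMatrix mi_map_cpp(NumericMatrix img, NumericMatrix tmpl,
                         int nbins, int min_pairs) {
  const int M = img.nrow(), N = img.ncol();
  const int m = tmpl.nrow(), n = tmpl.ncol();
  const int DR = M - m + 1, DC = N - n + 1;
  NumericMatrix out(DR, DC);
  std::vector<double> a(m * n), b(m * n);
  std::vector<int> joint(nbins * nbins), ma(nbins), mb(nbins);
  const double log2e = 1.0 / std::log(2.0);

  for (int dr = 0; dr < DR; ++dr) {
    for (int dc = 0; dc < DC; ++dc) {
      int cnt = 0;
      double amin = R_PosInf, amax = R_NegInf, bmin = R_PosInf, bmax = R_NegInf;
      for (int j = 0; j < n; ++j) {
        for (int i = 0; i < m; ++i) {
          double tv = tmpl(i, j);
          if (!R_finite(tv)) continue;
          double iv = img(dr + i, dc + j);
          if (!R_finite(iv)) continue;
          a[cnt] = iv; b[cnt] = tv; ++cnt;
          if (iv < amin) amin = iv;
          if (iv > amax) amax = iv;
          if (tv < bmin) bmin = tv;
          if (tv > bmax) bmax = tv;
        }
      }
      if (cnt < min_pairs) { out(dr, dc) = NA_REAL; continue; }
      if (amax <= amin || bmax <= bmin) { out(dr, dc) = 0.0; continue; }
      std::fill(joint.begin(), joint.end(), 0);
      std::fill(ma.begin(), ma.end(), 0);
      std::fill(mb.begin(), mb.end(), 0);
      const double sa = nbins / (amax - amin), sb = nbins / (bmax - bmin);
      for (int k = 0; k < cnt; ++k) {
        int ia = (int)((a[k] - amin) * sa); if (ia >= nbins) ia = nbins - 1;
        int ib = (int)((b[k] - bmin) * sb); if (ib >= nbins) ib = nbins - 1;
        ++joint[ia * nbins + ib]; ++ma[ia]; ++mb[ib];
      }
      double mi = 0.0;
      const double dn = (double)cnt;
      for (int ia = 0; ia < nbins; ++ia) {
        if (!ma[ia]) continue;
        for (int ib = 0; ib < nbins; ++ib) {
          int c = joint[ia * nbins + ib];
          if (!c) continue;
          mi += (c / dn) * std::log((c * dn) / ((double)ma[ia] * mb[ib])) * log2e;
        }
      }
      out(dr, dc) = mi > 0.0 ? mi : 0.0;
    }
  }
  return out;
}
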