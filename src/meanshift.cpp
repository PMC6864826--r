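#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Joint spatial-spectral mean-shift filtering.
//
// bands: npix x nb matrix, pixel index p = row + col * nrow (R column-major).
// For every pixel the mode-seeking iteration moves a joint vector
// y = (y_s, y_r): neighbors are pixels within spatial range hs of y_s AND
// spectral range hr of y_r; the update is the kernel-weighted mean of the
// neighbors' joint vectors (spatial coordinates and raw spectral values).
// Distances are normalized by (hs, hr); iteration stops when the joint
// normalized displacement drops below tol or after max_iter steps.
// kernel: 0 = Epanechnikov (weight 1 - u^2 on u^2 <= 1), 1 = Gaussian.
// [[Rcpp::export]]
List ms_filter_cpp(NumericMatrix bands, int nrow, int ncol,
                   double hs, double hr, int kernel,
                   int max_iter, double tol, LogicalVector nodata) {
  const int npix = nrow * ncol;
  const int nb = bands.ncol();
  NumericMatrix sp_mode(npix, 2);   // (col, row), 0-based pixel units
  NumericMatrix sc_mode(npix, nb);
  IntegerVector iters(npix);

  std::vector<double> yr(nb), acc(nb);
  const double hs2 = hs * hs, hr2 = hr * hr;

  for (int c = 0; c < ncol; ++c) {
    for (int r = 0; r < nrow; ++r) {
      const int p = r + c * nrow;
      if (nodata[p]) {
        sp_mode(p, 0) = c; sp_mode(p, 1) = r;
        for (int b = 0; b < nb; ++b) sc_mode(p, b) = NA_REAL;
        continue;
      }
      double ysx = c, ysy = r;
      for (int b = 0; b < nb; ++b) yr[b] = bands(p, b);
      int j = 0;
      for (; j < max_iter; ++j) {
        int c0 = (int)std::floor(ysx - hs), c1 = (int)std::ceil(ysx + hs);
        int r0 = (int)std::floor(ysy - hs), r1 = (int)std::ceil(ysy + hs);
        if (c0 < 0) c0 = 0; if (r0 < 0) r0 = 0;
        if (c1 > ncol - 1) c1 = ncol - 1; if (r1 > nrow - 1) r1 = nrow - 1;
        double wsum = 0, ax = 0, ay = 0;
        std::fill(acc.begin(), acc.end(), 0.0);
        for (int cc = c0; cc <= c1; ++cc) {
          for (int rr = r0; rr <= r1; ++rr) {
            const int q = rr + cc * nrow;
            if (nodata[q]) continue;
            const double dx = cc - ysx, dy = rr - ysy;
            const double ds2 = (dx * dx + dy * dy) / hs2;
            if (ds2 > 1.0) continue;
            double dr2 = 0;
            for (int b = 0; b < nb; ++b) {
              const double d = bands(q, b) - yr[b];
              dr2 += d * d;
            }
            dr2 /= hr2;
            if (dr2 > 1.0) continue;
            const double u2 = ds2 + dr2;
            const double w = kernel == 0 ? (1.0 - u2) : std::exp(-0.5 * u2);
            if (w <= 0) continue;
            wsum += w;
            ax += w * cc; ay += w * rr;
            for (int b = 0; b < nb; ++b) acc[b] += w * bands(q, b);
          }
        }
        if (wsum <= 0) break;
        const double nx = ax / wsum, ny = ay / wsum;
        double disp2 = ((nx - ysx) * (nx - ysx) + (ny - ysy) * (ny - ysy)) / hs2;
        for (int b = 0; b < nb; ++b) {
          const double nv = acc[b] / wsum;
          disp2 += (nv - yr[b]) * (nv - yr[b]) / hr2;
          yr[b] = nv;
        }
        ysx = nx; ysy = ny;
        if (std::sqrt(disp2) < tol) { ++j; break; }
      }
      sp_mode(p, 0) = ysx; sp_mode(p, 1) = ysy;
      for (int b = 0; b < nb; ++b) sc_mode(p, b) = yr[b];
      iters[p] = j;
    }
  }
  return List::create(_["spatial"] = sp_mode, _["spectral"] = sc_mode,
                      _["iterations"] = iters);
}
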