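#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Mean-shift filtering of a 3-channel image (Comaniciu-Meer style, as used
// for flat-region color smoothing). For each pixel, the joint spatial/color
// window mean is followed until the shift converges (< eps in summed
// position+color displacement) or max_iter is reached; the pixel takes the
// converged window-mean color. Channels are passed as separate
// height x width matrices; access in the hot loop is through raw
// column-major pointers.
// [[Rcpp::export]]
List meanshift_filter_cpp(NumericMatrix c1, NumericMatrix c2,
                          NumericMatrix c3, int sp, double sr, int max_iter,
                          double eps = 1.0) {
  const int h = c1.nrow(), w = c1.ncol();
  NumericMatrix o1(h, w), o2(h, w), o3(h, w);
  const double sr2 = sr * sr;
  const double *p1 = REAL(c1), *p2 = REAL(c2), *p3 = REAL(c3);

  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      double y = i, x = j;
      const std::size_t c0 = (std::size_t)j * h + i;
      double v1 = p1[c0], v2 = p2[c0], v3 = p3[c0];
      double m1 = v1, m2 = v2, m3 = v3;
      for (int it = 0; it < max_iter; ++it) {
        const int yc = (int)std::lround(y), xc = (int)std::lround(x);
        const int r0 = yc - sp < 0 ? 0 : yc - sp;
        const int r1 = yc + sp >= h ? h - 1 : yc + sp;
        const int q0 = xc - sp < 0 ? 0 : xc - sp;
        const int q1 = xc + sp >= w ? w - 1 : xc + sp;
        double sy = 0, sx = 0, s1 = 0, s2 = 0, s3 = 0;
        int n = 0;
        for (int q = q0; q <= q1; ++q) {
          const std::size_t base = (std::size_t)q * h;
          const double *a1 = p1 + base, *a2 = p2 + base, *a3 = p3 + base;
          double ry = 0; int nq = 0;
          for (int r = r0; r <= r1; ++r) {
            const double d1 = a1[r] - v1, d2 = a2[r] - v2, d3 = a3[r] - v3;
            if (d1 * d1 + d2 * d2 + d3 * d3 <= sr2) {
              ry += r;
              s1 += a1[r]; s2 += a2[r]; s3 += a3[r];
              ++nq;
            }
          }
          sy += ry; sx += (double)nq * q; n += nq;
        }
        if (n == 0) break;
        const double ny = sy / n, nx = sx / n;
        const double n1 = s1 / n, n2 = s2 / n, n3 = s3 / n;
        const double shift = std::fabs(ny - y) + std::fabs(nx - x) +
                             std::fabs(n1 - v1) + std::fabs(n2 - v2) +
                             std::fabs(n3 - v3);
        y = ny; x = nx; v1 = n1; v2 = n2; v3 = n3;
        m1 = n1; m2 = n2; m3 = n3;
        if (shift < eps) break;
      }
      o1[c0] = m1; o2[c0] = m2; o3[c0] = m3;
    }
  }
  return List::create(o1, o2, o3);
}
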