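#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Gradient-voting accumulator of the circle Hough transform: each edge
// pixel votes along its gradient direction (both senses) at every candidate
// radius. Returns the h x w vote count matrix.
//
// [[Rcpp::export]]
IntegerMatrix hough_circle_votes_cpp(IntegerVector ex, IntegerVector ey,
                                     NumericVector ux, NumericVector uy,
                                     NumericVector radii, int h, int w) {
  IntegerMatrix acc(h, w);
  const int n = ex.size(), nr = radii.size();
  for (int k = 0; k < n; ++k) {
    const double x = ex[k], y = ey[k], dx = ux[k], dy = uy[k];
    for (int ri = 0; ri < nr; ++ri) {
      const double r = radii[ri];
      for (int s = -1; s <= 1; s += 2) {
        int vx = (int)std::lround(x + s * r * dx);
        int vy = (int)std::lround(y + s * r * dy);
        if (vx >= 1 && vx <= w && vy >= 1 && vy <= h) acc(vy - 1, vx - 1)++;
      }
    }
  }
  return acc;
}
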