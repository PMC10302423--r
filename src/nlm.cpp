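#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

// Non-local means denoising of a grayscale image (8-bit scale).
//
// Offset-major formulation: for every search-window offset o the squared
// difference image diff_o(p) = (I(p) - I(p+o))^2 is box-summed with
// separable running sums, giving mean patch distances for all pixels at
// once; weights come from a lookup table over exp(-d2/h^2). The patch
// distance is symmetric, d2(p, p+o) = d2(p+o, p), so each +/- offset pair
// shares one difference pass: S(p) weights the neighbor at p+o and S(p-o)
// the neighbor at p-o. Borders are replicate-padded. O(H * W * S^2 / 2).
//
// [[Rcpp::export]]
NumericMatrix nlm_denoise_cpp(NumericMatrix img, double strength,
                              int patch_size, int search_window,
                              double noise_sigma = 0.0) {
  const int h = img.nrow(), w = img.ncol();
  const int pr = patch_size / 2;          // patch radius
  const int sr = search_window / 2;       // search radius
  const int pad = pr + sr;
  const int H = h + 2 * pad, W = w + 2 * pad;
  const double h2 = strength * strength;
  const double npatch = (double)patch_size * patch_size;
  // noise-compensated patch distance: two copies of the same signal under
  // iid noise of sd sigma differ by 2*sigma^2 in expectation
  const double noise2 = 2.0 * noise_sigma * noise_sigma;

  // replicate-padded copy (column-major like R)
  std::vector<double> Ibuf((size_t)H * W);
  double *I = Ibuf.data();
  for (int j = 0; j < W; ++j) {
    int js = std::min(std::max(j - pad, 0), w - 1);
    for (int i = 0; i < H; ++i) {
      int is = std::min(std::max(i - pad, 0), h - 1);
      I[(size_t)j * H + i] = img(is, js);
    }
  }

  // weight LUT over normalized distances in [0, 10*h^2]
  const int nbins = 8192;
  const double dmax = 10.0 * h2;
  std::vector<double> lutbuf(nbins + 1);
  double *lut = lutbuf.data();
  for (int k = 0; k <= nbins; ++k)
    lut[k] = std::exp(-(dmax * k / nbins) / h2);
  const double lscale = nbins / dmax;

  std::vector<double> accbuf((size_t)h * w, 0.0), wsumbuf((size_t)h * w, 0.0);
  std::vector<double> diffbuf((size_t)H * W), rowbuf((size_t)H * W),
      boxbuf((size_t)H * W);
  double *acc = accbuf.data(), *wsum = wsumbuf.data();
  double *diff = diffbuf.data(), *rowacc = rowbuf.data(), *box = boxbuf.data();

  // center offset: weight exactly 1
  for (int jj = 0; jj < w; ++jj)
    for (int ii = 0; ii < h; ++ii) {
      acc[(size_t)jj * h + ii] += I[(size_t)(jj + pad) * H + ii + pad];
      wsum[(size_t)jj * h + ii] += 1.0;
    }

  // half-plane offsets; each handles o and -o
  for (int dy = 0; dy <= sr; ++dy) {
    const int dx_start = (dy == 0) ? 1 : -sr;
    for (int dx = dx_start; dx <= sr; ++dx) {
      const int ilo = std::max(0, -dy), ihi = std::min(H, H - dy);
      const int jlo = std::max(0, -dx), jhi = std::min(W, W - dx);
      // fused per-column squared difference + vertical patch running sum
      for (int j = 0; j < W; ++j) {
        double *d = diff + (size_t)j * H;
        if (j < jlo || j >= jhi) {
          std::fill(d, d + H, 0.0);
        } else {
          const double *a = I + (size_t)j * H;
          const double *b = I + (ptrdiff_t)(j + dx) * H + dy;
          if (ilo > 0) std::fill(d, d + ilo, 0.0);
          for (int i = ilo; i < ihi; ++i) {
            double v = a[i] - b[i];
            d[i] = v * v;
          }
          if (ihi < H) std::fill(d + ihi, d + H, 0.0);
        }
        double *ra = rowacc + (size_t)j * H;
        double s = 0.0;
        for (int i = 0; i < 2 * pr && i < H; ++i) s += d[i];
        for (int i = pr; i < H - pr; ++i) {
          s += d[i + pr];
          ra[i] = s;
          s -= d[i - pr];
        }
      }
      // horizontal sliding box over columns (contiguous column updates)
      {
        std::vector<double> B(H, 0.0);
        for (int jk = 0; jk <= 2 * pr && jk < W; ++jk) {
          const double *ra = rowacc + (size_t)jk * H;
          for (int i = pr; i < H - pr; ++i) B[i] += ra[i];
        }
        for (int j = pr; j < W - pr; ++j) {
          double *bx = box + (size_t)j * H;
          for (int i = pr; i < H - pr; ++i) bx[i] = B[i];
          if (j + 1 < W - pr) {
            const double *radd = rowacc + (size_t)(j + pr + 1) * H;
            const double *rsub = rowacc + (size_t)(j - pr) * H;
            for (int i = pr; i < H - pr; ++i) B[i] += radd[i] - rsub[i];
          }
        }
      }
      // accumulate both senses of the offset
      for (int jj = 0; jj < w; ++jj) {
        const int j = jj + pad;
        double *ac = acc + (size_t)jj * h;
        double *wc = wsum + (size_t)jj * h;
        const double *bp = box + (size_t)j * H + pad;
        const double *bm = box + (ptrdiff_t)(j - dx) * H + pad - dy;
        const double *np = I + (ptrdiff_t)(j + dx) * H + pad + dy;
        const double *nm = I + (ptrdiff_t)(j - dx) * H + pad - dy;
        for (int ii = 0; ii < h; ++ii) {
          double d2p = std::max(bp[ii] / npatch - noise2, 0.0);
          double d2m = std::max(bm[ii] / npatch - noise2, 0.0);
          double wp = d2p >= dmax ? 0.0 : lut[(int)(d2p * lscale)];
          double wm = d2m >= dmax ? 0.0 : lut[(int)(d2m * lscale)];
          ac[ii] += wp * np[ii] + wm * nm[ii];
          wc[ii] += wp + wm;
        }
      }
    }
  }

  NumericMatrix out(h, w);
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i)
      out(i, j) = acc[(size_t)j * h + i] / wsum[(size_t)j * h + i];
  return out;
}
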