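#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Non-local means denoising of a single 8-bit grayscale frame.
//
// Patch distances are computed offset-wise: for each displacement within
// the search window an integral image of squared pixel differences gives
// every patch distance in O(1), so the cost is O(npix * search^2) instead
// of O(npix * search^2 * template^2). Two symmetric displacements share one
// distance field (d2 between the patches at p and p+o is the same seen from
// either side), so only half the search window is traversed and each pass
// scatters its weighted contribution to both endpoints. Weights are
// exp(-d2 / h^2) with d2 the mean squared difference over the template
// patch, read from a table over integer-quantized d2 (intensities are
// 8-bit, so d2 lies in [0, 255^2]; the table step of one intensity unit
// squared is far below any h in use). The center pixel participates with
// weight 1. Borders are handled by coordinate clamping (replicated edges).
// [[Rcpp::export]]
NumericMatrix nlm_denoise_cpp(NumericMatrix img, double h, int tmpl, int search) {
  const int nr = img.nrow(), nc = img.ncol();
  const int t2 = tmpl / 2, s2 = search / 2;
  const double h2 = h * h;

  // weight lookup over quantized mean squared patch difference
  const int lutn = 255 * 255 + 2;
  std::vector<double> lut(lutn);
  for (int i = 0; i < lutn; ++i) lut[i] = std::exp(-static_cast<double>(i) / h2);

  const double *I = img.begin();
  std::vector<double> num(static_cast<size_t>(nr) * nc),
                      den(static_cast<size_t>(nr) * nc);
  for (size_t i = 0; i < num.size(); ++i) { num[i] = I[i]; den[i] = 1.0; }

  std::vector<double> d2(static_cast<size_t>(nr) * nc);
  std::vector<double> integ(static_cast<size_t>(nr + 1) * (nc + 1), 0.0);
  const int inr = nr + 1;
  std::vector<int> rowShift(nr), colShift(nc);

  for (int dx = 0; dx <= s2; ++dx) {
    const int dyStart = (dx == 0) ? 1 : -s2;
    for (int dy = dyStart; dy <= s2; ++dy) {
      for (int r = 0; r < nr; ++r) rowShift[r] = clampi(r + dy, 0, nr - 1);
      for (int c = 0; c < nc; ++c) colShift[c] = clampi(c + dx, 0, nc - 1);

      // squared differences against the displaced (clamped) image
      for (int c = 0; c < nc; ++c) {
        const double *colA = I + static_cast<size_t>(c) * nr;
        const double *colB = I + static_cast<size_t>(colShift[c]) * nr;
        double *out = &d2[static_cast<size_t>(c) * nr];
        for (int r = 0; r < nr; ++r) {
          const double d = colA[r] - colB[rowShift[r]];
          out[r] = d * d;
        }
      }
      // integral image of d2
      for (int c = 0; c < nc; ++c) {
        double colsum = 0.0;
        const double *in = &d2[static_cast<size_t>(c) * nr];
        const double *prev = &integ[static_cast<size_t>(c) * inr];
        double *cur = &integ[static_cast<size_t>(c + 1) * inr];
        for (int r = 0; r < nr; ++r) {
          colsum += in[r];
          cur[r + 1] = prev[r + 1] + colsum;
        }
      }
      // scatter weighted contributions to both endpoints of the offset
      for (int c = 0; c < nc; ++c) {
        const int c0 = c - t2 < 0 ? 0 : c - t2;
        const int c1 = c + t2 >= nc ? nc - 1 : c + t2;
        const size_t qcol = static_cast<size_t>(colShift[c]) * nr;
        const size_t pcol = static_cast<size_t>(c) * nr;
        for (int r = 0; r < nr; ++r) {
          const int r0 = r - t2 < 0 ? 0 : r - t2;
          const int r1 = r + t2 >= nr ? nr - 1 : r + t2;
          const double box =
            integ[static_cast<size_t>(c1 + 1) * inr + (r1 + 1)] -
            integ[static_cast<size_t>(c0) * inr + (r1 + 1)] -
            integ[static_cast<size_t>(c1 + 1) * inr + r0] +
            integ[static_cast<size_t>(c0) * inr + r0];
          const int npatch = (r1 - r0 + 1) * (c1 - c0 + 1);
          int idx = static_cast<int>(box / npatch + 0.5);
          if (idx >= lutn) idx = lutn - 1;
          const double w = lut[idx];
          const size_t p = pcol + r, q = qcol + rowShift[r];
          num[p] += w * I[q];
          den[p] += w;
          num[q] += w * I[p];
          den[q] += w;
        }
      }
    }
  }

  NumericMatrix out(nr, nc);
  double *O = out.begin();
  for (size_t i = 0; i < num.size(); ++i) O[i] = num[i] / den[i];
  return out;
}
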