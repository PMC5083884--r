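#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Masked block matching with zero-mean normalized cross-correlation.
//
// For every mask-true left pixel, scans the same row of the right image over
// the disparity range [d_min, d_max] (a positive disparity d matches left
// column c against right column c - d), scores each shift by ZNCC over a
// square window of side `block`, and keeps the best score.  The winning
// integer disparity is refined by fitting a parabola through the scores at
// d-1, d, d+1.  A pixel is reported invalid when:
//   * its window does not fit inside either image,
//   * the left window is textureless (zero variance),
//   * the peak correlation is below `min_corr`,
//   * the winner sits on the boundary of the (clipped) search range, where
//     no subpixel fit is possible and the true optimum may lie outside.
// Ties between equal scores resolve to the smallest disparity (farthest
// surface), scanning order being deterministic.
//
// Returns the disparity matrix (NA where invalid), the validity mask, and
// the total number of window-score evaluations performed (used to verify
// that masking actually bounds the work done).
// [[Rcpp::export]]
List bm_zncc(NumericMatrix left, NumericMatrix right, LogicalMatrix mask,
             int d_min, int d_max, int block, double min_corr) {
  const int nr = left.nrow(), nc = left.ncol();
  const int h = block / 2;
  const int n = block * block;
  NumericMatrix disp(nr, nc);
  LogicalMatrix valid(nr, nc);
  std::fill(disp.begin(), disp.end(), NA_REAL);
  double evals = 0.0;
  const int nd = d_max - d_min + 1;
  std::vector<double> score(nd);

  for (int r = h; r < nr - h; ++r) {
    for (int c = h; c < nc - h; ++c) {
      if (!mask(r, c)) continue;

      double sl = 0.0, sll = 0.0;
      for (int j = -h; j <= h; ++j)
        for (int i = -h; i <= h; ++i) {
          const double v = left(r + i, c + j);
          sl += v; sll += v * v;
        }
      const double ml = sl / n;
      const double varl = sll - n * ml * ml;
      if (varl <= 1e-12) continue;

      // clip the search so the right window stays inside the image
      const int dlo = std::max(d_min, c + h - (nc - 1));
      const int dhi = std::min(d_max, c - h);
      if (dlo > dhi) continue;

      int best = dlo - 1;
      double best_s = -2.0;
      for (int d = dlo; d <= dhi; ++d) {
        double sr = 0.0, srr = 0.0, slr = 0.0;
        const int cr = c - d;
        for (int j = -h; j <= h; ++j)
          for (int i = -h; i <= h; ++i) {
            const double lv = left(r + i, c + j);
            const double rv = right(r + i, cr + j);
            sr += rv; srr += rv * rv; slr += lv * rv;
          }
        evals += 1.0;
        const double mr = sr / n;
        const double varr = srr - n * mr * mr;
        const double cov = slr - n * ml * mr;
        const double s = (varr <= 1e-12) ? -1.0
                         : cov / std::sqrt(varl * varr);
        score[d - d_min] = s;
        if (s > best_s) { best_s = s; best = d; }
      }

      if (best_s < min_corr) continue;
      if (best == dlo || best == dhi) continue;

      const double s0 = score[best - d_min - 1];
      const double s1 = best_s;
      const double s2 = score[best - d_min + 1];
      const double denom = s0 - 2.0 * s1 + s2;
      double delta = 0.0;
      if (denom < -1e-12) {
        delta = 0.5 * (s0 - s2) / denom;
        if (delta > 0.5) delta = 0.5;
        if (delta < -0.5) delta = -0.5;
      }
      disp(r, c) = best + delta;
      valid(r, c) = true;
    }
  }
  return List::create(_["values"] = disp, _["valid"] = valid,
                      _["evals"] = evals);
}

// CRC-32 (ISO 3309 / PNG) over a raw vector; used by the 16-bit PNG writer.
// [[Rcpp::export]]
double crc32_raw(RawVector bytes) {
  static uint32_t table[256];
  static bool have_table = false;
  if (!have_table) {
    for (uint32_t i = 0; i < 256; ++i) {
      uint32_t c = i;
      for (int k = 0; k < 8; ++k)
        c = (c & 1) ? 0xEDB88320u ^ (c >> 1) : c >> 1;
      table[i] = c;
    }
    have_table = true;
  }
  uint32_t crc = 0xFFFFFFFFu;
  for (R_xlen_t i = 0; i < bytes.size(); ++i)
    crc = table[(crc ^ bytes[i]) & 0xFFu] ^ (crc >> 8);
  return static_cast<double>(crc ^ 0xFFFFFFFFu);
}
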