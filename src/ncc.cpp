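#include <Rcpp.h>
using namespace Rcpp;

// Normalised cross-correlation response of a zero-mean/unit-variance
// template around a centre position in a grayscale image.
//
// image: H x W matrix; templ: p x p (odd p) normalised template;
// cx, cy: 1-based centre (col, row) of the search window; win: odd window
// side. Returns a win_eff x win_eff matrix of NCC values in [-1, 1] (0
// where the template would leave the image), with attributes set by the
// R wrapper. Positions are clamped so every evaluated patch lies inside
// the image.
// [[Rcpp::export]]
NumericMatrix ncc_response(NumericMatrix image, NumericMatrix templ,
                           int cx, int cy, int win) {
  const int H = image.nrow(), W = image.ncol();
  const int p = templ.nrow(), hp = p / 2, hw = win / 2;
  const int n = p * p;
  NumericMatrix resp(win, win);

  for (int dy = -hw; dy <= hw; ++dy) {
    for (int dx = -hw; dx <= hw; ++dx) {
      int px = cx + dx, py = cy + dy;  // candidate landmark position
      if (px - hp < 1 || px + hp > W || py - hp < 1 || py + hp > H) {
        resp(dy + hw, dx + hw) = 0.0;
        continue;
      }
      double sum = 0.0, sum2 = 0.0, cross = 0.0;
      for (int j = 0; j < p; ++j) {
        for (int i = 0; i < p; ++i) {
          double v = image(py - hp - 1 + i, px - hp - 1 + j);
          sum += v;
          sum2 += v * v;
          cross += v * templ(i, j);
        }
      }
      double mean = sum / n;
      double var = sum2 - n * mean * mean;
      if (var < 1e-12) {
        resp(dy + hw, dx + hw) = 0.0;
      } else {
        // templ is zero-mean, so cross already removes the patch mean term
        resp(dy + hw, dx + hw) = cross / std::sqrt(var);
      }
    }
  }
  return resp;
}

// One constrained-local-model mean-shift step for all landmarks: for each
// landmark, score its unit-norm template around the current position,
// square the positive responses, weight by a Gaussian spatial prior and
// step to the weighted centroid. Returns a 66 x 2 target matrix with the
// response peaks in column 3.
// [[Rcpp::export]]
NumericMatrix clm_mean_shift(NumericMatrix image, List templates,
                             NumericMatrix pts, int win) {
  const int H = image.nrow(), W = image.ncol();
  const int n = pts.nrow();
  const int hw = win / 2;
  const double sigma2 = 2.0 * (win / 3.0) * (win / 3.0);
  const double *img = REAL(image);
  NumericMatrix out(n, 3);

  for (int j = 0; j < n; ++j) {
    NumericMatrix tm = templates[j];
    const double *tp = REAL(tm);
    const int p = tm.nrow(), hp = p / 2;
    const int cx = (int) std::lround(pts(j, 0));
    const int cy = (int) std::lround(pts(j, 1));
    double sw = 0.0, sx = 0.0, sy = 0.0, peak = -2.0;
    for (int dy = -hw; dy <= hw; ++dy) {
      for (int dx = -hw; dx <= hw; ++dx) {
        const int px = cx + dx, py = cy + dy;
        if (px - hp < 1 || px + hp > W || py - hp < 1 || py + hp > H)
          continue;
        double sum = 0.0, sum2 = 0.0, cross = 0.0;
        const double *base = img + (size_t)(px - hp - 1) * H + (py - hp - 1);
        for (int c = 0; c < p; ++c) {
          const double *col = base + (size_t) c * H;
          const double *tcol = tp + (size_t) c * p;
          for (int r = 0; r < p; ++r) {
            const double v = col[r];
            sum += v;
            sum2 += v * v;
            cross += v * tcol[r];
          }
        }
        const double np = (double) p * p;
        const double var = sum2 - sum * sum / np;
        double resp = (var < 1e-12) ? 0.0 : cross / std::sqrt(var);
        if (resp > peak) peak = resp;
        if (resp > 0.0) {
          const double w = resp * resp *
            std::exp(-(dx * dx + dy * dy) / sigma2);
          sw += w;
          sx += w * dx;
          sy += w * dy;
        }
      }
    }
    if (sw > 1e-9) {
      out(j, 0) = cx + sx / sw;
      out(j, 1) = cy + sy / sw;
    } else {
      out(j, 0) = pts(j, 0);
      out(j, 1) = pts(j, 1);
    }
    out(j, 2) = peak;
  }
  return out;
}
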