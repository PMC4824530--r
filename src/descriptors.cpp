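// Batch SIFT descriptor and orientation kernels. These are the inner loops
// of the registration: every epipolar-segment candidate needs a 128-element
// gradient histogram, and a noisy pair can require hundreds of thousands of
// them per fit.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double TWO_PI = 6.283185307179586;

// reduce an angle into [0, 2*pi); avoids libm fmod (symbol versioning)
static inline double wrap2pi(double a) {
  a -= std::floor(a / TWO_PI) * TWO_PI;
  if (a >= TWO_PI || a < 0) a = 0.0;
  return a;
}

// bilinear sample of a matrix at 0-based (x = col, y = row); 0 outside
static inline double bilin(const NumericMatrix& m, double x, double y) {
  int h = m.nrow(), w = m.ncol();
  if (x < 0 || y < 0 || x > w - 1 || y > h - 1 || !std::isfinite(x) ||
      !std::isfinite(y)) {
    return 0.0;
  }
  int x0 = (int)std::floor(x); if (x0 > w - 2) x0 = w - 2; if (x0 < 0) x0 = 0;
  int y0 = (int)std::floor(y); if (y0 > h - 2) y0 = h - 2; if (y0 < 0) y0 = 0;
  double fx = x - x0, fy = y - y0;
  return m(y0, x0) * (1 - fx) * (1 - fy) + m(y0, x0 + 1) * fx * (1 - fy) +
         m(y0 + 1, x0) * (1 - fx) * fy + m(y0 + 1, x0 + 1) * fx * fy;
}

// 128-element descriptors (4x4 spatial cells x 8 orientation bins, layout
// index = (row_cell * 4 + col_cell) * 8 + orientation) for a batch of
// keypoints given gradient fields, positions, per-point scale and
// orientation. Mirrors the R reference implementation bit-for-bit up to
// floating-point association.
// [[Rcpp::export(name = ".desc128_batch")]]
NumericMatrix desc128_batch(const NumericMatrix& gx, const NumericMatrix& gy,
                            const NumericVector& x, const NumericVector& y,
                            const NumericVector& sigma_rel,
                            const NumericVector& theta) {
  int n = x.size();
  NumericMatrix out(n, 128);
  for (int i = 0; i < n; ++i) {
    double wc = 3.0 * sigma_rel[i];
    double ct = std::cos(theta[i]), st = std::sin(theta[i]);
    double d[128];
    std::fill(d, d + 128, 0.0);
    for (int gj = 0; gj < 16; ++gj) {        // row of the sample grid
      double vc = (gj - 7.5) / 4.0;          // row offset in cell units
      for (int gi = 0; gi < 16; ++gi) {      // column of the sample grid
        double uc = (gi - 7.5) / 4.0;
        double win = std::exp(-(uc * uc + vc * vc) / 8.0);
        double upx = uc * wc, vpx = vc * wc;
        double X = x[i] + ct * upx - st * vpx;
        double Y = y[i] + st * upx + ct * vpx;
        double sgx = bilin(gx, X, Y), sgy = bilin(gy, X, Y);
        double mag = std::sqrt(sgx * sgx + sgy * sgy) * win;
        if (mag <= 0) continue;
        double ang = wrap2pi(std::atan2(sgy, sgx) - theta[i]);
        double ob = ang / TWO_PI * 8.0;
        double xb = uc + 1.5, yb = vc + 1.5;
        int x0 = (int)std::floor(xb), y0 = (int)std::floor(yb),
            o0 = (int)std::floor(ob);
        double fx = xb - x0, fy = yb - y0, fo = ob - o0;
        for (int cx = 0; cx < 2; ++cx) {
          int xc = x0 + cx;
          if (xc < 0 || xc > 3) continue;
          double wx = cx ? fx : 1 - fx;
          for (int cy = 0; cy < 2; ++cy) {
            int yc = y0 + cy;
            if (yc < 0 || yc > 3) continue;
            double wy = cy ? fy : 1 - fy;
            for (int co = 0; co < 2; ++co) {
              int oc = (o0 + co) % 8;
              double wo = co ? fo : 1 - fo;
              d[(yc * 4 + xc) * 8 + oc] += mag * wx * wy * wo;
            }
          }
        }
      }
    }
    double nrm = 0;
    for (int k = 0; k < 128; ++k) nrm += d[k] * d[k];
    nrm = std::sqrt(nrm);
    if (nrm == 0) nrm = 1;
    double nrm2 = 0;
    for (int k = 0; k < 128; ++k) {
      d[k] /= nrm;
      if (d[k] > 0.2) d[k] = 0.2;          // illumination clamp
      nrm2 += d[k] * d[k];
    }
    nrm2 = std::sqrt(nrm2);
    if (nrm2 == 0) nrm2 = 1;
    for (int k = 0; k < 128; ++k) out(i, k) = d[k] / nrm2;
  }
  return out;
}

// Dominant gradient orientation(s) per point: 36-bin Gaussian-weighted
// histogram in a radius of 3 * 1.5 * sigma, two circular smoothing passes,
// peaks >= 0.8 * max with parabolic refinement. Returns an n x max_peaks
// matrix padded with NA.
// [[Rcpp::export(name = ".orientation_batch")]]
NumericMatrix orientation_batch(const NumericMatrix& gx,
                                const NumericMatrix& gy,
                                const NumericVector& x,
                                const NumericVector& y,
                                const NumericVector& sigma_rel,
                                int max_peaks) {
  int n = x.size();
  int h = gx.nrow(), w = gx.ncol();
  NumericMatrix out(n, max_peaks);
  std::fill(out.begin(), out.end(), NA_REAL);
  for (int i = 0; i < n; ++i) {
    double sw = 1.5 * sigma_rel[i];
    int R = std::max(2, (int)std::lround(3 * sw));
    int xc = (int)std::lround(x[i]), yc = (int)std::lround(y[i]);
    int c0 = std::min(std::max(xc - R, 0), w - 1);
    int c1 = std::min(std::max(xc + R, 0), w - 1);
    int r0 = std::min(std::max(yc - R, 0), h - 1);
    int r1 = std::min(std::max(yc + R, 0), h - 1);
    double hist[36];
    std::fill(hist, hist + 36, 0.0);
    for (int c = c0; c <= c1; ++c) {
      for (int r = r0; r <= r1; ++r) {
        double dx = c - x[i], dy = r - y[i];
        double wgt = std::exp(-(dx * dx + dy * dy) / (2 * sw * sw));
        double sgx = gx(r, c), sgy = gy(r, c);
        double mag = std::sqrt(sgx * sgx + sgy * sgy) * wgt;
        if (mag <= 0) continue;
        double ang = wrap2pi(std::atan2(sgy, sgx));
        int b = (int)std::floor(ang / TWO_PI * 36.0) % 36;
        hist[b] += mag;
      }
    }
    double sm[36];
    for (int pass = 0; pass < 2; ++pass) {
      for (int b = 0; b < 36; ++b) {
        sm[b] = (hist[(b + 35) % 36] + hist[b] + hist[(b + 1) % 36]) / 3.0;
      }
      std::copy(sm, sm + 36, hist);
    }
    double mx = *std::max_element(hist, hist + 36);
    if (mx <= 0) { out(i, 0) = 0.0; continue; }
    // collect peaks in descending height
    int order[36];
    int npk = 0;
    for (int b = 0; b < 36; ++b) {
      double l = hist[(b + 35) % 36], r = hist[(b + 1) % 36];
      if (hist[b] >= 0.8 * mx && hist[b] > l && hist[b] >= r) order[npk++] = b;
    }
    if (npk == 0) {
      order[npk++] = (int)(std::max_element(hist, hist + 36) - hist);
    }
    std::stable_sort(order, order + npk,
              [&](int a, int b) { return hist[a] > hist[b]; });
    int keep = std::min(npk, max_peaks);
    for (int k = 0; k < keep; ++k) {
      int b = order[k];
      double l = hist[(b + 35) % 36], cmid = hist[b], r = hist[(b + 1) % 36];
      double den = l - 2 * cmid + r;
      double off = std::fabs(den) > 1e-12 ? 0.5 * (l - r) / den : 0.0;
      double th = wrap2pi((b + off + 0.5) / 36.0 * TWO_PI);
      out(i, k) = th;
    }
  }
  return out;
}
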