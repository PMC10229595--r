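#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Radial FOV-distortion model.
//
// Image convention throughout: matrices are indexed img(y, x) with 0-based
// x = column (fast axis), y = row (slow axis); an image with C columns and
// R rows is an R x C matrix.  The distortion center is
//   c1 = 0.5 * C * (1 + X_off / S_x),  c2 = 0.5 * R * (1 + Y_off / S_y)
// with |X_off|, |Y_off| used here; a negative sign on an offset encodes a
// flip along that axis, handled by the callers via flip_x / flip_y.
// For normalized radius r_u the distorted radius is
//   r_d = (360 / (A pi)) * atan(2 r_u tan(A pi / 720))
// and the sampling maps scale the centered coordinates by f = r_u/r_d
// (pincushion) or r_d/r_u (barrel), with f = 1 at r_u = 0.

static inline double map_factor(double ru, double A_rad_third,
                                double tan_half, double inv_scale,
                                bool pincushion) {
  // A_rad_third = A*pi/360 precomputed pieces: rd = inv_scale * atan(2*ru*tan_half)
  if (ru <= 0.0) return 1.0;
  double rd = inv_scale * std::atan(2.0 * ru * tan_half);
  if (rd <= 0.0) return 1.0;
  return pincushion ? (ru / rd) : (rd / ru);
}

// [[Rcpp::export]]
List cpp_pixel_maps(double A_deg, double xoff, double yoff,
                    double Sx, double Sy, int C, int R, bool pincushion) {
  NumericMatrix Mx(R, C), My(R, C);
  const double c1 = 0.5 * C * (1.0 + xoff / Sx);
  const double c2 = 0.5 * R * (1.0 + yoff / Sy);
  const bool identity = (A_deg < 1e-9);
  const double tan_half = identity ? 0.0 : std::tan(A_deg * M_PI / 720.0);
  const double inv_scale = identity ? 0.0 : 360.0 / (A_deg * M_PI);
  for (int y = 0; y < R; ++y) {
    double ry = (y - c2) / c2;
    for (int x = 0; x < C; ++x) {
      double rx = (x - c1) / c1;
      double f = 1.0;
      if (!identity) {
        double ru = std::sqrt(rx * rx + ry * ry);
        f = map_factor(ru, 0.0, tan_half, inv_scale, pincushion);
      }
      Mx(y, x) = c1 * (1.0 + rx * f);
      My(y, x) = c2 * (1.0 + ry * f);
    }
  }
  return List::create(_["Mx"] = Mx, _["My"] = My);
}

// Maps for the exact inverse of the compensation remap: the gather map of
// the compensation scales the normalized radius as g(r) = r * f(r); the
// forward (inducing) distortion samples at radius g^{-1}(r) so that the
// two remaps compose to the identity in continuous coordinates.  g is
// monotone, so it is inverted by a dense table + linear interpolation.
// `pincushion` names the compensation mode being inverted.
// [[Rcpp::export]]
List cpp_pixel_maps_inv(double A_deg, double xoff, double yoff,
                        double Sx, double Sy, int C, int R,
                        bool pincushion) {
  NumericMatrix Mx(R, C), My(R, C);
  const double c1 = 0.5 * C * (1.0 + xoff / Sx);
  const double c2 = 0.5 * R * (1.0 + yoff / Sy);
  const bool identity = (A_deg < 1e-9);
  const double tan_half = identity ? 0.0 : std::tan(A_deg * M_PI / 720.0);
  const double inv_scale = identity ? 0.0 : 360.0 / (A_deg * M_PI);
  const int N = 8192;
  const double smax = 4.0;
  std::vector<double> g(N + 1);
  if (!identity) {
    for (int i = 0; i <= N; ++i) {
      double s = smax * i / N;
      g[i] = s * map_factor(s, 0.0, tan_half, inv_scale, pincushion);
    }
  }
  for (int y = 0; y < R; ++y) {
    double ry = (y - c2) / c2;
    for (int x = 0; x < C; ++x) {
      double rx = (x - c1) / c1;
      double f = 1.0;
      if (!identity) {
        double ru = std::sqrt(rx * rx + ry * ry);
        if (ru > 0.0) {
          // binary search the monotone table for g(s) = ru
          if (ru >= g[N]) {
            f = smax / ru;
          } else {
            int lo = 0, hi = N;
            while (hi - lo > 1) {
              int mid = (lo + hi) / 2;
              if (g[mid] <= ru) lo = mid; else hi = mid;
            }
            double w = (g[hi] > g[lo]) ? (ru - g[lo]) / (g[hi] - g[lo]) : 0.0;
            double s = smax * (lo + w) / N;
            f = s / ru;
          }
        }
      }
      Mx(y, x) = c1 * (1.0 + rx * f);
      My(y, x) = c2 * (1.0 + ry * f);
    }
  }
  return List::create(_["Mx"] = Mx, _["My"] = My);
}

static inline double sample_bilinear(const NumericMatrix &img,
                                     double sx, double sy) {
  const int R = img.nrow(), C = img.ncol();
  // guard against coordinates a rounding error outside the valid range
  const double eps = 1e-3;
  if (sx > -eps && sx < 0.0) sx = 0.0;
  if (sy > -eps && sy < 0.0) sy = 0.0;
  if (sx > C - 1.0 && sx < C - 1.0 + eps) sx = C - 1.0;
  if (sy > R - 1.0 && sy < R - 1.0 + eps) sy = R - 1.0;
  if (sx < 0.0 || sy < 0.0 || sx > C - 1.0 || sy > R - 1.0)
    return 0.0;  // border fill
  int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy);
  int x1 = x0 + 1 < C ? x0 + 1 : x0;
  int y1 = y0 + 1 < R ? y0 + 1 : y0;
  double wx = sx - x0, wy = sy - y0;
  double top = img(y0, x0) * (1.0 - wx) + img(y0, x1) * wx;
  double bot = img(y1, x0) * (1.0 - wx) + img(y1, x1) * wx;
  return top * (1.0 - wy) + bot * wy;
}

// Remap an image through precomputed maps with an optional flip along each
// axis applied before remapping and undone afterwards (equivalently: the
// output pixel (x, y) reads the maps at the mirrored position and samples
// the input at the mirrored source coordinate).
// [[Rcpp::export]]
NumericMatrix cpp_remap(const NumericMatrix &img,
                        const NumericMatrix &Mx, const NumericMatrix &My,
                        bool flip_x, bool flip_y) {
  const int R = img.nrow(), C = img.ncol();
  NumericMatrix out(R, C);
  for (int y = 0; y < R; ++y) {
    int v = flip_y ? (R - 1 - y) : y;
    for (int x = 0; x < C; ++x) {
      int u = flip_x ? (C - 1 - x) : x;
      double mx = Mx(v, u), my = My(v, u);
      double sx = flip_x ? (C - 1.0 - mx) : mx;
      double sy = flip_y ? (R - 1.0 - my) : my;
      out(y, x) = sample_bilinear(img, sx, sy);
    }
  }
  return out;
}

// Mean absolute difference d_k between the remapped versions of two tiles
// over their overlap ROI, with map values evaluated on the fly so the grid
// search never allocates full maps.  (x1, y1) and (x2, y2) are the 0-based
// top-left corners of the ROI in tile 1 and tile 2 coordinates.
// Pixels whose remap samples outside either tile carry no data and are
// excluded; d_k is normalized by the valid area.  Candidates leaving fewer
// than min_valid_frac of the ROI valid score +Inf.
// [[Rcpp::export]]
double cpp_dk(const NumericMatrix &t1, const NumericMatrix &t2,
              int x1, int y1, int x2, int y2, int roi_w, int roi_h,
              double A_deg, double xoff, double yoff,
              double Sx, double Sy,
              bool flip_x, bool flip_y, bool pincushion,
              double min_valid_frac = 0.25) {
  const int R = t1.nrow(), C = t1.ncol();
  const double c1 = 0.5 * C * (1.0 + xoff / Sx);
  const double c2 = 0.5 * R * (1.0 + yoff / Sy);
  const bool identity = (A_deg < 1e-9);
  const double tan_half = identity ? 0.0 : std::tan(A_deg * M_PI / 720.0);
  const double inv_scale = identity ? 0.0 : 360.0 / (A_deg * M_PI);
  double acc = 0.0;
  long n_valid = 0;
  for (int j = 0; j < roi_h; ++j) {
    for (int i = 0; i < roi_w; ++i) {
      double val[2];
      bool valid = true;
      for (int t = 0; t < 2; ++t) {
        int x = (t == 0 ? x1 : x2) + i;
        int y = (t == 0 ? y1 : y2) + j;
        int u = flip_x ? (C - 1 - x) : x;
        int v = flip_y ? (R - 1 - y) : y;
        double rx = (u - c1) / c1;
        double ry = (v - c2) / c2;
        double f = 1.0;
        if (!identity) {
          double ru = std::sqrt(rx * rx + ry * ry);
          f = map_factor(ru, 0.0, tan_half, inv_scale, pincushion);
        }
        double mx = c1 * (1.0 + rx * f);
        double my = c2 * (1.0 + ry * f);
        double sx = flip_x ? (C - 1.0 - mx) : mx;
        double sy = flip_y ? (R - 1.0 - my) : my;
        if (sx < -1e-3 || sy < -1e-3 ||
            sx > C - 1.0 + 1e-3 || sy > R - 1.0 + 1e-3) {
          valid = false;
          break;
        }
        val[t] = sample_bilinear(t == 0 ? t1 : t2, sx, sy);
      }
      if (valid) {
        acc += std::fabs(val[0] - val[1]);
        ++n_valid;
      }
    }
  }
  if (n_valid < min_valid_frac * (double)roi_w * (double)roi_h)
    return R_PosInf;
  return acc / (double)n_valid;
}

// Plain edge-preserving bilateral filter on an 8-bit-range image.
// [[Rcpp::export]]
NumericMatrix cpp_bilateral(const NumericMatrix &img,
                            double sigma_s, double sigma_r) {
  const int R = img.nrow(), C = img.ncol();
  const int rad = std::max(1, (int)std::ceil(2.5 * sigma_s));
  const double gs = -0.5 / (sigma_s * sigma_s);
  const double gr = -0.5 / (sigma_r * sigma_r);
  NumericMatrix out(R, C);
  for (int y = 0; y < R; ++y) {
    for (int x = 0; x < C; ++x) {
      double center = img(y, x), wsum = 0.0, vsum = 0.0;
      for (int dy = -rad; dy <= rad; ++dy) {
        int yy = y + dy;
        if (yy < 0 || yy >= R) continue;
        for (int dx = -rad; dx <= rad; ++dx) {
          int xx = x + dx;
          if (xx < 0 || xx >= C) continue;
          double dv = img(yy, xx) - center;
          double w = std::exp((dx * dx + dy * dy) * gs + dv * dv * gr);
          wsum += w;
          vsum += w * img(yy, xx);
        }
      }
      out(y, x) = vsum / wsum;
    }
  }
  return out;
}
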