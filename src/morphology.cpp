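#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Grayscale erosion/dilation by a non-flat ball (spherical) structuring
// element: offsets (di,dj) with di^2+dj^2 <= radius^2, height
// z = height_scale * sqrt(radius^2 - d^2) in intensity units.
// Border handling: offsets falling outside the image are skipped, i.e. the
// extremum runs over in-bounds pixels only. The ball is symmetric, so
// erosion E(p) = min_q f(p+q) - z(q) and dilation D(p) = max_q f(p+q) + z(q)
// share one streaming kernel loop (per-offset pass, column-major contiguous).
static NumericMatrix ball_filter(const NumericMatrix &img, double radius,
                                 double height_scale, bool erode) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  std::fill(out.begin(), out.end(), erode ? R_PosInf : R_NegInf);
  int r = (int) std::floor(radius);
  const double *ip = &img(0, 0);
  double *op = &out(0, 0);
  for (int dj = -r; dj <= r; ++dj) {
    for (int di = -r; di <= r; ++di) {
      double d2 = (double) di * di + (double) dj * dj;
      if (d2 > radius * radius) continue;
      double z = height_scale * std::sqrt(radius * radius - d2);
      int j0 = std::max(0, -dj), j1 = nc - 1 - std::max(0, dj);
      int i0 = std::max(0, -di), i1 = nr - 1 - std::max(0, di);
      for (int j = j0; j <= j1; ++j) {
        const double *src = ip + (size_t)(j + dj) * nr + di;
        double *dst = op + (size_t) j * nr;
        if (erode) {
          for (int i = i0; i <= i1; ++i) {
            double v = src[i] - z;
            dst[i] = v < dst[i] ? v : dst[i];
          }
        } else {
          for (int i = i0; i <= i1; ++i) {
            double v = src[i] + z;
            dst[i] = v > dst[i] ? v : dst[i];
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".ball_erode_cpp")]]
NumericMatrix ball_erode_cpp(NumericMatrix img, double radius, double height_scale) {
  return ball_filter(img, radius, height_scale, true);
}

// [[Rcpp::export(name = ".ball_dilate_cpp")]]
NumericMatrix ball_dilate_cpp(NumericMatrix img, double radius, double height_scale) {
  return ball_filter(img, radius, height_scale, false);
}

// Separable Gaussian blur with replicate (edge-clamp) boundary handling.
// The 1D kernel exp(-t^2 / (2 sigma^2)), t in [-R, R] with R = ceil(3 sigma),
// is normalized to sum 1; its outer product is the exact 2D kernel, so the
// two-pass result equals direct 2D convolution up to rounding.
// [[Rcpp::export(name = ".gauss_blur_cpp")]]
NumericMatrix gauss_blur_cpp(NumericMatrix img, double sigma) {
  int nr = img.nrow(), nc = img.ncol();
  int R = (int) std::ceil(3.0 * sigma);
  std::vector<double> k(2 * R + 1);
  double s = 0.0;
  for (int t = -R; t <= R; ++t) {
    k[t + R] = std::exp(-0.5 * t * t / (sigma * sigma));
    s += k[t + R];
  }
  for (double &v : k) v /= s;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int j = 0; j < nc; ++j) {          // along columns (row offsets)
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int t = -R; t <= R; ++t) {
        int ii = std::min(std::max(i + t, 0), nr - 1);
        acc += k[t + R] * img(ii, j);
      }
      tmp(i, j) = acc;
    }
  }
  for (int j = 0; j < nc; ++j) {          // along rows (column offsets)
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int t = -R; t <= R; ++t) {
        int jj = std::min(std::max(j + t, 0), nc - 1);
        acc += k[t + R] * tmp(i, jj);
      }
      out(i, j) = acc;
    }
  }
  return out;
}

// Connected-component labeling of a binary mask (4- or 8-connectivity),
// labels assigned in raster-scan order of first encounter.
// [[Rcpp::export(name = ".cc_label_cpp")]]
IntegerMatrix cc_label_cpp(LogicalMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  static const int dx8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  static const int dy8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  int nnb = (connectivity == 8) ? 8 : 4;
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      stack.clear();
      stack.push_back(i + j * nr);
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        int pi = p % nr, pj = p / nr;
        for (int t = 0; t < nnb; ++t) {
          int ii = pi + dx8[t], jj = pj + dy8[t];
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          if (mask(ii, jj) && lab(ii, jj) == 0) {
            lab(ii, jj) = next;
            stack.push_back(ii + jj * nr);
          }
        }
      }
    }
  }
  return lab;
}

// Additive rendering of edge-feathered disks: each colony contributes
// intensity * Phi((r - d)/feather) (Gaussian edge profile), evaluated inside
// an expanded bounding box. cx/cy are 0-based (row, col) pixel centers.
// [[Rcpp::export(name = ".render_disks_cpp")]]
NumericMatrix render_disks_cpp(NumericMatrix bg, NumericVector cx, NumericVector cy,
                               NumericVector r_px, double intensity, double feather_px) {
  int nr = bg.nrow(), nc = bg.ncol();
  NumericMatrix out = clone(bg);
  int n = cx.size();
  double pad = 4.0 * feather_px;
  for (int t = 0; t < n; ++t) {
    int i0 = std::max(0, (int) std::floor(cx[t] - r_px[t] - pad));
    int i1 = std::min(nr - 1, (int) std::ceil(cx[t] + r_px[t] + pad));
    int j0 = std::max(0, (int) std::floor(cy[t] - r_px[t] - pad));
    int j1 = std::min(nc - 1, (int) std::ceil(cy[t] + r_px[t] + pad));
    for (int j = j0; j <= j1; ++j) {
      for (int i = i0; i <= i1; ++i) {
        double d = std::sqrt((i - cx[t]) * (i - cx[t]) + (j - cy[t]) * (j - cy[t]));
        double f = R::pnorm((r_px[t] - d) / feather_px, 0.0, 1.0, 1, 0);
        out(i, j) += intensity * f;
      }
    }
  }
  return out;
}

// Hard-disk ground-truth mask: pixel true if within radius of any center.
// [[Rcpp::export(name = ".disk_mask_cpp")]]
LogicalMatrix disk_mask_cpp(int nr, int nc, NumericVector cx, NumericVector cy,
                            NumericVector r_px) {
  LogicalMatrix out(nr, nc);
  std::fill(out.begin(), out.end(), false);
  int n = cx.size();
  for (int t = 0; t < n; ++t) {
    int i0 = std::max(0, (int) std::floor(cx[t] - r_px[t]));
    int i1 = std::min(nr - 1, (int) std::ceil(cx[t] + r_px[t]));
    int j0 = std::max(0, (int) std::floor(cy[t] - r_px[t]));
    int j1 = std::min(nc - 1, (int) std::ceil(cy[t] + r_px[t]));
    double r2 = r_px[t] * r_px[t];
    for (int j = j0; j <= j1; ++j) {
      for (int i = i0; i <= i1; ++i) {
        double d2 = (i - cx[t]) * (i - cx[t]) + (j - cy[t]) * (j - cy[t]);
        if (d2 <= r2) out(i, j) = true;
      }
    }
  }
  return out;
}
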