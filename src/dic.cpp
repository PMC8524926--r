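#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Pixel convention throughout: (x, y) zero-based, x = column index
// (rightward), y = row index (downward). An R image matrix m has
// m(y, x) = intensity at pixel (x, y).

static inline double ncc_core(const double* t, const double* p, int n) {
  double num = 0.0, et = 0.0, ep = 0.0;
  for (int i = 0; i < n; ++i) {
    num += t[i] * p[i];
    et  += t[i] * t[i];
    ep  += p[i] * p[i];
  }
  double den = std::sqrt(et * ep);
  if (den <= 0.0) return NA_REAL;
  return num / den;
}

// [[Rcpp::export(name = ".ncc_cpp")]]
double ncc_cpp(NumericMatrix tmpl, NumericMatrix region) {
  if (tmpl.nrow() != region.nrow() || tmpl.ncol() != region.ncol())
    stop("template and region must have identical dimensions");
  return ncc_core(tmpl.begin(), region.begin(), tmpl.size());
}

static inline double bilinear(const NumericMatrix& img, double x, double y) {
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  double fx = x - x0, fy = y - y0;
  int x1 = x0 + (fx > 0.0 ? 1 : 0), y1 = y0 + (fy > 0.0 ? 1 : 0);
  double i00 = img(y0, x0), i10 = img(y0, x1);
  double i01 = img(y1, x0), i11 = img(y1, x1);
  return i00 * (1 - fx) * (1 - fy) + i10 * fx * (1 - fy) +
         i01 * (1 - fx) * fy + i11 * fx * fy;
}

// NCC between the reference subset centred at (cx, cy) and the deformed
// image sampled (bilinearly) at fractional offset (u, v).
static double ncc_at_offset(const std::vector<double>& tmpl, double t_energy,
                            const NumericMatrix& def,
                            int cx, int cy, int half, double u, double v) {
  int W = def.ncol(), H = def.nrow();
  double num = 0.0, ep = 0.0;
  int k = 0;
  for (int dx = -half; dx <= half; ++dx) {
    for (int dy = -half; dy <= half; ++dy, ++k) {
      double X = cx + dx + u, Y = cy + dy + v;
      if (X < 0.0 || Y < 0.0 || X > W - 1.0 || Y > H - 1.0)
        return -2.0; // out of bounds: never selected
      double p = bilinear(def, X, Y);
      num += tmpl[k] * p;
      ep  += p * p;
    }
  }
  double den = std::sqrt(t_energy * ep);
  if (den <= 0.0) return -2.0;
  return num / den;
}

// Subset matching at one point: exhaustive integer-offset NCC search over
// the search window, then optional subpixel refinement on a shrinking
// fractional grid evaluated against bilinearly interpolated grey levels.
// Returns (u, v, c, valid). Ties in the integer stage are broken toward
// the smallest-magnitude displacement, then first in row-major order.
// [[Rcpp::export(name = ".match_subset_cpp")]]
NumericVector match_subset_cpp(NumericMatrix ref, NumericMatrix def,
                               int cx, int cy, int subset, int search,
                               bool subpix, double granularity,
                               double corr_floor, int extra_margin) {
  int half = subset / 2;
  int r = (search - subset) / 2;
  int W = ref.ncol(), H = ref.nrow();
  int margin = half + r + (subpix ? 1 : 0) + extra_margin;
  NumericVector out = NumericVector::create(NA_REAL, NA_REAL, NA_REAL, 0.0);
  if (cx - margin < 0 || cy - margin < 0 || cx + margin > W - 1 ||
      cy + margin > H - 1)
    return out; // search window leaves the image: invalid point
  if (def.ncol() != W || def.nrow() != H)
    stop("reference and deformed images must share dimensions");

  int n = subset * subset;
  std::vector<double> tmpl(n);
  double t_energy = 0.0, t_sum = 0.0;
  int k = 0;
  // template stored column-major (dx outer, dy inner) to match the
  // column-major layout of R matrices in the search loops below
  for (int dx = -half; dx <= half; ++dx) {
    const double* col = &ref(0, cx + dx);
    for (int dy = -half; dy <= half; ++dy, ++k) {
      double t = col[cy + dy];
      tmpl[k] = t;
      t_energy += t * t;
      t_sum += t;
    }
  }
  // degenerate (constant) subset carries no texture to match
  double t_var = t_energy / n - (t_sum / n) * (t_sum / n);
  if (t_energy <= 0.0 || t_var <= 1e-12 * t_energy / n) return out;

  // coarse stage: exhaustive integer search
  double best = -2.0; int bu = 0, bv = 0; double bmag = 1e30;
  for (int dv = -r; dv <= r; ++dv) {
    for (int du = -r; du <= r; ++du) {
      double num = 0.0, ep = 0.0;
      k = 0;
      for (int dx = -half; dx <= half; ++dx) {
        const double* col = &def(0, cx + du + dx);
        for (int dy = -half; dy <= half; ++dy, ++k) {
          double p = col[cy + dv + dy];
          num += tmpl[k] * p;
          ep  += p * p;
        }
      }
      double den = std::sqrt(t_energy * ep);
      if (den <= 0.0) continue;
      double c = num / den;
      double mag = (double)du * du + (double)dv * dv;
      if (c > best + 1e-12 ||
          (std::fabs(c - best) <= 1e-12 && mag < bmag)) {
        best = c; bu = du; bv = dv; bmag = mag;
      }
    }
  }
  if (best <= -2.0) return out;

  double u = bu, v = bv, c = best;
  if (subpix && granularity > 0.0) {
    double h = 0.25;
    while (true) {
      double cu = u, cv = v;
      for (int i = -2; i <= 2; ++i) {
        for (int j = -2; j <= 2; ++j) {
          if (i == 0 && j == 0) continue;
          double uu = cu + j * h, vv = cv + i * h;
          if (std::fabs(uu) > r + 0.5 || std::fabs(vv) > r + 0.5) continue;
          double cc = ncc_at_offset(tmpl, t_energy, def, cx, cy, half, uu, vv);
          if (cc > c + 1e-15) { c = cc; u = uu; v = vv; }
        }
      }
      if (h <= granularity + 1e-12) break;
      h = std::max(h / 5.0, granularity);
    }
  }
  out[0] = u; out[1] = v; out[2] = c;
  out[3] = (c >= corr_floor) ? 1.0 : 0.0;
  return out;
}

// Vectorised matching over a lattice of subset centres.
// Returns a (npoints x 4) matrix of (u, v, c, valid).
// [[Rcpp::export(name = ".match_grid_cpp")]]
NumericMatrix match_grid_cpp(NumericMatrix ref, NumericMatrix def,
                             IntegerVector cx, IntegerVector cy,
                             int subset, int search, bool subpix,
                             double granularity, double corr_floor,
                             int extra_margin) {
  int np = cx.size();
  NumericMatrix out(np, 4);
  for (int i = 0; i < np; ++i) {
    NumericVector m = match_subset_cpp(ref, def, cx[i], cy[i], subset,
                                       search, subpix, granularity,
                                       corr_floor, extra_margin);
    out(i, 0) = m[0]; out(i, 1) = m[1]; out(i, 2) = m[2]; out(i, 3) = m[3];
  }
  return out;
}
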