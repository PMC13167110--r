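#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Grayscale morphology with an arbitrary (possibly non-flat) structuring
// element given as parallel offset/height vectors. Out-of-bounds neighbours
// are ignored (min/max over the valid support only), which leaves constant
// images constant under opening.
// [[Rcpp::export]]
NumericMatrix gray_morph(NumericMatrix img, IntegerVector dx, IntegerVector dy,
                         NumericVector h, int op) {
  const int nr = img.nrow(), nc = img.ncol(), k = dx.size();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double acc = (op == 0) ? R_PosInf : R_NegInf;
      for (int m = 0; m < k; ++m) {
        int ii = i + dy[m], jj = j + dx[m];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        double v = (op == 0) ? img(ii, jj) - h[m] : img(ii, jj) + h[m];
        if (op == 0) { if (v < acc) acc = v; } else { if (v > acc) acc = v; }
      }
      out(i, j) = acc;
    }
  }
  return out;
}

static inline void similarity_inverse(double xf, double yf, double cxf, double cyf,
                                      double cxm, double cym, double tx, double ty,
                                      double cth, double sth, double scale,
                                      double* xm, double* ym) {
  // forward map: [xf; yf] = s * R(theta) * ([xm; ym] - c_m) + c_f + t
  double u = xf - cxf - tx, v = yf - cyf - ty;
  *xm = ( cth * u + sth * v) / scale + cxm;
  *ym = (-sth * u + cth * v) / scale + cym;
}

// Pearson correlation between `fixed` and `moving` warped into the fixed
// frame by a similarity transform (scale about centre, rotate, translate).
// Evaluated on the valid-overlap region, optionally on a strided pixel
// lattice. Returns -Inf when the overlap is below `min_overlap` of the
// sampled fixed pixels.
// [[Rcpp::export]]
double warp_correlate(NumericMatrix fixed, NumericMatrix moving,
                      double tx, double ty, double rot_deg, double scale,
                      double min_overlap, int stride) {
  const int nrf = fixed.nrow(), ncf = fixed.ncol();
  const int nrm = moving.nrow(), ncm = moving.ncol();
  const double th = rot_deg * M_PI / 180.0, cth = std::cos(th), sth = std::sin(th);
  const double cxf = (ncf + 1) / 2.0, cyf = (nrf + 1) / 2.0;
  const double cxm = (ncm + 1) / 2.0, cym = (nrm + 1) / 2.0;
  double sx = 0, sy = 0, sxx = 0, syy = 0, sxy = 0;
  long n = 0, total = 0;
  for (int j = 0; j < ncf; j += stride) {
    for (int i = 0; i < nrf; i += stride) {
      ++total;
      double xm, ym;
      similarity_inverse(j + 1.0, i + 1.0, cxf, cyf, cxm, cym, tx, ty,
                         cth, sth, scale, &xm, &ym);
      if (xm < 1.0 || xm > ncm || ym < 1.0 || ym > nrm) continue;
      int j0 = (int)std::floor(xm) - 1, i0 = (int)std::floor(ym) - 1;
      if (j0 > ncm - 2) j0 = ncm - 2;
      if (i0 > nrm - 2) i0 = nrm - 2;
      double fx = xm - 1.0 - j0, fy = ym - 1.0 - i0;
      double a = moving(i0, j0) * (1 - fx) * (1 - fy)
               + moving(i0, j0 + 1) * fx * (1 - fy)
               + moving(i0 + 1, j0) * (1 - fx) * fy
               + moving(i0 + 1, j0 + 1) * fx * fy;
      double b = fixed(i, j);
      sx += b; sy += a; sxx += b * b; syy += a * a; sxy += a * b;
      ++n;
    }
  }
  if (total == 0 || (double)n / (double)total < min_overlap || n < 3)
    return R_NegInf;
  double vx = sxx - sx * sx / n, vy = syy - sy * sy / n;
  if (vx <= 0 || vy <= 0) return R_NegInf;
  return (sxy - sx * sy / n) / std::sqrt(vx * vy);
}

// Warp `moving` into a fixed frame of size (out_nr, out_nc) by the same
// similarity transform. mode 0 = bilinear (fill NA), 1 = nearest (fill 0).
// [[Rcpp::export]]
NumericMatrix warp_image(NumericMatrix moving, int out_nr, int out_nc,
                         double tx, double ty, double rot_deg, double scale,
                         int mode) {
  const int nrm = moving.nrow(), ncm = moving.ncol();
  const double th = rot_deg * M_PI / 180.0, cth = std::cos(th), sth = std::sin(th);
  const double cxf = (out_nc + 1) / 2.0, cyf = (out_nr + 1) / 2.0;
  const double cxm = (ncm + 1) / 2.0, cym = (nrm + 1) / 2.0;
  NumericMatrix out(out_nr, out_nc);
  for (int j = 0; j < out_nc; ++j) {
    for (int i = 0; i < out_nr; ++i) {
      double xm, ym;
      similarity_inverse(j + 1.0, i + 1.0, cxf, cyf, cxm, cym, tx, ty,
                         cth, sth, scale, &xm, &ym);
      if (mode == 1) {
        int jj = (int)std::lround(xm) - 1, ii = (int)std::lround(ym) - 1;
        out(i, j) = (ii < 0 || ii >= nrm || jj < 0 || jj >= ncm)
                      ? 0.0 : moving(ii, jj);
      } else {
        if (xm < 1.0 || xm > ncm || ym < 1.0 || ym > nrm) {
          out(i, j) = NA_REAL;
        } else {
          int j0 = (int)std::floor(xm) - 1, i0 = (int)std::floor(ym) - 1;
          if (j0 > ncm - 2) j0 = ncm - 2;
          if (i0 > nrm - 2) i0 = nrm - 2;
          double fx = xm - 1.0 - j0, fy = ym - 1.0 - i0;
          out(i, j) = moving(i0, j0) * (1 - fx) * (1 - fy)
                    + moving(i0, j0 + 1) * fx * (1 - fy)
                    + moving(i0 + 1, j0) * (1 - fx) * fy
                    + moving(i0 + 1, j0 + 1) * fx * fy;
        }
      }
    }
  }
  return out;
}
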