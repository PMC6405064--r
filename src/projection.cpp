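#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Bilinear sample of an n x n image; coordinates in pixel units with the
// rotation centre at (c, c), c = (n - 1) / 2. Out-of-grid reads are 0.
static inline double sample_bilinear(const double* img, int n, double x, double y) {
  if (x < 0.0 || y < 0.0 || x > n - 1.0 || y > n - 1.0) return 0.0;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  int x1 = x0 + 1, y1 = y0 + 1;
  double fx = x - x0, fy = y - y0;
  double v00 = img[x0 + n * y0];
  double v10 = (x1 < n) ? img[x1 + n * y0] : 0.0;
  double v01 = (y1 < n) ? img[x0 + n * y1] : 0.0;
  double v11 = (x1 < n && y1 < n) ? img[x1 + n * y1] : 0.0;
  return v00 * (1 - fx) * (1 - fy) + v10 * fx * (1 - fy) +
         v01 * (1 - fx) * fy + v11 * fx * fy;
}

// Parallel-beam forward projection (discrete Radon transform) of one slice.
// image: n x n matrix; angles in radians. Returns n_det x n_angles sinogram
// of line integrals in pixel-length units (step size `step` pixels).
// [[Rcpp::export]]
NumericMatrix forward_project_cpp(NumericMatrix image, NumericVector angles,
                                  double step = 0.5) {
  int n = image.nrow();
  if (image.ncol() != n) stop("image must be square");
  int na = angles.size();
  NumericMatrix sino(n, na);
  double c = (n - 1.0) / 2.0;
  double smax = n / 2.0;
  int nsteps = (int)std::ceil(2.0 * smax / step);
  const double* img = image.begin();
  for (int a = 0; a < na; ++a) {
    double ct = std::cos(angles[a]), st = std::sin(angles[a]);
    for (int d = 0; d < n; ++d) {
      double t = d - c;     // detector offset from centre, pixels
      double acc = 0.0;
      for (int k = 0; k <= nsteps; ++k) {
        double s = -smax + k * step;
        double x = c + t * (-st) + s * ct;
        double y = c + t * ct + s * st;
        acc += sample_bilinear(img, n, x, y);
      }
      sino(d, a) = acc * step;
    }
  }
  return sino;
}

// Backprojection of a (ramp-filtered) sinogram onto an n x n grid.
// Applies the standard pi / n_angles weighting.
// [[Rcpp::export]]
NumericMatrix backproject_cpp(NumericMatrix fsino, NumericVector angles) {
  int n = fsino.nrow();
  int na = angles.size();
  if (fsino.ncol() != na) stop("sinogram/angle mismatch");
  NumericMatrix out(n, n);
  double c = (n - 1.0) / 2.0;
  double w = M_PI / na;
  for (int a = 0; a < na; ++a) {
    double ct = std::cos(angles[a]), st = std::sin(angles[a]);
    const double* col = &fsino(0, a);
    for (int j = 0; j < n; ++j) {
      double yc = j - c;
      for (int i = 0; i < n; ++i) {
        double xc = i - c;
        double t = xc * (-st) + yc * ct + c;   // detector coordinate
        if (t < 0.0 || t > n - 1.0) continue;
        int t0 = (int)std::floor(t);
        double ft = t - t0;
        double v = col[t0] * (1 - ft);
        if (t0 + 1 < n) v += col[t0 + 1] * ft;
        out(i, j) += v * w;
      }
    }
  }
  return out;
}
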