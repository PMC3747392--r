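#include <Rcpp.h>
#include <cmath>

// Separable kernel-weighted sampling of 3D volumes.
//
// Kernel ids: 0 nearest, 1 trilinear, 2 lagrange4, 3 lagrange6, 4 lagrange8,
//             5 bspline3, 6 bspline4, 7 windowed_sinc.
// Boundary ids: 0 zero, 1 clamp, 2 mirror.
//
// Convention (shared with the R layer): 0-based voxel indices, sample
// positions at voxel centres, continuous coordinate == index.

static const double PI = 3.14159265358979323846;

// Centered cardinal B-spline of given degree via the two-term recursion.
static double bspline_card(int degree, double x) {
  double a = std::fabs(x);
  if (degree == 3) {  // closed form of the two-term recursion
    if (a < 1.0) return 2.0 / 3.0 - a * a + a * a * a * 0.5;
    if (a < 2.0) { double t = 2.0 - a; return t * t * t / 6.0; }
    return 0.0;
  }
  if (degree == 4) {
    if (a < 0.5) {
      double a2 = a * a;
      return 115.0 / 192.0 - 5.0 / 8.0 * a2 + 0.25 * a2 * a2;
    }
    if (a < 1.5)
      return (55.0 + a * (20.0 + a * (-120.0 + a * (80.0 - 16.0 * a)))) / 96.0;
    if (a < 2.5) { double t = 5.0 - 2.0 * a; double t2 = t * t; return t2 * t2 / 384.0; }
    return 0.0;
  }
  if (degree == 0) return (x >= -0.5 && x < 0.5) ? 1.0 : 0.0;
  double h = (degree + 1) * 0.5;
  return ((x + h) * bspline_card(degree - 1, x + 0.5) +
          (h - x) * bspline_card(degree - 1, x - 0.5)) / degree;
}

// Fill taps (0-based input indices, unfolded) and weights for one axis.
// Returns the number of taps. tap[j] is the integer grid position, w[j] its
// kernel weight at continuous position x.
static int axis_weights(double x, int kernel, int radius, int *tap, double *w) {
  int n = 0;
  switch (kernel) {
  case 0: { // nearest: box kernel, half-open [n-1/2, n+1/2)
    tap[0] = (int)std::floor(x + 0.5);
    w[0] = 1.0;
    n = 1;
    break;
  }
  case 1: case 2: case 3: case 4: { // central Lagrange, N = 2, 4, 6, 8
    int N = 2 * (kernel == 1 ? 1 : (kernel == 2 ? 2 : (kernel == 3 ? 3 : 4)));
    int half = N / 2;
    double base = std::floor(x);
    double f = x - base;
    // taps at relative offsets k = -(half-1) .. half
    for (int j = 0; j < N; ++j) {
      int k = j - (half - 1);
      tap[j] = (int)base + k;
      double num = 1.0, den = 1.0;
      for (int m = -(half - 1); m <= half; ++m) {
        if (m == k) continue;
        num *= (f - m);
        den *= (double)(k - m);
      }
      w[j] = num / den;
    }
    n = N;
    break;
  }
  case 5: { // cubic B-spline, support (-2, 2)
    int base = (int)std::floor(x);
    for (int j = 0; j < 4; ++j) {
      tap[j] = base - 1 + j;
      w[j] = bspline_card(3, x - tap[j]);
    }
    n = 4;
    break;
  }
  case 6: { // quartic B-spline, support (-2.5, 2.5)
    int center = (int)std::floor(x + 0.5);
    for (int j = 0; j < 5; ++j) {
      tap[j] = center - 2 + j;
      w[j] = bspline_card(4, x - tap[j]);
    }
    n = 5;
    break;
  }
  case 7: { // sinc windowed by a Hann lobe of the given radius
    int r = radius;
    double base = std::floor(x);
    double f = x - base;
    double spf = std::sin(PI * f);
    // Hann factors via the cosine addition recurrence: angles step by pi/r.
    double step = PI / r;
    double two_cos_step = 2.0 * std::cos(step);
    double th0 = (f + r - 1) * step; // angle for j = 0 (largest |d|)
    double c_prev = std::cos(th0);
    double c_curr = std::cos(th0 - step);
    for (int j = 0; j < 2 * r; ++j) {
      int k = j - (r - 1);
      tap[j] = (int)base + k;
      double d = f - k;
      double s;
      if (d == 0.0) {
        s = 1.0;
      } else {
        s = ((k % 2 == 0) ? spf : -spf) / (PI * d);
      }
      double cosv = (j == 0) ? c_prev : c_curr;
      double hann = (std::fabs(d) < r) ? 0.5 * (1.0 + cosv) : 0.0;
      w[j] = s * hann;
      if (j >= 1) {
        double c_next = two_cos_step * c_curr - c_prev;
        c_prev = c_curr;
        c_curr = c_next;
      }
    }
    n = 2 * r;
    break;
  }
  default:
    Rcpp::stop("unknown kernel id");
  }
  return n;
}

// Fold an index into [0, n) per boundary policy; returns -1 when the sample
// contributes zero (boundary id 0).
static inline int fold_index(int i, int n, int boundary) {
  if (i >= 0 && i < n) return i;
  switch (boundary) {
  case 0: return -1;
  case 1: return (i < 0) ? 0 : (n - 1);
  case 2: {
    if (n == 1) return 0;
    int period = 2 * n - 2;
    int j = i % period;
    if (j < 0) j += period;
    return (j < n) ? j : (period - j);
  }
  default: Rcpp::stop("unknown boundary id");
  }
  return -1;
}

#define MAX_TAPS 64

static double sample_one(const double *data, int nx, int ny, int nz,
                         double px, double py, double pz,
                         int kernel, int radius, int boundary) {
  int tx[MAX_TAPS], ty[MAX_TAPS], tz[MAX_TAPS];
  double wx[MAX_TAPS], wy[MAX_TAPS], wz[MAX_TAPS];
  int cx = axis_weights(px, kernel, radius, tx, wx);
  int cy = axis_weights(py, kernel, radius, ty, wy);
  int cz = axis_weights(pz, kernel, radius, tz, wz);
  int ix[MAX_TAPS], iy[MAX_TAPS], iz[MAX_TAPS];
  for (int j = 0; j < cx; ++j) ix[j] = fold_index(tx[j], nx, boundary);
  for (int j = 0; j < cy; ++j) iy[j] = fold_index(ty[j], ny, boundary);
  for (int j = 0; j < cz; ++j) iz[j] = fold_index(tz[j], nz, boundary);
  double acc = 0.0;
  for (int c = 0; c < cz; ++c) {
    if (iz[c] < 0 || wz[c] == 0.0) continue;
    double accz = 0.0;
    long long offz = (long long)iz[c] * ny;
    for (int b = 0; b < cy; ++b) {
      if (iy[b] < 0 || wy[b] == 0.0) continue;
      double accy = 0.0;
      long long offy = (offz + iy[b]) * nx;
      for (int a = 0; a < cx; ++a) {
        if (ix[a] < 0) continue;
        accy += wx[a] * data[offy + ix[a]];
      }
      accz += wy[b] * accy;
    }
    acc += wz[c] * accz;
  }
  return acc;
}

// [[Rcpp::export(name = ".cpp_sample_points")]]
Rcpp::NumericVector cpp_sample_points(Rcpp::NumericVector data,
                                      Rcpp::IntegerVector dim,
                                      Rcpp::NumericMatrix pts,
                                      int kernel, int radius, int boundary) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int npts = pts.nrow();
  Rcpp::NumericVector out(npts);
  const double *d = data.begin();
  for (int i = 0; i < npts; ++i) {
    out[i] = sample_one(d, nx, ny, nz, pts(i, 0), pts(i, 1), pts(i, 2),
                        kernel, radius, boundary);
  }
  return out;
}

// Resample through an affine map. M is a 3x4 matrix taking 0-based OUTPUT
// voxel indices to continuous INPUT voxel coordinates. Returns the resampled
// values plus a logical vector marking output voxels whose pull-back lies
// within the input grid (to within half a voxel).
// [[Rcpp::export(name = ".cpp_resample_affine")]]
Rcpp::List cpp_resample_affine(Rcpp::NumericVector data,
                               Rcpp::IntegerVector dim,
                               Rcpp::NumericMatrix M,
                               Rcpp::IntegerVector outdim,
                               int kernel, int radius, int boundary) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int ox = outdim[0], oy = outdim[1], oz = outdim[2];
  long long ntot = (long long)ox * oy * oz;
  Rcpp::NumericVector out((R_xlen_t)ntot);
  Rcpp::LogicalVector inside((R_xlen_t)ntot);
  const double *d = data.begin();
  double m00 = M(0, 0), m01 = M(0, 1), m02 = M(0, 2), m03 = M(0, 3);
  double m10 = M(1, 0), m11 = M(1, 1), m12 = M(1, 2), m13 = M(1, 3);
  double m20 = M(2, 0), m21 = M(2, 1), m22 = M(2, 2), m23 = M(2, 3);
  long long idx = 0;
  for (int k = 0; k < oz; ++k) {
    double pxk = m02 * k + m03, pyk = m12 * k + m13, pzk = m22 * k + m23;
    for (int j = 0; j < oy; ++j) {
      double pxj = pxk + m01 * j, pyj = pyk + m11 * j, pzj = pzk + m21 * j;
      double px = pxj, py = pyj, pz = pzj;
      for (int i = 0; i < ox; ++i, ++idx, px += m00, py += m10, pz += m20) {
        out[idx] = sample_one(d, nx, ny, nz, px, py, pz, kernel, radius, boundary);
        inside[idx] = (px >= -0.5 && px < nx - 0.5 &&
                       py >= -0.5 && py < ny - 0.5 &&
                       pz >= -0.5 && pz < nz - 0.5);
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("values") = out,
                            Rcpp::Named("inside") = inside);
}

// Kernel weight function exposed for validation: evaluates the 1D kernel at
// arbitrary signed offsets (same code path the resampler uses).
// [[Rcpp::export(name = ".cpp_kernel_eval")]]
Rcpp::NumericVector cpp_kernel_eval(Rcpp::NumericVector x, int kernel, int radius) {
  int nx = x.size();
  Rcpp::NumericVector out(nx);
  int tap[MAX_TAPS];
  double w[MAX_TAPS];
  for (int i = 0; i < nx; ++i) {
    // Weights at continuous position x[i] relative to the grid; the weight
    // attached to grid point 0 is the kernel value at offset x[i].
    int n = axis_weights(x[i], kernel, radius, tap, w);
    double v = 0.0;
    for (int j = 0; j < n; ++j) if (tap[j] == 0) v = w[j];
    out[i] = v;
  }
  return out;
}
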