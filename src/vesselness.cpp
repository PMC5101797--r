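#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Sampled Gaussian-derivative kernels, radius 4*sigma. Discrete moments are
// corrected so that convolution reproduces derivatives of polynomials exactly:
// order 0 sums to 1; order 1 maps x -> 1; order 2 maps x^2/2 -> 1.
static std::vector<double> gauss_kernel(double sigma, int order) {
  int R = std::max(1, (int)std::ceil(4.0 * sigma));
  int n = 2 * R + 1;
  std::vector<double> g(n), k(n);
  double s2 = sigma * sigma;
  double sum = 0.0;
  for (int i = 0; i < n; i++) {
    double x = i - R;
    g[i] = std::exp(-0.5 * x * x / s2);
    sum += g[i];
  }
  for (int i = 0; i < n; i++) g[i] /= sum;
  if (order == 0) return g;
  if (order == 1) {
    for (int i = 0; i < n; i++) {
      double x = i - R;
      k[i] = -(x / s2) * g[i];
    }
    double m1 = 0.0;
    for (int i = 0; i < n; i++) m1 += -(double)(i - R) * k[i];
    for (int i = 0; i < n; i++) k[i] /= m1;
    return k;
  }
  for (int i = 0; i < n; i++) {
    double x = i - R;
    k[i] = ((x * x / s2) - 1.0) / s2 * g[i];
  }
  double mean = 0.0;
  for (int i = 0; i < n; i++) mean += k[i];
  mean /= n;
  for (int i = 0; i < n; i++) k[i] -= mean;
  double m2 = 0.0;
  for (int i = 0; i < n; i++) {
    double x = i - R;
    m2 += 0.5 * x * x * k[i];
  }
  for (int i = 0; i < n; i++) k[i] /= m2;
  return k;
}

// mirror-with-edge reflection (a b c | c b a)
static inline int reflect_idx(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// 1D convolution along one axis of a 3D array (column-major, x fastest).
// in == out is allowed (each line is buffered before writing).
static void conv_axis(const double* in, double* out,
                      int nx, int ny, int nz, int axis,
                      const std::vector<double>& k, int sym) {
  int R = ((int)k.size() - 1) / 2;
  long n[3] = {nx, ny, nz};
  long stride[3] = {1, nx, (long)nx * ny};
  int a1 = (axis == 0) ? 1 : 0;
  int a2 = (axis == 2) ? 1 : 2;
  int len = (int)n[axis];
  long sa = stride[axis];
  std::vector<double> line(len);
  for (long j2 = 0; j2 < n[a2]; j2++) {
    for (long j1 = 0; j1 < n[a1]; j1++) {
      long base = j1 * stride[a1] + j2 * stride[a2];
      for (int i = 0; i < len; i++) line[i] = in[base + (long)i * sa];
      for (int i = 0; i < len; i++) {
        double acc;
        if (i - R >= 0 && i + R < len) {
          // interior: pair the taps (kernels are symmetric or antisymmetric)
          const double* lp = &line[i];
          acc = k[R] * lp[0];
          if (sym > 0)
            for (int m = 1; m <= R; m++) acc += k[R + m] * (lp[-m] + lp[m]);
          else
            for (int m = 1; m <= R; m++) acc += k[R + m] * (lp[-m] - lp[m]);
        } else {
          acc = 0.0;
          for (int m = -R; m <= R; m++)
            acc += line[reflect_idx(i - m, len)] * k[m + R];
        }
        out[base + (long)i * sa] = acc;
      }
    }
  }
}

// Six unique components of the sigma^2-normalized Hessian (gamma = 2) of the
// Gaussian-smoothed volume, by separable convolution with shared passes.
static void hessian_components(const double* vol, int nx, int ny, int nz,
                               double sigma,
                               std::vector<double>& hxx, std::vector<double>& hyy,
                               std::vector<double>& hzz, std::vector<double>& hxy,
                               std::vector<double>& hxz, std::vector<double>& hyz) {
  long N = (long)nx * ny * nz;
  std::vector<double> g0 = gauss_kernel(sigma, 0);
  std::vector<double> g1 = gauss_kernel(sigma, 1);
  std::vector<double> g2 = gauss_kernel(sigma, 2);

  std::vector<double> a0(N), a1(N), a2(N);
  conv_axis(vol, a0.data(), nx, ny, nz, 0, g0, 1);
  conv_axis(vol, a1.data(), nx, ny, nz, 0, g1, -1);
  conv_axis(vol, a2.data(), nx, ny, nz, 0, g2, 1);

  hyy.resize(N); hzz.resize(N); hyz.resize(N);
  hxy.resize(N); hxz.resize(N); hxx.resize(N);
  conv_axis(a0.data(), hyy.data(), nx, ny, nz, 1, g2, 1); // x0 y2 -> z0
  conv_axis(a0.data(), hzz.data(), nx, ny, nz, 1, g0, 1); // x0 y0 -> z2
  conv_axis(a0.data(), hyz.data(), nx, ny, nz, 1, g1, -1); // x0 y1 -> z1
  conv_axis(a1.data(), hxy.data(), nx, ny, nz, 1, g1, -1); // x1 y1 -> z0
  conv_axis(a1.data(), hxz.data(), nx, ny, nz, 1, g0, 1); // x1 y0 -> z1
  conv_axis(a2.data(), hxx.data(), nx, ny, nz, 1, g0, 1); // x2 y0 -> z0
  a0.clear(); a0.shrink_to_fit();
  a1.clear(); a1.shrink_to_fit();
  a2.clear(); a2.shrink_to_fit();

  conv_axis(hyy.data(), hyy.data(), nx, ny, nz, 2, g0, 1);
  conv_axis(hzz.data(), hzz.data(), nx, ny, nz, 2, g2, 1);
  conv_axis(hyz.data(), hyz.data(), nx, ny, nz, 2, g1, -1);
  conv_axis(hxy.data(), hxy.data(), nx, ny, nz, 2, g0, 1);
  conv_axis(hxz.data(), hxz.data(), nx, ny, nz, 2, g1, -1);
  conv_axis(hxx.data(), hxx.data(), nx, ny, nz, 2, g0, 1);

  double s2 = sigma * sigma;
  for (long i = 0; i < N; i++) {
    hxx[i] *= s2; hyy[i] *= s2; hzz[i] *= s2;
    hxy[i] *= s2; hxz[i] *= s2; hyz[i] *= s2;
  }
}

// Eigenvalues of the symmetric matrix [[a,d,e],[d,b,f],[e,f,c]] by the
// trigonometric closed form; written to w unsorted.
static inline void eig_sym3(double a, double b, double c,
                            double d, double e, double f, double* w) {
  double p1 = d * d + e * e + f * f;
  if (p1 == 0.0) {
    w[0] = a; w[1] = b; w[2] = c;
    return;
  }
  double q = (a + b + c) / 3.0;
  double p2 = (a - q) * (a - q) + (b - q) * (b - q) + (c - q) * (c - q) + 2.0 * p1;
  double p = std::sqrt(p2 / 6.0);
  if (p <= 0.0) {
    w[0] = q; w[1] = q; w[2] = q;
    return;
  }
  double B11 = (a - q) / p, B22 = (b - q) / p, B33 = (c - q) / p;
  double B12 = d / p, B13 = e / p, B23 = f / p;
  double detB = B11 * (B22 * B33 - B23 * B23)
              - B12 * (B12 * B33 - B23 * B13)
              + B13 * (B12 * B23 - B22 * B13);
  double r = detB / 2.0;
  if (r < -1.0) r = -1.0;
  if (r > 1.0) r = 1.0;
  double phi = std::acos(r) / 3.0;
  double e1 = q + 2.0 * p * std::cos(phi);
  double e3 = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
  w[0] = e1;
  w[1] = 3.0 * q - e1 - e3;
  w[2] = e3;
}

static inline void sort_by_abs(double* w) {
  double a0 = std::fabs(w[0]), a1 = std::fabs(w[1]), a2 = std::fabs(w[2]);
  double t;
  if (a1 < a0) { t = w[0]; w[0] = w[1]; w[1] = t; t = a0; a0 = a1; a1 = t; }
  if (a2 < a1) {
    t = w[1]; w[1] = w[2]; w[2] = t; t = a1; a1 = a2; a2 = t;
    if (a1 < a0) { t = w[0]; w[0] = w[1]; w[1] = t; }
  }
}

// [[Rcpp::export]]
List cpp_hessian_scale(NumericVector vol, IntegerVector dims, double sigma) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long N = (long)nx * ny * nz;
  std::vector<double> hxx, hyy, hzz, hxy, hxz, hyz;
  hessian_components(REAL(vol), nx, ny, nz, sigma, hxx, hyy, hzz, hxy, hxz, hyz);
  NumericVector oxx(N), oyy(N), ozz(N), oxy(N), oxz(N), oyz(N);
  std::copy(hxx.begin(), hxx.end(), oxx.begin());
  std::copy(hyy.begin(), hyy.end(), oyy.begin());
  std::copy(hzz.begin(), hzz.end(), ozz.begin());
  std::copy(hxy.begin(), hxy.end(), oxy.begin());
  std::copy(hxz.begin(), hxz.end(), oxz.begin());
  std::copy(hyz.begin(), hyz.end(), oyz.begin());
  return List::create(_["hxx"] = oxx, _["hyy"] = oyy, _["hzz"] = ozz,
                      _["hxy"] = oxy, _["hxz"] = oxz, _["hyz"] = oyz);
}

// [[Rcpp::export]]
List cpp_eigvals_sym3(NumericVector hxx, NumericVector hyy, NumericVector hzz,
                      NumericVector hxy, NumericVector hxz, NumericVector hyz) {
  long N = hxx.size();
  NumericVector h1(N), h2(N), h3(N);
  double w[3];
  for (long i = 0; i < N; i++) {
    eig_sym3(hxx[i], hyy[i], hzz[i], hxy[i], hxz[i], hyz[i], w);
    sort_by_abs(w);
    h1[i] = w[0]; h2[i] = w[1]; h3[i] = w[2];
  }
  return List::create(_["h1"] = h1, _["h2"] = h2, _["h3"] = h3);
}

// Per-scale geometry factor A = (1 - exp(-RA^2/2a^2)) * exp(-RB^2/2b^2)
// (zero where h2 > 0 or h3 > 0, or h3 == 0) and structureness S = ||H||_F.
// The noise-suppression factor (1 - exp(-S^2/2c^2)) is applied later, once
// c has been resolved across scales.
// [[Rcpp::export]]
List cpp_vesselness_scale(NumericVector vol, IntegerVector dims, double sigma,
                          double alpha, double beta) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long N = (long)nx * ny * nz;
  std::vector<double> hxx, hyy, hzz, hxy, hxz, hyz;
  hessian_components(REAL(vol), nx, ny, nz, sigma, hxx, hyy, hzz, hxy, hxz, hyz);
  NumericVector A(N), S(N);
  double inv2a2 = 1.0 / (2.0 * alpha * alpha);
  double inv2b2 = 1.0 / (2.0 * beta * beta);
  double w[3];
  for (long i = 0; i < N; i++) {
    eig_sym3(hxx[i], hyy[i], hzz[i], hxy[i], hxz[i], hyz[i], w);
    sort_by_abs(w);
    double h1 = w[0], h2 = w[1], h3 = w[2];
    S[i] = std::sqrt(h1 * h1 + h2 * h2 + h3 * h3);
    if (h2 > 0.0 || h3 > 0.0 || h3 == 0.0) {
      A[i] = 0.0;
    } else {
      double RA = std::fabs(h2) / std::fabs(h3);
      double RB = std::fabs(h1) / std::sqrt(std::fabs(h2 * h3));
      A[i] = (1.0 - std::exp(-RA * RA * inv2a2)) * std::exp(-RB * RB * inv2b2);
    }
  }
  return List::create(_["A"] = A, _["S"] = S);
}
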