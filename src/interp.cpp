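// Separable cubic B-spline volume interpolation (coefficient prefilter with
// the standard recursive filter, mirror boundaries), nearest-neighbour
// resampling for masks, and a nearest-value fill used before resampling
// feature maps that are undefined outside the ROI.
#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

static const double POLE = -0.26794919243112270647;  // sqrt(3) - 2

static void prefilter_line(double* c, int n, int stride) {
  if (n == 1) return;
  const double z = POLE, lambda = 6.0;
  for (int i = 0; i < n; ++i) c[i * stride] *= lambda;
  // causal init under whole-sample mirror boundaries: truncated geometric
  // sum when the horizon fits, otherwise the exact closed form
  int horizon = (int)std::ceil(std::log(1e-14) / std::log(std::fabs(z)));
  double sum;
  if (horizon < n) {
    sum = c[0];
    double zk = z;
    for (int k = 1; k < horizon; ++k) { sum += zk * c[k * stride]; zk *= z; }
  } else {
    double zn = std::pow(z, (double)(n - 1));
    sum = c[0] + zn * c[(n - 1) * stride];
    zn = zn * zn / z;
    double z1 = z;
    for (int k = 1; k <= n - 2; ++k) {
      sum += (z1 + zn) * c[k * stride];
      z1 *= z;
      zn /= z;
    }
    sum /= (1.0 - std::pow(z, (double)(2 * n - 2)));
  }
  c[0] = sum;
  for (int i = 1; i < n; ++i) c[i * stride] += z * c[(i - 1) * stride];
  // anticausal init (mirror boundary)
  c[(n - 1) * stride] = (z / (z * z - 1.0)) *
      (z * c[(n - 2) * stride] + c[(n - 1) * stride]);
  for (int i = n - 2; i >= 0; --i)
    c[i * stride] = z * (c[(i + 1) * stride] - c[i * stride]);
}

static inline int mirror(int i, int n) {
  if (n == 1) return 0;
  int p = 2 * n - 2;
  i = std::abs(i) % p;
  return (i < n) ? i : p - i;
}

static inline void bspline_w(double f, double w[4]) {
  double f2 = f * f, f3 = f2 * f;
  w[0] = (1.0 - 3.0 * f + 3.0 * f2 - f3) / 6.0;
  w[1] = (4.0 - 6.0 * f2 + 3.0 * f3) / 6.0;
  w[2] = (1.0 + 3.0 * f + 3.0 * f2 - 3.0 * f3) / 6.0;
  w[3] = f3 / 6.0;
}

// [[Rcpp::export]]
NumericVector cpp_resample_bspline(NumericVector values, IntegerVector dims,
                                   NumericVector t_x, NumericVector t_y,
                                   NumericVector t_z) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<double> c(values.begin(), values.end());
  // prefilter along each axis
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      prefilter_line(&c[(size_t)nx * (y + (size_t)ny * z)], nx, 1);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x)
      prefilter_line(&c[x + (size_t)nx * ny * z], ny, nx);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x)
      prefilter_line(&c[x + (size_t)nx * y], nz, nx * ny);
  int mx = t_x.size(), my = t_y.size(), mz = t_z.size();
  NumericVector out((R_xlen_t)mx * my * mz);
  std::vector<double> wx(4 * mx), wy(4 * my), wz(4 * mz);
  std::vector<int> ix(4 * mx), iy(4 * my), iz(4 * mz);
  auto prep = [&](NumericVector t, int m, int n, std::vector<double>& w,
                  std::vector<int>& id) {
    for (int k = 0; k < m; ++k) {
      double tt = t[k];
      int i0 = (int)std::floor(tt);
      double f = tt - i0;
      double ww[4]; bspline_w(f, ww);
      for (int j = 0; j < 4; ++j) {
        w[4 * k + j] = ww[j];
        id[4 * k + j] = mirror(i0 - 1 + j, n);
      }
    }
  };
  prep(t_x, mx, nx, wx, ix);
  prep(t_y, my, ny, wy, iy);
  prep(t_z, mz, nz, wz, iz);
  for (int z = 0; z < mz; ++z)
    for (int y = 0; y < my; ++y)
      for (int x = 0; x < mx; ++x) {
        double acc = 0.0;
        for (int c3 = 0; c3 < 4; ++c3) {
          double az = 0.0;
          for (int c2 = 0; c2 < 4; ++c2) {
            double ay = 0.0;
            for (int c1 = 0; c1 < 4; ++c1)
              ay += wx[4 * x + c1] *
                    c[ix[4 * x + c1] + (size_t)nx * (iy[4 * y + c2] + (size_t)ny * iz[4 * z + c3])];
            az += wy[4 * y + c2] * ay;
          }
          acc += wz[4 * z + c3] * az;
        }
        out[x + (size_t)mx * (y + (size_t)my * z)] = acc;
      }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_resample_nearest(NumericVector values, IntegerVector dims,
                                   NumericVector t_x, NumericVector t_y,
                                   NumericVector t_z) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int mx = t_x.size(), my = t_y.size(), mz = t_z.size();
  NumericVector out((R_xlen_t)mx * my * mz);
  auto clampi = [](int i, int n) { return i < 0 ? 0 : (i >= n ? n - 1 : i); };
  for (int z = 0; z < mz; ++z) {
    int zi = clampi((int)std::floor(t_z[z] + 0.5), nz);
    for (int y = 0; y < my; ++y) {
      int yi = clampi((int)std::floor(t_y[y] + 0.5), ny);
      for (int x = 0; x < mx; ++x) {
        int xi = clampi((int)std::floor(t_x[x] + 0.5), nx);
        out[x + (size_t)mx * (y + (size_t)my * z)] =
            values[xi + (size_t)nx * (yi + (size_t)ny * zi)];
      }
    }
  }
  return out;
}

// breadth-first nearest-value fill of NA voxels from the defined region
// (6-neighbourhood); leaves the defined voxels untouched
// [[Rcpp::export]]
NumericVector cpp_fill_nearest(NumericVector values, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  NumericVector out(clone(values));
  std::queue<size_t> q;
  std::vector<char> seen(n, 0);
  for (size_t i = 0; i < n; ++i)
    if (!NumericVector::is_na(out[i])) { seen[i] = 1; q.push(i); }
  const int OFF[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  while (!q.empty()) {
    size_t i = q.front(); q.pop();
    int z = (int)(i / ((size_t)nx * ny)), y = (int)((i / nx) % ny), x = (int)(i % nx);
    for (int k = 0; k < 6; ++k) {
      int x2 = x + OFF[k][0], y2 = y + OFF[k][1], z2 = z + OFF[k][2];
      if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz) continue;
      size_t j = x2 + (size_t)nx * (y2 + (size_t)ny * z2);
      if (!seen[j]) { seen[j] = 1; out[j] = out[i]; q.push(j); }
    }
  }
  return out;
}
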