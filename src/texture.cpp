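// Sliding-window engine for voxel-wise radiomic feature maps.
//
// Levels are 1-based global gray levels (0 marks voxels excluded from the
// region, i.e. outside the ROI or outside the image). Texture matrices use
// distance-1 neighbourhoods over the 13 unique 3D directions; GLCM and GLRLM
// are accumulated over directions before feature computation, GLDM uses a
// dependence threshold of 0, NGTDM the 26-neighbourhood.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const int NDIR = 13;
static const int DIRS[NDIR][3] = {
  {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
  {1, 1, 0}, {1, -1, 0}, {1, 0, 1}, {1, 0, -1}, {0, 1, 1}, {0, 1, -1},
  {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {1, -1, -1}
};

static const double EPS = 2.220446049250313e-16;

static inline double log2s(double x) { return std::log(x) / std::log(2.0); }

struct Workspace {
  int L;            // number of global gray levels
  int maxlen;       // longest possible run
  std::vector<double> glcm;    // L x L counts
  std::vector<double> glrlm;   // L x maxlen counts
  std::vector<double> gldm;    // L x 27 counts
  std::vector<double> ngt_s;   // L
  std::vector<double> ngt_n;   // L
  std::vector<double> hist;    // L
  std::vector<double> raws;    // raw values in region
  std::vector<int> lev;        // local cube levels
  Workspace(int L_, int maxlen_) : L(L_), maxlen(maxlen_) {
    glcm.resize((size_t)L * L);
    glrlm.resize((size_t)L * maxlen);
    gldm.resize((size_t)L * 27);
    ngt_s.resize(L);
    ngt_n.resize(L);
    hist.resize(L);
  }
};

static inline int cidx(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// ---- matrix builders over a level cube (0 = excluded) ----

static void build_glcm(const std::vector<int>& lev, int nx, int ny, int nz,
                       std::vector<double>& glcm, int L) {
  std::fill(glcm.begin(), glcm.end(), 0.0);
  for (int d = 0; d < NDIR; ++d) {
    int dx = DIRS[d][0], dy = DIRS[d][1], dz = DIRS[d][2];
    for (int z = 0; z < nz; ++z) {
      int z2 = z + dz; if (z2 < 0 || z2 >= nz) continue;
      for (int y = 0; y < ny; ++y) {
        int y2 = y + dy; if (y2 < 0 || y2 >= ny) continue;
        for (int x = 0; x < nx; ++x) {
          int x2 = x + dx; if (x2 < 0 || x2 >= nx) continue;
          int a = lev[cidx(x, y, z, nx, ny)];
          if (!a) continue;
          int b = lev[cidx(x2, y2, z2, nx, ny)];
          if (!b) continue;
          glcm[(size_t)(a - 1) * L + (b - 1)] += 1.0;
          glcm[(size_t)(b - 1) * L + (a - 1)] += 1.0;
        }
      }
    }
  }
}

static void build_glrlm(const std::vector<int>& lev, int nx, int ny, int nz,
                        std::vector<double>& glrlm, int L, int maxlen) {
  std::fill(glrlm.begin(), glrlm.end(), 0.0);
  for (int d = 0; d < NDIR; ++d) {
    int dx = DIRS[d][0], dy = DIRS[d][1], dz = DIRS[d][2];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int a = lev[cidx(x, y, z, nx, ny)];
          if (!a) continue;
          // start of a maximal run? predecessor must be absent or different
          int px = x - dx, py = y - dy, pz = z - dz;
          if (px >= 0 && px < nx && py >= 0 && py < ny && pz >= 0 && pz < nz &&
              lev[cidx(px, py, pz, nx, ny)] == a)
            continue;
          int len = 1;
          int qx = x + dx, qy = y + dy, qz = z + dz;
          while (qx >= 0 && qx < nx && qy >= 0 && qy < ny && qz >= 0 && qz < nz &&
                 lev[cidx(qx, qy, qz, nx, ny)] == a) {
            ++len; qx += dx; qy += dy; qz += dz;
          }
          if (len > maxlen) len = maxlen;
          glrlm[(size_t)(a - 1) * maxlen + (len - 1)] += 1.0;
        }
  }
}

static void build_gldm_ngtdm(const std::vector<int>& lev, int nx, int ny, int nz,
                             std::vector<double>& gldm,
                             std::vector<double>& ngt_s, std::vector<double>& ngt_n,
                             int L) {
  std::fill(gldm.begin(), gldm.end(), 0.0);
  std::fill(ngt_s.begin(), ngt_s.end(), 0.0);
  std::fill(ngt_n.begin(), ngt_n.end(), 0.0);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int a = lev[cidx(x, y, z, nx, ny)];
        if (!a) continue;
        int dep = 0, nnb = 0;
        double sum = 0.0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              int x2 = x + dx, y2 = y + dy, z2 = z + dz;
              if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
                continue;
              int b = lev[cidx(x2, y2, z2, nx, ny)];
              if (!b) continue;
              ++nnb; sum += b;
              if (b == a) ++dep;  // alpha = 0
            }
        // dependence size includes the centre voxel itself (minimum 1)
        gldm[(size_t)(a - 1) * 27 + dep] += 1.0;
        if (nnb > 0) {
          ngt_s[a - 1] += std::fabs((double)a - sum / nnb);
          ngt_n[a - 1] += 1.0;
        }
      }
}

// ---- feature computation ----

// first-order: 18 values appended to out
static void firstorder_features(std::vector<double>& v,
                                const std::vector<double>& hist, int L,
                                double voxvol, double* out) {
  size_t n = v.size();
  std::sort(v.begin(), v.end());
  double sum = 0.0, sum2 = 0.0;
  for (size_t i = 0; i < n; ++i) { sum += v[i]; sum2 += v[i] * v[i]; }
  double mean = sum / n;
  double m2 = 0.0, m3 = 0.0, m4 = 0.0, mad = 0.0;
  for (size_t i = 0; i < n; ++i) {
    double d = v[i] - mean;
    m2 += d * d; m3 += d * d * d; m4 += d * d * d * d;
    mad += std::fabs(d);
  }
  m2 /= n; m3 /= n; m4 /= n; mad /= n;
  auto pct = [&](double p) {  // linear interpolation, R type 7 / numpy default
    if (n == 1) return v[0];
    double h = (n - 1) * p;
    size_t lo = (size_t)std::floor(h);
    if (lo >= n - 1) return v[n - 1];
    return v[lo] + (h - lo) * (v[lo + 1] - v[lo]);
  };
  double p10 = pct(0.10), p90 = pct(0.90);
  // robust MAD: voxels within [P10, P90]
  double rsum = 0.0; size_t rn = 0;
  for (size_t i = 0; i < n; ++i)
    if (v[i] >= p10 && v[i] <= p90) { rsum += v[i]; ++rn; }
  double rmad = 0.0;
  if (rn > 0) {
    double rmean = rsum / rn;
    for (size_t i = 0; i < n; ++i)
      if (v[i] >= p10 && v[i] <= p90) rmad += std::fabs(v[i] - rmean);
    rmad /= rn;
  }
  double ntot = 0.0, ent = 0.0, unif = 0.0;
  for (int l = 0; l < L; ++l) ntot += hist[l];
  for (int l = 0; l < L; ++l)
    if (hist[l] > 0) {
      double p = hist[l] / ntot;
      ent -= p * log2s(p);
      unif += p * p;
    }
  double sd = std::sqrt(m2);
  int k = 0;
  out[k++] = sum2;                              // Energy
  out[k++] = voxvol * sum2;                     // TotalEnergy
  out[k++] = ent;                               // Entropy
  out[k++] = v[0];                              // Minimum
  out[k++] = p10;                               // 10Percentile
  out[k++] = p90;                               // 90Percentile
  out[k++] = v[n - 1];                          // Maximum
  out[k++] = mean;                              // Mean
  out[k++] = pct(0.5);                          // Median
  out[k++] = pct(0.75) - pct(0.25);             // InterquartileRange
  out[k++] = v[n - 1] - v[0];                   // Range
  out[k++] = mad;                               // MeanAbsoluteDeviation
  out[k++] = rmad;                              // RobustMeanAbsoluteDeviation
  out[k++] = std::sqrt(sum2 / n);               // RootMeanSquared
  out[k++] = (sd > 0) ? m3 / (m2 * sd) : 0.0;   // Skewness
  out[k++] = (m2 > 0) ? m4 / (m2 * m2) : 0.0;   // Kurtosis (not excess)
  out[k++] = m2;                                // Variance (population)
  out[k++] = unif;                              // Uniformity
}

// GLCM: 24 values appended to out
static void glcm_features(const std::vector<double>& glcm, int L, double* out) {
  double tot = 0.0;
  for (size_t i = 0; i < glcm.size(); ++i) tot += glcm[i];
  if (tot <= 0) {  // no voxel pairs at distance 1: define all features as 0
    for (int k = 0; k < 24; ++k) out[k] = 0.0;
    return;
  }
  // present levels (nonzero marginal)
  std::vector<int> levels;
  std::vector<double> px(L, 0.0);
  for (int i = 0; i < L; ++i) {
    double m = 0.0;
    for (int j = 0; j < L; ++j) m += glcm[(size_t)i * L + j];
    px[i] = m / tot;
    if (m > 0) levels.push_back(i);
  }
  int Ng = (int)levels.size();
  double mux = 0.0;
  for (int a = 0; a < Ng; ++a) mux += px[levels[a]] * (levels[a] + 1);
  double muy = mux;  // symmetric
  double sx2 = 0.0;
  for (int a = 0; a < Ng; ++a) {
    double d = (levels[a] + 1) - mux;
    sx2 += px[levels[a]] * d * d;
  }
  double autoc = 0, cp = 0, cs = 0, ct = 0, contrast = 0, corr_num = 0;
  double id = 0, idm = 0, idmn = 0, idn = 0, invvar = 0;
  double je = 0, jent = 0, maxp = 0, ssq = 0;
  double hxy = 0, hxy1 = 0;
  std::vector<double> pdiff(L, 0.0), psum(2 * L, 0.0);
  for (int a = 0; a < Ng; ++a) {
    int i = levels[a]; double gi = i + 1;
    for (int b = 0; b < Ng; ++b) {
      int j = levels[b]; double gj = j + 1;
      double p = glcm[(size_t)i * L + j] / tot;
      if (p <= 0) continue;
      double dd = gi - gj, ad = std::fabs(dd);
      autoc += p * gi * gj;
      double cbase = gi + gj - mux - muy;
      ct += p * cbase * cbase;
      cs += p * cbase * cbase * cbase;
      cp += p * cbase * cbase * cbase * cbase;
      contrast += p * dd * dd;
      corr_num += p * gi * gj;
      id += p / (1.0 + ad);
      idm += p / (1.0 + dd * dd);
      idmn += p / (1.0 + dd * dd / ((double)Ng * Ng));
      idn += p / (1.0 + ad / (double)Ng);
      if (i != j) invvar += p / (dd * dd);
      je += p * p;
      jent -= p * log2s(p + EPS);
      if (p > maxp) maxp = p;
      double dmu = gi - mux;
      ssq += p * dmu * dmu;
      hxy -= p * log2s(p + EPS);
      hxy1 -= p * log2s(px[i] * px[j] + EPS);
      pdiff[(int)ad] += p;          // |i-j| in 0..L-1
      psum[i + j] += p;             // gi+gj = i+j+2, index by i+j
    }
  }
  double corr = 1.0;
  if (sx2 > 0) corr = (corr_num - mux * muy) / sx2;
  double da = 0, dent = 0, dvar = 0;
  for (int kk = 0; kk < L; ++kk)
    if (pdiff[kk] > 0) { da += kk * pdiff[kk]; dent -= pdiff[kk] * log2s(pdiff[kk] + EPS); }
  for (int kk = 0; kk < L; ++kk)
    if (pdiff[kk] > 0) { double d = kk - da; dvar += pdiff[kk] * d * d; }
  double sa = 0, sent = 0;
  for (int kk = 0; kk < 2 * L; ++kk)
    if (psum[kk] > 0) { sa += (kk + 2) * psum[kk]; sent -= psum[kk] * log2s(psum[kk] + EPS); }
  double hx = 0, hxy2 = 0;
  for (int a = 0; a < Ng; ++a) {
    double p = px[levels[a]];
    if (p > 0) hx -= p * log2s(p + EPS);
    for (int b = 0; b < Ng; ++b) {
      double q = px[levels[a]] * px[levels[b]];
      if (q > 0) hxy2 -= q * log2s(q + EPS);
    }
  }
  double imc1 = 0.0, imc2 = 0.0;
  double hmax = hx;  // HX == HY by symmetry
  if (hmax > 0) imc1 = (hxy - hxy1) / hmax;
  double e2 = -2.0 * (hxy2 - hxy);
  if (e2 < 0) {
    double t = 1.0 - std::exp(e2);
    imc2 = (t > 0) ? std::sqrt(t) : 0.0;
  }
  // MCC: sqrt of second-largest eigenvalue of Q(i,j) = sum_k p(i,k)p(j,k)/(px_i py_k)
  double mcc = 1.0;
  if (Ng > 1) {
    arma::mat Q(Ng, Ng, arma::fill::zeros);
    for (int a = 0; a < Ng; ++a)
      for (int b = 0; b < Ng; ++b) {
        double s = 0.0;
        for (int c = 0; c < Ng; ++c) {
          double pik = glcm[(size_t)levels[a] * L + levels[c]] / tot;
          double pjk = glcm[(size_t)levels[b] * L + levels[c]] / tot;
          double den = px[levels[a]] * px[levels[c]];
          if (den > 0) s += pik * pjk / den;
        }
        Q(a, b) = s;
      }
    arma::cx_vec ev;
    bool ok = arma::eig_gen(ev, Q);
    if (ok) {
      arma::vec re = arma::sort(arma::real(ev), "descend");
      double second = re(1);
      if (second < 0) second = 0;
      if (second > 1) second = 1;
      mcc = std::sqrt(second);
    }
  }
  int k = 0;
  out[k++] = autoc;      // Autocorrelation
  out[k++] = cp;         // ClusterProminence
  out[k++] = cs;         // ClusterShade
  out[k++] = ct;         // ClusterTendency
  out[k++] = contrast;   // Contrast
  out[k++] = corr;       // Correlation
  out[k++] = da;         // DifferenceAverage
  out[k++] = dent;       // DifferenceEntropy
  out[k++] = dvar;       // DifferenceVariance
  out[k++] = id;         // Id
  out[k++] = idm;        // Idm
  out[k++] = idmn;       // Idmn
  out[k++] = idn;        // Idn
  out[k++] = imc1;       // Imc1
  out[k++] = imc2;       // Imc2
  out[k++] = invvar;     // InverseVariance
  out[k++] = mux;        // JointAverage
  out[k++] = je;         // JointEnergy
  out[k++] = jent;       // JointEntropy
  out[k++] = maxp;       // MaximumProbability
  out[k++] = mcc;        // MCC
  out[k++] = sa;         // SumAverage
  out[k++] = sent;       // SumEntropy
  out[k++] = ssq;        // SumSquares
}

// GLDM: 14 values
static void gldm_features(const std::vector<double>& gldm, int L, double* out) {
  double Nz = 0.0;
  for (size_t i = 0; i < gldm.size(); ++i) Nz += gldm[i];
  if (Nz <= 0) { for (int k = 0; k < 14; ++k) out[k] = 0.0; return; }
  double sde = 0, lde = 0, gln = 0, dn = 0, glv = 0, dv = 0, de = 0;
  double lgle = 0, hgle = 0, sdlgle = 0, sdhgle = 0, ldlgle = 0, ldhgle = 0;
  double mu_i = 0, mu_j = 0;
  for (int i = 0; i < L; ++i) {
    double gi = i + 1, rowsum = 0.0;
    for (int d = 0; d < 27; ++d) {
      double c = gldm[(size_t)i * 27 + d];
      if (c <= 0) continue;
      double j = d + 1;  // dependence size (centre voxel included)
      double p = c / Nz;
      rowsum += c;
      sde += c / (j * j); lde += c * j * j;
      lgle += c / (gi * gi); hgle += c * gi * gi;
      sdlgle += c / (gi * gi * j * j); sdhgle += c * gi * gi / (j * j);
      ldlgle += c * j * j / (gi * gi); ldhgle += c * gi * gi * j * j;
      de -= p * log2s(p + EPS);
      mu_i += p * gi; mu_j += p * j;
    }
    gln += rowsum * rowsum;
  }
  for (int d = 0; d < 27; ++d) {
    double colsum = 0.0;
    for (int i = 0; i < L; ++i) colsum += gldm[(size_t)i * 27 + d];
    dn += colsum * colsum;
  }
  for (int i = 0; i < L; ++i)
    for (int d = 0; d < 27; ++d) {
      double c = gldm[(size_t)i * 27 + d];
      if (c <= 0) continue;
      double p = c / Nz, gi = i + 1, j = d + 1;
      glv += p * (gi - mu_i) * (gi - mu_i);
      dv += p * (j - mu_j) * (j - mu_j);
    }
  int k = 0;
  out[k++] = sde / Nz;        // SmallDependenceEmphasis
  out[k++] = lde / Nz;        // LargeDependenceEmphasis
  out[k++] = gln / Nz;        // GrayLevelNonUniformity
  out[k++] = dn / Nz;         // DependenceNonUniformity
  out[k++] = dn / (Nz * Nz);  // DependenceNonUniformityNormalized
  out[k++] = glv;             // GrayLevelVariance
  out[k++] = dv;              // DependenceVariance
  out[k++] = de;              // DependenceEntropy
  out[k++] = lgle / Nz;       // LowGrayLevelEmphasis
  out[k++] = hgle / Nz;       // HighGrayLevelEmphasis
  out[k++] = sdlgle / Nz;     // SmallDependenceLowGrayLevelEmphasis
  out[k++] = sdhgle / Nz;     // SmallDependenceHighGrayLevelEmphasis
  out[k++] = ldlgle / Nz;     // LargeDependenceLowGrayLevelEmphasis
  out[k++] = ldhgle / Nz;     // LargeDependenceHighGrayLevelEmphasis
}

// GLRLM: 16 values; Np = number of region voxels (for RunPercentage over 13 dirs)
static void glrlm_features(const std::vector<double>& glrlm, int L, int maxlen,
                           double Np, double* out) {
  double Nr = 0.0;
  for (size_t i = 0; i < glrlm.size(); ++i) Nr += glrlm[i];
  if (Nr <= 0) { for (int k = 0; k < 16; ++k) out[k] = 0.0; return; }
  double sre = 0, lre = 0, gln = 0, rln = 0, glv = 0, rv = 0, rent = 0;
  double lglre = 0, hglre = 0, srlgle = 0, srhgle = 0, lrlgle = 0, lrhgle = 0;
  double mu_i = 0, mu_l = 0;
  for (int i = 0; i < L; ++i) {
    double gi = i + 1, rowsum = 0.0;
    for (int l = 0; l < maxlen; ++l) {
      double c = glrlm[(size_t)i * maxlen + l];
      if (c <= 0) continue;
      double rl = l + 1, p = c / Nr;
      rowsum += c;
      sre += c / (rl * rl); lre += c * rl * rl;
      lglre += c / (gi * gi); hglre += c * gi * gi;
      srlgle += c / (gi * gi * rl * rl); srhgle += c * gi * gi / (rl * rl);
      lrlgle += c * rl * rl / (gi * gi); lrhgle += c * gi * gi * rl * rl;
      rent -= p * log2s(p + EPS);
      mu_i += p * gi; mu_l += p * rl;
    }
    gln += rowsum * rowsum;
  }
  for (int l = 0; l < maxlen; ++l) {
    double colsum = 0.0;
    for (int i = 0; i < L; ++i) colsum += glrlm[(size_t)i * maxlen + l];
    rln += colsum * colsum;
  }
  for (int i = 0; i < L; ++i)
    for (int l = 0; l < maxlen; ++l) {
      double c = glrlm[(size_t)i * maxlen + l];
      if (c <= 0) continue;
      double p = c / Nr, gi = i + 1, rl = l + 1;
      glv += p * (gi - mu_i) * (gi - mu_i);
      rv += p * (rl - mu_l) * (rl - mu_l);
    }
  int k = 0;
  out[k++] = sre / Nr;          // ShortRunEmphasis
  out[k++] = lre / Nr;          // LongRunEmphasis
  out[k++] = gln / Nr;          // GrayLevelNonUniformity
  out[k++] = gln / (Nr * Nr);   // GrayLevelNonUniformityNormalized
  out[k++] = rln / Nr;          // RunLengthNonUniformity
  out[k++] = rln / (Nr * Nr);   // RunLengthNonUniformityNormalized
  out[k++] = Nr / (Np * NDIR);  // RunPercentage
  out[k++] = glv;               // GrayLevelVariance
  out[k++] = rv;                // RunVariance
  out[k++] = rent;              // RunEntropy
  out[k++] = lglre / Nr;        // LowGrayLevelRunEmphasis
  out[k++] = hglre / Nr;        // HighGrayLevelRunEmphasis
  out[k++] = srlgle / Nr;       // ShortRunLowGrayLevelEmphasis
  out[k++] = srhgle / Nr;       // ShortRunHighGrayLevelEmphasis
  out[k++] = lrlgle / Nr;       // LongRunLowGrayLevelEmphasis
  out[k++] = lrhgle / Nr;       // LongRunHighGrayLevelEmphasis
}

// NGTDM: 5 values
static void ngtdm_features(const std::vector<double>& s, const std::vector<double>& n,
                           int L, double* out) {
  double Nvp = 0.0;
  for (int i = 0; i < L; ++i) Nvp += n[i];
  if (Nvp <= 0) { for (int k = 0; k < 5; ++k) out[k] = 0.0; return; }
  std::vector<int> lv;
  for (int i = 0; i < L; ++i) if (n[i] > 0) lv.push_back(i);
  int Ngp = (int)lv.size();
  double ssum = 0.0, ps_sum = 0.0;
  for (int i = 0; i < L; ++i) ssum += s[i];
  for (int a = 0; a < Ngp; ++a) ps_sum += (n[lv[a]] / Nvp) * s[lv[a]];
  double coarse = (ps_sum > 0) ? 1.0 / ps_sum : 1e6;
  double contrast = 0.0, busy_den = 0.0, cmplx = 0.0, str_num = 0.0;
  for (int a = 0; a < Ngp; ++a) {
    double pi = n[lv[a]] / Nvp, gi = lv[a] + 1;
    for (int b = 0; b < Ngp; ++b) {
      double pj = n[lv[b]] / Nvp, gj = lv[b] + 1;
      contrast += pi * pj * (gi - gj) * (gi - gj);
      busy_den += std::fabs(gi * pi - gj * pj);
      cmplx += std::fabs(gi - gj) * (pi * s[lv[a]] + pj * s[lv[b]]) / (pi + pj);
      str_num += (pi + pj) * (gi - gj) * (gi - gj);
    }
  }
  double contr = 0.0;
  if (Ngp > 1) contr = contrast / ((double)Ngp * (Ngp - 1)) * (ssum / Nvp);
  double busy = (Ngp > 1 && busy_den > 0) ? ps_sum / busy_den : 0.0;
  cmplx /= Nvp;
  double strength = (ssum > 0) ? str_num / ssum : 0.0;
  out[0] = coarse; out[1] = contr; out[2] = busy; out[3] = cmplx; out[4] = strength;
}

// full 77-feature vector for one region (level cube + raw values)
static void compute77(Workspace& ws, int nx, int ny, int nz,
                      double voxvol, double* out) {
  int L = ws.L;
  std::fill(ws.hist.begin(), ws.hist.end(), 0.0);
  double npv = 0.0;
  for (size_t i = 0; i < ws.lev.size(); ++i)
    if (ws.lev[i] > 0) { ws.hist[ws.lev[i] - 1] += 1.0; npv += 1.0; }
  firstorder_features(ws.raws, ws.hist, L, voxvol, out);
  build_glcm(ws.lev, nx, ny, nz, ws.glcm, L);
  glcm_features(ws.glcm, L, out + 18);
  build_gldm_ngtdm(ws.lev, nx, ny, nz, ws.gldm, ws.ngt_s, ws.ngt_n, L);
  gldm_features(ws.gldm, L, out + 42);
  build_glrlm(ws.lev, nx, ny, nz, ws.glrlm, L, ws.maxlen);
  glrlm_features(ws.glrlm, L, ws.maxlen, npv, out + 56);
  ngtdm_features(ws.ngt_s, ws.ngt_n, L, out + 72);
}

// [[Rcpp::export]]
List cpp_extract_maps(IntegerVector lev, NumericVector raw, LogicalVector roi,
                      LogicalVector centers, IntegerVector dims, int window,
                      int n_levels, double voxel_volume) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int h = window / 2;
  std::vector<int> roi_idx;
  for (int i = 0; i < lev.size(); ++i)
    if (centers[i] == TRUE) roi_idx.push_back(i);
  int nvox = (int)roi_idx.size();
  NumericMatrix vals(nvox, 77);
  IntegerVector n_in(nvox);
  Workspace ws(n_levels, window);
  ws.lev.assign((size_t)window * window * window, 0);
  for (int r = 0; r < nvox; ++r) {
    int idx = roi_idx[r];
    int cz = idx / (nx * ny), cy = (idx / nx) % ny, cx = idx % nx;
    std::fill(ws.lev.begin(), ws.lev.end(), 0);
    ws.raws.clear();
    int cnt = 0;
    for (int dz = -h; dz <= h; ++dz) {
      int z = cz + dz; if (z < 0 || z >= nz) continue;
      for (int dy = -h; dy <= h; ++dy) {
        int y = cy + dy; if (y < 0 || y >= ny) continue;
        for (int dx = -h; dx <= h; ++dx) {
          int x = cx + dx; if (x < 0 || x >= nx) continue;
          int g = cidx(x, y, z, nx, ny);
          if (roi[g] != TRUE) continue;
          int l = lev[g];
          if (l == NA_INTEGER || l <= 0) continue;
          ws.lev[cidx(dx + h, dy + h, dz + h, window, window)] = l;
          ws.raws.push_back(raw[g]);
          ++cnt;
        }
      }
    }
    n_in[r] = cnt;
    if (cnt < 2) {
      for (int f = 0; f < 77; ++f) vals(r, f) = NA_REAL;
    } else {
      double out[77];
      compute77(ws, window, window, window, voxel_volume, out);
      for (int f = 0; f < 77; ++f) vals(r, f) = out[f];
    }
  }
  IntegerVector ridx(nvox);
  for (int r = 0; r < nvox; ++r) ridx[r] = roi_idx[r] + 1;
  return List::create(_["values"] = vals, _["index"] = ridx,
                      _["n_in_window"] = n_in);
}

// [[Rcpp::export]]
NumericVector cpp_region_features(IntegerVector lev, NumericVector raw,
                                  LogicalVector mask, IntegerVector dims,
                                  int n_levels, double voxel_volume) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  Workspace ws(n_levels, std::max(nx, std::max(ny, nz)));
  ws.lev.assign((size_t)nx * ny * nz, 0);
  ws.raws.clear();
  for (int i = 0; i < lev.size(); ++i)
    if (mask[i] == TRUE && lev[i] != NA_INTEGER && lev[i] > 0) {
      ws.lev[i] = lev[i];
      ws.raws.push_back(raw[i]);
    }
  if ((int)ws.raws.size() < 2) stop("region must contain at least 2 voxels");
  NumericVector out(77);
  double buf[77];
  compute77(ws, nx, ny, nz, voxel_volume, buf);
  for (int f = 0; f < 77; ++f) out[f] = buf[f];
  return out;
}

// [[Rcpp::export]]
List cpp_texture_matrices(IntegerVector lev, LogicalVector mask,
                          IntegerVector dims, int n_levels) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int maxlen = std::max(nx, std::max(ny, nz));
  std::vector<int> cube((size_t)nx * ny * nz, 0);
  double npv = 0.0;
  for (int i = 0; i < lev.size(); ++i)
    if (mask[i] == TRUE && lev[i] != NA_INTEGER && lev[i] > 0) {
      cube[i] = lev[i];
      npv += 1.0;
    }
  if (npv < 2) stop("mask must contain at least 2 voxels");
  int L = n_levels;
  std::vector<double> glcm((size_t)L * L), glrlm((size_t)L * maxlen),
      gldm((size_t)L * 27), s(L), n(L);
  build_glcm(cube, nx, ny, nz, glcm, L);
  build_glrlm(cube, nx, ny, nz, glrlm, L, maxlen);
  build_gldm_ngtdm(cube, nx, ny, nz, gldm, s, n, L);
  NumericMatrix Mglcm(L, L), Mglrlm(L, maxlen), Mgldm(L, 27);
  for (int i = 0; i < L; ++i) {
    for (int j = 0; j < L; ++j) Mglcm(i, j) = glcm[(size_t)i * L + j];
    for (int l = 0; l < maxlen; ++l) Mglrlm(i, l) = glrlm[(size_t)i * maxlen + l];
    for (int d = 0; d < 27; ++d) Mgldm(i, d) = gldm[(size_t)i * 27 + d];
  }
  NumericVector Vs(L), Vn(L);
  for (int i = 0; i < L; ++i) { Vs[i] = s[i]; Vn[i] = n[i]; }
  return List::create(_["glcm"] = Mglcm, _["glrlm"] = Mglrlm,
                      _["gldm"] = Mgldm,
                      _["ngtdm"] = List::create(_["s"] = Vs, _["n"] = Vn));
}
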