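// Compiled kernels: dynamic-speckle position simulator, generalized
// differences, separable 3D Gaussian / 2D boxcar filters, 3D labeling.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: xoshiro256++ seeded through splitmix64. Self-contained so simulated
// scans are bit-reproducible from an integer seed across platforms and R
// versions, independently of R's global RNG state.
struct Xo {
  uint64_t s[4];
  explicit Xo(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; i++) {
      x += 0x9E3779B97F4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
};

// Standard normal via inverse-CDF lookup (4096-node table, linear
// interpolation; exact qnorm in the extreme tails). Table error is < 1e-6 in
// the central range, far below the 8-bit quantization it feeds.
struct NormTab {
  std::vector<double> q;
  NormTab() : q(4097) {
    for (int i = 1; i < 4096; i++)
      q[i] = R::qnorm((double)i / 4096.0, 0.0, 1.0, 1, 0);
    q[0] = q[1]; q[4096] = q[4095];
  }
};
static NormTab* normtab_ptr = 0;
static inline const double* normtab() {
  if (!normtab_ptr) normtab_ptr = new NormTab();
  return normtab_ptr->q.data();
}
static inline double rnorm_fast(Xo& g, const double* q) {
  double u = g.unif();
  double t = u * 4096.0;
  int i = (int)t;
  if (i < 1 || i >= 4095) {
    if (u <= 0) u = 2.8e-17;
    if (u >= 1) u = 1.0 - 2.8e-17;
    return R::qnorm(u, 0.0, 1.0, 1, 0);
  }
  double f = t - i;
  return q[i] * (1.0 - f) + q[i + 1] * f;
}

// L1-normalized Gaussian kernel (smoothing); radius ceil(4*sigma).
static std::vector<double> gauss_l1(double sigma) {
  if (sigma <= 0) return std::vector<double>(1, 1.0);
  int r = std::max(1, (int)std::ceil(4.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; i++) {
    k[i + r] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (size_t i = 0; i < k.size(); i++) k[i] /= s;
  return k;
}
// L2-normalized kernel: filtering unit-variance white noise preserves the
// per-pixel variance (used for speckle grain and clutter texture).
static std::vector<double> gauss_l2(double sigma) {
  std::vector<double> k = gauss_l1(sigma);
  double s2 = 0;
  for (size_t i = 0; i < k.size(); i++) s2 += k[i] * k[i];
  s2 = std::sqrt(s2);
  for (size_t i = 0; i < k.size(); i++) k[i] /= s2;
  return k;
}

// Circular (wrap) separable convolution on an nx-by-ny column-major grid,
// line-buffered so the inner loop is a straight dot product. Wrap keeps the
// filtered field exactly stationary, borders included.
static void conv2_circ(std::vector<double>& a, int nx, int ny,
                       const std::vector<double>& k) {
  int r = ((int)k.size() - 1) / 2;
  if (r == 0) return;
  int kn = 2 * r + 1;
  std::vector<double> tmp(a.size());
  std::vector<double> buf(std::max(nx, ny) + 2 * r);
  for (int j = 0; j < ny; j++) {          // along x (rows)
    const double* col = &a[(size_t)j * nx];
    for (int i = -r; i < nx + r; i++) {
      int ii = i % nx; if (ii < 0) ii += nx;
      buf[i + r] = col[ii];
    }
    double* out = &tmp[(size_t)j * nx];
    for (int i = 0; i < nx; i++) {
      double acc = 0;
      const double* b = &buf[i];
      for (int d = 0; d < kn; d++) acc += b[d] * k[d];
      out[i] = acc;
    }
  }
  for (int i = 0; i < nx; i++) {          // along y (cols)
    for (int j = -r; j < ny + r; j++) {
      int jj = j % ny; if (jj < 0) jj += ny;
      buf[j + r] = tmp[(size_t)jj * nx + i];
    }
    for (int j = 0; j < ny; j++) {
      double acc = 0;
      const double* b = &buf[j];
      for (int d = 0; d < kn; d++) acc += b[d] * k[d];
      a[(size_t)j * nx + i] = acc;
    }
  }
}

// All-pairs sum of |x_i - x_j| from a value histogram on [lo, hi]:
// the sorted-order identity sum_k (2k - 1 - N) x_(k).
static inline double allpairs_from_hist(const int* h, int lo, int hi, int n) {
  long long acc = 0, cum = 0;
  for (int v = lo; v <= hi; v++) {
    int c = h[v];
    if (!c) continue;
    acc += (long long)v * c * (2 * cum + c - n);
    cum += c;
  }
  return (double)acc;
}

static inline double allpairs_sorted(std::vector<double>& x) {
  std::sort(x.begin(), x.end());
  int n = (int)x.size();
  double acc = 0;
  for (int k = 0; k < n; k++) acc += (2.0 * (k + 1) - 1.0 - n) * x[k];
  return acc;
}

// ---------------------------------------------------------------------------
// Quantized read-noise sampler. The recorded value of a static pixel with
// clean intensity v is round(v + sigma*N) clipped to [0, maxval]; its
// distribution over integers depends on v only through base = floor(v) and
// the fractional part. A CDF table over NFRAC quantized fractional parts x
// integer offsets lets each frame value be drawn with one uniform and a
// short integer-compare scan - exact up to the 1/NFRAC fractional-part
// quantization (< 1/512 DN displacement).
struct QNoise {
  int m_lo, m_hi, width, nfrac, mid;
  std::vector<uint64_t> cdf;  // nfrac rows of `width` cumulative thresholds
  void build(double sd, int nfrac_) {
    nfrac = nfrac_;
    int span = std::max(1, (int)std::ceil(6.0 * sd));
    m_lo = -span; m_hi = span;
    width = m_hi - m_lo + 1;
    mid = -m_lo;  // offset index of m = 0, near the distribution median
    cdf.assign((size_t)nfrac * width, 0);
    for (int f = 0; f < nfrac; f++) {
      double frac = (f + 0.5) / nfrac;
      double cum = 0;
      for (int m = m_lo; m <= m_hi; m++) {
        double hiq = (m + 0.5 - frac) / sd;
        cum = R::pnorm(hiq, 0.0, 1.0, 1, 0);
        if (m == m_hi) cum = 1.0;
        cdf[(size_t)f * width + (m - m_lo)] =
            (uint64_t)(cum * 18446744073709551615.0);
      }
    }
  }
  inline const uint64_t* row(int frac_idx) const {
    return &cdf[(size_t)frac_idx * width];
  }
  // one uniform; branch-free bin location (sum of threshold comparisons)
  inline int draw(Xo& g, const uint64_t* r, int base, int maxval) const {
    uint64_t u = g.next();
    int m = 0;
    for (int j = 0; j < width - 1; j++) m += (u > r[j]);
    int iv = base + m_lo + m;
    if (iv < 0) iv = 0;
    if (iv > maxval) iv = maxval;
    return iv;
  }
};

// ---------------------------------------------------------------------------
// Simulate one light-sheet position: frozen fully-developed speckle from the
// static matrix (plus optional lognormal clutter texture), AR(1) temporal
// decorrelation where rho < 1, sensor saturation (roots), read noise and
// quantization. Optionally accumulates the generalized-differences image of
// the stack in the same pass; the frame values drawn are identical whether
// or not frames are materialized.
// [[Rcpp::export]]
List cpp_sim_position(NumericMatrix rho, NumericMatrix brightness,
                      LogicalMatrix saturate, LogicalMatrix obj_mask,
                      int nframes, double exposure, double read_sd,
                      int maxval, double grain_sigma,
                      double clutter_sd, double clutter_scale,
                      double seed, int frames_mode, bool return_gd,
                      int max_lag) {
  // frames_mode: 0 = no frames, 1 = full stack, 2 = first frame only
  const bool return_frames = frames_mode == 1;
  const bool first_only = frames_mode == 2;
  const double* qt = normtab();
  const int nx = rho.nrow(), ny = rho.ncol();
  const size_t n = (size_t)nx * ny;
  Xo g((uint64_t)seed);

  // 1. initial circular complex Gaussian field, unit mean intensity;
  //    spatial grain via low-pass filtering of the initial field
  std::vector<double> re(n), im(n);
  const double isq2 = 0.70710678118654752;
  for (size_t p = 0; p < n; p++) {
    re[p] = rnorm_fast(g, qt) * isq2;
    im[p] = rnorm_fast(g, qt) * isq2;
  }
  if (grain_sigma > 0) {
    std::vector<double> k = gauss_l2(grain_sigma);
    conv2_circ(re, nx, ny, k);
    conv2_circ(im, nx, ny, k);
  }

  // 2. static clutter texture (unit-mean lognormal), background only
  std::vector<double> bright(n);
  for (size_t p = 0; p < n; p++) bright[p] = brightness[p];
  if (clutter_sd > 0) {
    std::vector<double> gc(n);
    for (size_t p = 0; p < n; p++) gc[p] = rnorm_fast(g, qt);
    conv2_circ(gc, nx, ny, gauss_l2(clutter_scale));
    double half = 0.5 * clutter_sd * clutter_sd;
    for (size_t p = 0; p < n; p++)
      if (!obj_mask[p]) bright[p] *= std::exp(clutter_sd * gc[p] - half);
  }

  // 3. clean static intensities
  std::vector<double> istat(n);
  for (size_t p = 0; p < n; p++)
    istat[p] = (re[p] * re[p] + im[p] * im[p]) * exposure * bright[p];

  // 4. temporal evolution at decorrelating pixels (per-pixel AR(1))
  std::vector<int> active;
  for (size_t p = 0; p < n; p++)
    if (rho[p] < 1.0 && !saturate[p]) active.push_back((int)p);
  size_t n_act = active.size();
  std::vector<float> series;
  std::vector<int> row_of;
  if (n_act) {
    row_of.assign(n, -1);
    series.assign(n_act * (size_t)nframes, 0.0f);
    for (size_t a = 0; a < n_act; a++) row_of[active[a]] = (int)a;
    for (size_t a = 0; a < n_act; a++) {
      int p = active[a];
      double r0 = rho[p], s0 = std::sqrt(1.0 - r0 * r0);
      double er = re[p], ei = im[p];
      double sc = exposure * bright[p];
      float* row = &series[a * (size_t)nframes];
      row[0] = (float)((er * er + ei * ei) * sc);
      for (int t = 1; t < nframes; t++) {
        er = r0 * er + s0 * rnorm_fast(g, qt) * isq2;
        ei = r0 * ei + s0 * rnorm_fast(g, qt) * isq2;
        row[t] = (float)((er * er + ei * ei) * sc);
      }
    }
  }

  // 5. readout: noise + quantization, streaming GD and/or frames
  QNoise qn;
  const int NFRAC = 256;
  if (read_sd > 0) qn.build(read_sd, NFRAC);
  IntegerVector frames;
  if (return_frames) frames = IntegerVector((R_xlen_t)n * nframes);
  IntegerMatrix frame1;
  if (first_only) frame1 = IntegerMatrix(nx, ny);
  NumericMatrix gd;
  if (return_gd) gd = NumericMatrix(nx, ny);
  bool hist_ok = (maxval <= 65535) && (max_lag <= 0);
  std::vector<int> hist(hist_ok ? (maxval + 1) : 0, 0);
  std::vector<int> vals(nframes);
  int* fr = return_frames ? &frames[0] : (int*)0;
  int* f1 = first_only ? &frame1[0] : (int*)0;

  for (size_t p = 0; p < n; p++) {
    int lo = maxval, hi = 0;
    int a = n_act ? row_of[p] : -1;
    if (saturate[p]) {
      // pushed far above full scale: reads maxval in every frame,
      // consumes no noise draws
      if (return_frames)
        for (int t = 0; t < nframes; t++) fr[(size_t)t * n + p] = maxval;
      if (first_only) f1[p] = maxval;
      if (return_gd) gd[p] = 0.0;
      continue;
    }
    if (a >= 0) {
      const float* row = &series[(size_t)a * nframes];
      for (int t = 0; t < nframes; t++) {
        double v = row[t];
        int iv;
        if (read_sd > 0) {
          int base = (int)std::floor(v);
          int fi = (int)((v - base) * NFRAC);
          if (fi >= NFRAC) fi = NFRAC - 1;
          iv = qn.draw(g, qn.row(fi), base, maxval);
        } else {
          iv = (int)std::floor(v + 0.5);
          if (iv < 0) iv = 0;
          if (iv > maxval) iv = maxval;
        }
        vals[t] = iv;
        if (return_frames) fr[(size_t)t * n + p] = iv;
        if (first_only && t == 0) f1[p] = iv;
        if (return_gd && hist_ok) {
          hist[iv]++;
          if (iv < lo) lo = iv;
          if (iv > hi) hi = iv;
        }
      }
    } else if (read_sd > 0) {
      double v = istat[p];
      int base = (int)std::floor(v);
      int fi = (int)((v - base) * NFRAC);
      if (fi >= NFRAC) fi = NFRAC - 1;
      const uint64_t* r = qn.row(fi);
      if (return_gd && hist_ok && !return_frames) {
        for (int t = 0; t < nframes; t++) {
          int iv = qn.draw(g, r, base, maxval);
          if (first_only && t == 0) f1[p] = iv;
          hist[iv]++;
          if (iv < lo) lo = iv;
          if (iv > hi) hi = iv;
        }
        gd[p] = allpairs_from_hist(hist.data(), lo, hi, nframes);
        for (int v2 = lo; v2 <= hi; v2++) hist[v2] = 0;
        continue;
      }
      for (int t = 0; t < nframes; t++) {
        int iv = qn.draw(g, r, base, maxval);
        vals[t] = iv;
        if (return_frames) fr[(size_t)t * n + p] = iv;
        if (first_only && t == 0) f1[p] = iv;
        if (return_gd && hist_ok) {
          hist[iv]++;
          if (iv < lo) lo = iv;
          if (iv > hi) hi = iv;
        }
      }
    } else {
      int iv = (int)std::floor(istat[p] + 0.5);
      if (iv < 0) iv = 0;
      if (iv > maxval) iv = maxval;
      if (return_frames)
        for (int t = 0; t < nframes; t++) fr[(size_t)t * n + p] = iv;
      if (first_only) f1[p] = iv;
      if (return_gd) gd[p] = 0.0;
      continue;
    }
    if (return_gd) {
      if (hist_ok) {
        gd[p] = allpairs_from_hist(hist.data(), lo, hi, nframes);
        for (int v = lo; v <= hi; v++) hist[v] = 0;
      } else if (max_lag > 0) {
        double acc = 0;
        for (int i = 0; i < nframes; i++)
          for (int j = 1; j <= max_lag && i + j < nframes; j++)
            acc += std::abs((double)vals[i + j] - vals[i]);
        gd[p] = acc;
      } else {
        std::vector<double> x(vals.begin(), vals.end());
        gd[p] = allpairs_sorted(x);
      }
    }
  }

  return List::create(_["gd"] = return_gd ? (SEXP)gd : R_NilValue,
                      _["frames"] = return_frames ? (SEXP)frames
                                                  : R_NilValue,
                      _["frame1"] = first_only ? (SEXP)frame1 : R_NilValue);
}

// ---------------------------------------------------------------------------
// Generalized differences of a materialized stack (nx, ny, N array).
// max_lag <= 0 means the full all-pairs sum.
// [[Rcpp::export]]
NumericMatrix cpp_gd_stack(NumericVector frames, IntegerVector dim,
                           int max_lag) {
  int nx = dim[0], ny = dim[1], nf = dim[2];
  size_t n = (size_t)nx * ny;
  NumericMatrix gd(nx, ny);
  std::vector<double> x(nf);
  for (size_t p = 0; p < n; p++) {
    for (int t = 0; t < nf; t++) x[t] = frames[(R_xlen_t)t * n + p];
    if (max_lag <= 0) {
      std::vector<double> xs(x);
      gd[p] = allpairs_sorted(xs);
    } else {
      double acc = 0;
      for (int i = 0; i < nf; i++)
        for (int j = 1; j <= max_lag && i + j < nf; j++)
          acc += std::abs(x[i + j] - x[i]);
      gd[p] = acc;
    }
  }
  return gd;
}

// ---------------------------------------------------------------------------
// Reflect (half-sample symmetric) index: ... c b a | a b c ... | c b a
static inline int refl(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// 1D convolution of every line along one axis of a 3D volume, line-buffered
// with reflect padding.
static void conv_axis(std::vector<double>& a, int nx, int ny, int nz,
                      int axis, const std::vector<double>& k) {
  int r = ((int)k.size() - 1) / 2;
  int kn = 2 * r + 1;
  size_t sxy = (size_t)nx * ny;
  int len = (axis == 0) ? nx : (axis == 1) ? ny : nz;
  std::vector<double> buf(len + 2 * r), out(len);
  int n_outer1 = (axis == 0) ? ny : nx;
  int n_outer2 = (axis == 2) ? ny : nz;
  for (int o2 = 0; o2 < n_outer2; o2++) {
    for (int o1 = 0; o1 < n_outer1; o1++) {
      size_t base; size_t stride;
      if (axis == 0) { base = (size_t)o2 * sxy + (size_t)o1 * nx; stride = 1; }
      else if (axis == 1) { base = (size_t)o2 * sxy + o1; stride = nx; }
      else { base = (size_t)o2 * nx + o1; stride = sxy; }
      for (int i = -r; i < len + r; i++)
        buf[i + r] = a[base + (size_t)refl(i, len) * stride];
      for (int i = 0; i < len; i++) {
        double acc = 0;
        const double* b = &buf[i];
        for (int d = 0; d < kn; d++) acc += b[d] * k[d];
        out[i] = acc;
      }
      for (int i = 0; i < len; i++) a[base + (size_t)i * stride] = out[i];
    }
  }
}

// Separable 3D Gaussian smoothing with reflect padding; per-axis sigma in
// voxel units; sigma <= 0 leaves the axis untouched.
// [[Rcpp::export]]
NumericVector cpp_gauss3d(NumericVector vol, IntegerVector dim,
                          double sx, double sy, double sz) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> a(vol.begin(), vol.end());
  if (sx > 0) conv_axis(a, nx, ny, nz, 0, gauss_l1(sx));
  if (sy > 0) conv_axis(a, nx, ny, nz, 1, gauss_l1(sy));
  if (sz > 0) conv_axis(a, nx, ny, nz, 2, gauss_l1(sz));
  NumericVector out(a.size());
  std::copy(a.begin(), a.end(), out.begin());
  out.attr("dim") = dim;
  return out;
}

// Running mean of every line along one axis (reflect padding, window 2r+1).
static void boxmean_axis(std::vector<double>& a, int nx, int ny, int nz,
                         int axis, int r) {
  size_t sxy = (size_t)nx * ny;
  int len = (axis == 0) ? nx : (axis == 1) ? ny : nz;
  std::vector<double> buf(len + 2 * r), out(len);
  double w = 2.0 * r + 1.0;
  int n_outer1 = (axis == 0) ? ny : nx;
  int n_outer2 = (axis == 2) ? ny : nz;
  for (int o2 = 0; o2 < n_outer2; o2++) {
    for (int o1 = 0; o1 < n_outer1; o1++) {
      size_t base; size_t stride;
      if (axis == 0) { base = (size_t)o2 * sxy + (size_t)o1 * nx; stride = 1; }
      else if (axis == 1) { base = (size_t)o2 * sxy + o1; stride = nx; }
      else { base = (size_t)o2 * nx + o1; stride = sxy; }
      for (int i = -r; i < len + r; i++)
        buf[i + r] = a[base + (size_t)refl(i, len) * stride];
      double s = 0;
      for (int d = 0; d < 2 * r + 1; d++) s += buf[d];
      out[0] = s / w;
      for (int i = 1; i < len; i++) {
        s += buf[i + 2 * r] - buf[i - 1];
        out[i] = s / w;
      }
      for (int i = 0; i < len; i++) a[base + (size_t)i * stride] = out[i];
    }
  }
}

// Per-slice 2D boxcar (moving-average) mean with reflect padding; window
// half-widths rx, ry in pixels. Returns the local-mean volume.
// [[Rcpp::export]]
NumericVector cpp_boxcar_mean(NumericVector vol, IntegerVector dim,
                              int rx, int ry) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> a(vol.begin(), vol.end());
  boxmean_axis(a, nx, ny, nz, 0, rx);
  boxmean_axis(a, nx, ny, nz, 1, ry);
  NumericVector out(a.size());
  std::copy(a.begin(), a.end(), out.begin());
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// 3D connected components on a binary volume; connectivity 6, 18 or 26.
// Labels are assigned in first-voxel scan order, so they are contiguous
// positive integers.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim,
                          int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz, sxy = (size_t)nx * ny;
  IntegerVector lab((R_xlen_t)n);
  std::vector<int> odx, ody, odz;
  for (int dz = -1; dz <= 1; dz++)
    for (int dy = -1; dy <= 1; dy++)
      for (int dx = -1; dx <= 1; dx++) {
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        odx.push_back(dx); ody.push_back(dy); odz.push_back(dz);
      }
  int nb = (int)odx.size();
  std::vector<size_t> stack;
  int next = 0;
  for (size_t p = 0; p < n; p++) {
    if (!mask[p] || lab[p]) continue;
    next++;
    lab[p] = next;
    stack.clear();
    stack.push_back(p);
    while (!stack.empty()) {
      size_t q = stack.back();
      stack.pop_back();
      int x = (int)(q % nx), y = (int)((q / nx) % ny), z = (int)(q / sxy);
      for (int b = 0; b < nb; b++) {
        int x2 = x + odx[b], y2 = y + ody[b], z2 = z + odz[b];
        if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
          continue;
        size_t q2 = (size_t)z2 * sxy + (size_t)y2 * nx + x2;
        if (mask[q2] && !lab[q2]) {
          lab[q2] = next;
          stack.push_back(q2);
        }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}
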