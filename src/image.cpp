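#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// 3D scalp-by-frequency image tools.  Volumes are nx * ny * nz column-major;
// the inside-head mask is 2D (nx * ny) and applies to every frequency plane.

static std::vector<double> gauss_kernel(double sigma) {
  if (sigma <= 0) return std::vector<double>(1, 1.0);
  int r = static_cast<int>(std::ceil(3.0 * sigma));   // 99.7% mass
  if (r < 1) r = 1;
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int o = -r; o <= r; ++o) {
    k[o + r] = std::exp(-0.5 * o * o / (sigma * sigma));
    s += k[o + r];
  }
  for (double& v : k) v /= s;
  return k;
}

// In-place separable convolution along one axis.  The volume is viewed as
// [inner stride s][axis length L][outer blocks]; each output slab (length
// s, contiguous) accumulates kernel-weighted source slabs, so every memory
// access is sequential and the inner loop vectorizes.
static void conv_axis(std::vector<double>& a, int nx, int ny, int nz,
                      int axis, const std::vector<double>& k) {
  const int r = (static_cast<int>(k.size()) - 1) / 2;
  if (r == 0) return;
  const size_t strides[3] = {1, static_cast<size_t>(nx),
                             static_cast<size_t>(nx) * ny};
  const int n[3] = {nx, ny, nz};
  const size_t s = strides[axis];
  const int L = n[axis];
  const size_t total = static_cast<size_t>(nx) * ny * nz;
  if (s == 1) {                    // contiguous lines: direct stencil
    const size_t nlines = total / L;
    std::vector<double> out(L);
    for (size_t ln = 0; ln < nlines; ++ln) {
      double* line = &a[ln * L];
      for (int i = 0; i < L; ++i) {
        const int lo = std::max(-i, -r), hi = std::min(r, L - 1 - i);
        double acc = 0.0;
        for (int o = lo; o <= hi; ++o) acc += k[o + r] * line[i + o];
        out[i] = acc;
      }
      std::copy(out.begin(), out.end(), line);
    }
    return;
  }
  const size_t block = s * L;
  const size_t outer = total / block;
  std::vector<double> buf(block);
  for (size_t b = 0; b < outer; ++b) {
    double* blk = &a[b * block];
    std::fill(buf.begin(), buf.end(), 0.0);
    for (int i = 0; i < L; ++i) {
      const int lo = std::max(-i, -r), hi = std::min(r, L - 1 - i);
      double* out = &buf[i * s];
      for (int o = lo; o <= hi; ++o) {
        const double kv = k[o + r];
        const double* src = blk + (i + o) * s;
        for (size_t t = 0; t < s; ++t) out[t] += kv * src[t];
      }
    }
    std::copy(buf.begin(), buf.end(), blk);
  }
}

// Separable Gaussian smoothing, mask- and NaN-normalized: the volume is
// multiplied by an indicator of valid voxels, both are smoothed, and the
// ratio is returned so that constants are preserved inside the mask.
// sigma is in voxel units per axis; sigma <= 0 means no smoothing.
// [[Rcpp::export]]
NumericVector cpp_smooth3d(NumericVector vol, IntegerVector dims,
                           LogicalVector mask, NumericVector sigma) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t total = static_cast<size_t>(nx) * ny * nz;
  const size_t plane = static_cast<size_t>(nx) * ny;
  std::vector<double> num(total), den(total);
  for (size_t v = 0; v < total; ++v) {
    const bool in = mask[v % plane] && R_finite(vol[v]);
    num[v] = in ? vol[v] : 0.0;
    den[v] = in ? 1.0 : 0.0;
  }
  for (int axis = 0; axis < 3; ++axis) {
    std::vector<double> k = gauss_kernel(sigma[axis]);
    conv_axis(num, nx, ny, nz, axis, k);
    conv_axis(den, nx, ny, nz, axis, k);
  }
  NumericVector out(total);
  for (size_t v = 0; v < total; ++v) {
    if (!mask[v % plane] || den[v] <= 1e-12)
      out[v] = NA_REAL;
    else
      out[v] = num[v] / den[v];
  }
  out.attr("dim") = dims;
  return out;
}

// Pseudo-T statistics for all permutations at once.  sum_a holds the
// group-A voxel sums per permutation (V x P, overwritten in place with the
// statistic and returned); sum_all and sq_sum_all are the voxelwise totals
// over all n = na + nb subjects.  Per permutation: group means, pooled
// variance, Gaussian variance smoothing (shared mask normalization), then
// T = (mean_a - mean_b) / sqrt(svar * (1/na + 1/nb)); voxels outside the
// mask or with non-finite T are set to 0.
// [[Rcpp::export]]
NumericMatrix cpp_pseudo_t_perm(NumericMatrix sum_a, NumericVector sum_all,
                                NumericVector sq_sum_all, int na, int nb,
                                IntegerVector dims, LogicalVector mask,
                                NumericVector sigma) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t total = static_cast<size_t>(nx) * ny * nz;
  const size_t plane = static_cast<size_t>(nx) * ny;
  const int P = sum_a.ncol();
  const int n = na + nb;
  const double scale = std::sqrt(1.0 / na + 1.0 / nb);
  std::vector<std::vector<double> > kernels(3);
  for (int axis = 0; axis < 3; ++axis) kernels[axis] = gauss_kernel(sigma[axis]);

  std::vector<unsigned char> vmask(total);
  for (size_t v = 0; v < total; ++v) vmask[v] = mask[v % plane] ? 1 : 0;
  std::vector<double> den(total);
  for (size_t v = 0; v < total; ++v) den[v] = vmask[v] ? 1.0 : 0.0;
  for (int axis = 0; axis < 3; ++axis) conv_axis(den, nx, ny, nz, axis, kernels[axis]);
  // fold the mask and normalization into one multiplier: 0 outside,
  // 1 / (den * scale^2) inside (t is formed as diff / sqrt(svar) later)
  std::vector<double> inv_den(total);
  for (size_t v = 0; v < total; ++v)
    inv_den[v] = (vmask[v] && den[v] > 1e-12) ? 1.0 / den[v] : 0.0;

  std::vector<double> diff(total), pooled(total);
  const double inv_na = 1.0 / na, inv_nb = 1.0 / nb, inv_df = 1.0 / (n - 2);
  for (int p = 0; p < P; ++p) {
    double* col = &sum_a(0, p);
    for (size_t v = 0; v < total; ++v) {
      const double ma = col[v] * inv_na;
      const double mb = (sum_all[v] - col[v]) * inv_nb;
      const double ss = sq_sum_all[v] - na * ma * ma - nb * mb * mb;
      diff[v] = ma - mb;
      pooled[v] = (ss > 0) ? ss * inv_df : 0.0;
    }
    for (int axis = 0; axis < 3; ++axis)
      conv_axis(pooled, nx, ny, nz, axis, kernels[axis]);
    for (size_t v = 0; v < total; ++v) {
      const double sv = pooled[v] * inv_den[v];
      const double t = diff[v] / (std::sqrt(sv) * scale);
      col[v] = (inv_den[v] > 0 && R_finite(t)) ? t : 0.0;
    }
  }
  return sum_a;
}

// Type-7 quantile of |stat| over masked voxels of every permutation,
// via nth_element selection.
// [[Rcpp::export]]
double cpp_quantile_abs_masked(NumericMatrix stat, IntegerVector dims,
                               LogicalVector mask, double q) {
  const size_t total = static_cast<size_t>(dims[0]) * dims[1] * dims[2];
  const size_t plane = static_cast<size_t>(dims[0]) * dims[1];
  const int P = stat.ncol();
  std::vector<unsigned char> vmask(total);
  for (size_t v = 0; v < total; ++v) vmask[v] = mask[v % plane] ? 1 : 0;
  std::vector<double> vals;
  vals.reserve(total * P);
  for (int p = 0; p < P; ++p) {
    const double* col = &stat(0, p);
    for (size_t v = 0; v < total; ++v)
      if (vmask[v]) vals.push_back(std::fabs(col[v]));
  }
  const size_t nv = vals.size();
  const double h = (nv - 1) * q;
  const size_t lo = static_cast<size_t>(std::floor(h));
  std::nth_element(vals.begin(), vals.begin() + lo, vals.end());
  const double xlo = vals[lo];
  if (lo + 1 >= nv) return xlo;
  const double xhi = *std::min_element(vals.begin() + lo + 1, vals.end());
  return xlo + (h - lo) * (xhi - xlo);
}

// Label 26-connected suprathreshold components (stat > thresh, inside mask).
// labels: 0 background, 1..K clusters; also returns cluster sizes.
static std::vector<int> label_volume(const double* stat, int nx, int ny, int nz,
                                     const int* mask, double thresh,
                                     bool absolute, std::vector<int>& labels) {
  const size_t total = static_cast<size_t>(nx) * ny * nz;
  const size_t plane = static_cast<size_t>(nx) * ny;
  labels.assign(total, 0);
  std::vector<int> sizes;
  std::vector<size_t> stack;
  int next = 0;
  for (size_t seed = 0; seed < total; ++seed) {
    if (labels[seed] != 0) continue;
    const double sv = absolute ? std::fabs(stat[seed]) : stat[seed];
    if (!mask[seed % plane] || !R_finite(stat[seed]) || sv <= thresh)
      continue;
    ++next;
    int count = 0;
    stack.clear();
    stack.push_back(seed);
    labels[seed] = next;
    while (!stack.empty()) {
      const size_t v = stack.back();
      stack.pop_back();
      ++count;
      const int x = static_cast<int>(v % nx);
      const int y = static_cast<int>((v / nx) % ny);
      const int z = static_cast<int>(v / plane);
      for (int dz = -1; dz <= 1; ++dz) {
        for (int dy = -1; dy <= 1; ++dy) {
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            const int X = x + dx, Y = y + dy, Z = z + dz;
            if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz)
              continue;
            const size_t w = X + static_cast<size_t>(Y) * nx + Z * plane;
            if (labels[w] != 0) continue;
            const double wv = absolute ? std::fabs(stat[w]) : stat[w];
            if (!mask[w % plane] || !R_finite(stat[w]) || wv <= thresh)
              continue;
            labels[w] = next;
            stack.push_back(w);
          }
        }
      }
    }
    sizes.push_back(count);
  }
  return sizes;
}

// [[Rcpp::export]]
List cpp_label_clusters(NumericVector stat, IntegerVector dims,
                        LogicalVector mask, double thresh,
                        bool absolute = false) {
  std::vector<int> labels;
  std::vector<int> msk(mask.begin(), mask.end());
  std::vector<int> sizes = label_volume(stat.begin(), dims[0], dims[1], dims[2],
                                        msk.data(), thresh, absolute, labels);
  IntegerVector lab(labels.begin(), labels.end());
  lab.attr("dim") = dims;
  return List::create(_["labels"] = lab,
                      _["sizes"] = IntegerVector(sizes.begin(), sizes.end()));
}

// Maximum suprathreshold cluster size for each column of a V x P matrix of
// permutation statistics (V = prod(dims)).
// [[Rcpp::export]]
IntegerVector cpp_max_cluster_sizes(NumericMatrix stats, IntegerVector dims,
                                    LogicalVector mask, double thresh,
                                    bool absolute = false) {
  const int P = stats.ncol();
  IntegerVector out(P);
  std::vector<int> labels;
  std::vector<int> msk(mask.begin(), mask.end());
  for (int p = 0; p < P; ++p) {
    std::vector<int> sizes = label_volume(&stats(0, p), dims[0], dims[1],
                                          dims[2], msk.data(), thresh,
                                          absolute, labels);
    int mx = 0;
    for (int s : sizes) mx = std::max(mx, s);
    out[p] = mx;
  }
  return out;
}
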