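#include <Rcpp.h>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static inline int clampi(int x, int lo, int hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// 3-D median filter with an odd cubic kernel; borders handled by
// replicating the nearest voxel (clamp indexing).
// [[Rcpp::export]]
NumericVector median_filter3(NumericVector vol, IntegerVector dim, int ksize) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const int r = ksize / 2, kn = ksize * ksize * ksize;
  NumericVector out(vol.size());
  std::vector<double> buf(kn);
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        int c = 0;
        for (int dk = -r; dk <= r; ++dk) {
          int kk = clampi(k + dk, 0, n3 - 1);
          for (int dj = -r; dj <= r; ++dj) {
            int jj = clampi(j + dj, 0, n2 - 1);
            for (int di = -r; di <= r; ++di) {
              int ii = clampi(i + di, 0, n1 - 1);
              buf[c++] = vol[ii + (size_t)n1 * (jj + (size_t)n2 * kk)];
            }
          }
        }
        std::nth_element(buf.begin(), buf.begin() + kn / 2, buf.begin() + kn);
        double med = buf[kn / 2];
        if (kn % 2 == 0) {
          double lo = *std::max_element(buf.begin(), buf.begin() + kn / 2);
          med = 0.5 * (med + lo);
        }
        out[i + (size_t)n1 * (j + (size_t)n2 * k)] = med;
      }
  return out;
}

// Median over a 3^3 neighbourhood restricted to voxels where mask != 0;
// voxels outside the mask are left at zero. Used for velocity-map
// denoising where zero-support voxels must not drag the median down.
// [[Rcpp::export]]
NumericVector masked_median_filter3(NumericVector vol, IntegerVector mask,
                                    IntegerVector dim, int ksize) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const int r = ksize / 2;
  NumericVector out(vol.size());
  std::vector<double> buf;
  buf.reserve((size_t)ksize * ksize * ksize);
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        size_t p = i + (size_t)n1 * (j + (size_t)n2 * k);
        if (!mask[p]) continue;
        buf.clear();
        for (int dk = -r; dk <= r; ++dk) {
          int kk = k + dk; if (kk < 0 || kk >= n3) continue;
          for (int dj = -r; dj <= r; ++dj) {
            int jj = j + dj; if (jj < 0 || jj >= n2) continue;
            for (int di = -r; di <= r; ++di) {
              int ii = i + di; if (ii < 0 || ii >= n1) continue;
              size_t q = ii + (size_t)n1 * (jj + (size_t)n2 * kk);
              if (mask[q]) buf.push_back(vol[q]);
            }
          }
        }
        size_t nb = buf.size();
        std::nth_element(buf.begin(), buf.begin() + nb / 2, buf.end());
        double med = buf[nb / 2];
        if (nb % 2 == 0) {
          double lo = *std::max_element(buf.begin(), buf.begin() + nb / 2);
          med = 0.5 * (med + lo);
        }
        out[p] = med;
      }
  return out;
}

// Greyscale erosion (min) or dilation (max) with an arbitrary structuring
// element given as a matrix of integer offsets (n_offsets x 3).
// Out-of-bounds neighbours are omitted from the extremum.
// [[Rcpp::export]]
NumericVector grey_morph3(NumericVector vol, IntegerVector dim,
                          IntegerMatrix offsets, bool dilate) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const int no = offsets.nrow();
  NumericVector out(vol.size());
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        double acc = vol[i + (size_t)n1 * (j + (size_t)n2 * k)];
        for (int o = 0; o < no; ++o) {
          int ii = i + offsets(o, 0);
          int jj = j + offsets(o, 1);
          int kk = k + offsets(o, 2);
          if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || kk < 0 || kk >= n3)
            continue;
          double v = vol[ii + (size_t)n1 * (jj + (size_t)n2 * kk)];
          if (dilate ? (v > acc) : (v < acc)) acc = v;
        }
        out[i + (size_t)n1 * (j + (size_t)n2 * k)] = acc;
      }
  return out;
}

// Separable Gaussian smoothing along all three axes with a truncated
// kernel (+-3 sigma). normalize = true renormalizes the kernel mass at
// the borders (replicate-like behaviour for smoothing); false uses plain
// zero padding (linear convolution, mass-preserving in the interior).
// [[Rcpp::export]]
NumericVector gaussian_filter3(NumericVector vol, IntegerVector dim,
                               double sigma, bool normalize) {
  const int n[3] = {dim[0], dim[1], dim[2]};
  if (sigma <= 0) return clone(vol);
  int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> ker(2 * r + 1);
  double s = 0.0;
  for (int t = -r; t <= r; ++t) {
    ker[t + r] = std::exp(-0.5 * t * t / (sigma * sigma));
    s += ker[t + r];
  }
  for (double &w : ker) w /= s;
  std::vector<double> cur(vol.begin(), vol.end()), nxt(vol.size());
  const size_t stride1 = 1, stride2 = (size_t)n[0],
               stride3 = (size_t)n[0] * n[1];
  const size_t strides[3] = {stride1, stride2, stride3};
  for (int axis = 0; axis < 3; ++axis) {
    const int len = n[axis];
    const size_t st = strides[axis];
    // iterate over all lines along `axis`
    const int na = n[(axis + 1) % 3], nb = n[(axis + 2) % 3];
    const size_t sta = strides[(axis + 1) % 3], stb = strides[(axis + 2) % 3];
    for (int b = 0; b < nb; ++b)
      for (int a = 0; a < na; ++a) {
        size_t base = a * sta + b * stb;
        for (int x = 0; x < len; ++x) {
          double acc = 0.0, wsum = 0.0;
          int lo = std::max(-r, -x), hi = std::min(r, len - 1 - x);
          for (int t = lo; t <= hi; ++t) {
            acc += ker[t + r] * cur[base + (size_t)(x + t) * st];
            wsum += ker[t + r];
          }
          nxt[base + (size_t)x * st] = normalize && wsum > 0 ? acc / wsum : acc;
        }
      }
    std::swap(cur, nxt);
  }
  return NumericVector(cur.begin(), cur.end());
}
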