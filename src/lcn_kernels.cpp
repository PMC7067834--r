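#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Index helpers: arrays are dim (nx, ny, nz), column-major as in R,
// voxel (i, j, k) 0-based here -> linear i + nx*(j + ny*k).

static inline int mirror_idx(int i, int n) {
  // reflect-without-repeat ("mirror") edge handling
  if (n == 1) return 0;
  int period = 2 * n - 2;
  i = ((i % period) + period) % period;
  return (i < n) ? i : period - i;
}

// [[Rcpp::export(name = ".cpp_median_filter3")]]
NumericVector cpp_median_filter3(NumericVector vol, IntegerVector dims, int radius) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  if (radius < 1) stop("radius must be >= 1");
  NumericVector out(vol.size());
  const int w = 2 * radius + 1;
  std::vector<double> window(static_cast<size_t>(w) * w * w);
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        size_t m = 0;
        for (int dk = -radius; dk <= radius; ++dk) {
          const int kk = mirror_idx(k + dk, nz);
          for (int dj = -radius; dj <= radius; ++dj) {
            const int jj = mirror_idx(j + dj, ny);
            const size_t base = static_cast<size_t>(nx) * (jj + static_cast<size_t>(ny) * kk);
            for (int di = -radius; di <= radius; ++di) {
              const int ii = mirror_idx(i + di, nx);
              window[m++] = vol[base + ii];
            }
          }
        }
        std::nth_element(window.begin(), window.begin() + m / 2, window.begin() + m);
        out[i + static_cast<size_t>(nx) * (j + static_cast<size_t>(ny) * k)] = window[m / 2];
      }
    }
  }
  return out;
}

// Connected component labeling of a binary mask, 6- or 26-connectivity.
// Labels are assigned in raster-scan order of each component's first voxel
// (so label order is deterministic); 0 is background.
// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims, int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t n = static_cast<size_t>(nx) * ny * nz;
  if (connectivity != 6 && connectivity != 26) stop("connectivity must be 6 or 26");
  IntegerVector labels(n, 0);

  // neighbour offsets
  std::vector<int> di, dj, dk;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        if (connectivity == 6 && (std::abs(a) + std::abs(b) + std::abs(c)) != 1) continue;
        di.push_back(a); dj.push_back(b); dk.push_back(c);
      }
  const int nb = static_cast<int>(di.size());

  std::vector<size_t> stack;
  int next_label = 0;
  for (size_t s = 0; s < n; ++s) {
    if (!mask[s] || labels[s] != 0) continue;
    ++next_label;
    labels[s] = next_label;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      const size_t cur = stack.back();
      stack.pop_back();
      const int k = static_cast<int>(cur / (static_cast<size_t>(nx) * ny));
      const int rem = static_cast<int>(cur % (static_cast<size_t>(nx) * ny));
      const int j = rem / nx;
      const int i = rem % nx;
      for (int q = 0; q < nb; ++q) {
        const int ii = i + di[q], jj = j + dj[q], kk = k + dk[q];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
        const size_t t = ii + static_cast<size_t>(nx) * (jj + static_cast<size_t>(ny) * kk);
        if (mask[t] && labels[t] == 0) {
          labels[t] = next_label;
          stack.push_back(t);
        }
      }
    }
  }
  labels.attr("n_labels") = next_label;
  return labels;
}

// 1D squared-distance transform (Felzenszwalb & Huttenlocher lower envelope).
static void dt1d(const double* f, double* d, int n,
                 std::vector<int>& v, std::vector<double>& z) {
  const double INF = std::numeric_limits<double>::infinity();
  // build the lower envelope over finite parabolas only (all-INF rows stay INF)
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (!std::isfinite(f[q])) continue;
    double s;
    while (k >= 0) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    if (k < 0) {
      k = 0;
      v[0] = q;
      z[0] = -INF;
    } else {
      ++k;
      v[k] = q;
      z[k] = s;
    }
    z[k + 1] = INF;
  }
  if (k < 0) {
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    const double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact squared Euclidean distance (in voxel units) from every voxel to the
// nearest TRUE voxel of `mask`. Voxels inside the mask get 0.
// [[Rcpp::export(name = ".cpp_edt_squared")]]
NumericVector cpp_edt_squared(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t n = static_cast<size_t>(nx) * ny * nz;
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector d(n);
  for (size_t s = 0; s < n; ++s) d[s] = mask[s] ? 0.0 : INF;

  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), g(nmax);
  std::vector<int> v(nmax);
  std::vector<double> z(nmax + 1);

  // along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      const size_t base = static_cast<size_t>(nx) * (j + static_cast<size_t>(ny) * k);
      for (int i = 0; i < nx; ++i) f[i] = d[base + i];
      dt1d(f.data(), g.data(), nx, v, z);
      for (int i = 0; i < nx; ++i) d[base + i] = g[i];
    }
  // along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      const size_t base = i + static_cast<size_t>(nx) * static_cast<size_t>(ny) * k;
      for (int j = 0; j < ny; ++j) f[j] = d[base + static_cast<size_t>(nx) * j];
      dt1d(f.data(), g.data(), ny, v, z);
      for (int j = 0; j < ny; ++j) d[base + static_cast<size_t>(nx) * j] = g[j];
    }
  // along z
  const size_t stride = static_cast<size_t>(nx) * ny;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      const size_t base = i + static_cast<size_t>(nx) * j;
      for (int k = 0; k < nz; ++k) f[k] = d[base + stride * k];
      dt1d(f.data(), g.data(), nz, v, z);
      for (int k = 0; k < nz; ++k) d[base + stride * k] = g[k];
    }
  return d;
}
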