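#ifndef PERAFR_CONV_H
#define PERAFR_CONV_H

#include <Rinternals.h>
#include <cmath>
#include <vector>
#include <algorithm>

// Separable Gaussian convolution along one axis (templated on the working
// precision) and BFS connected-component labelling, shared across
// translation units.

namespace perafr_conv {


// half-sample reflection of a 0-based index into [0, n)
inline int reflect_index(int p, int n) {
  while (p < 0 || p >= n) {
    if (p < 0) p = -p - 1;
    if (p >= n) p = 2 * n - p - 1;
  }
  return p;
}

inline std::vector<double> gauss_taps(double sd, int &r) {
  r = std::max(1, (int)std::ceil(4.0 * sd));
  std::vector<double> w(2 * r + 1);
  double s = 0.0;
  for (int j = -r; j <= r; ++j) {
    w[j + r] = std::exp(-0.5 * j * j / (sd * sd));
    s += w[j + r];
  }
  for (auto &v : w) v /= s;
  return w;
}

// convolve along one spatial axis of an (nx, ny, nz, nframes) volume;
// axes 1/2 accumulate over contiguous lower-dimensional blocks so the inner
// loops vectorize
template <typename T>
void conv_axis(std::vector<T> &a, std::vector<T> &b,
               const int dims[4], int axis, double sd) {
  int r;
  std::vector<double> wd = gauss_taps(sd, r);
  std::vector<T> w(wd.begin(), wd.end());
  int nx = dims[0], ny = dims[1], nz = dims[2], nf = dims[3];
  int n = dims[axis];
  if (axis == 0) {
    R_xlen_t nlines = (R_xlen_t)ny * nz * nf;
    std::fill(b.begin(), b.end(), T(0));
    for (R_xlen_t L = 0; L < nlines; ++L) {
      const T *__restrict in = a.data() + L * nx;
      T *__restrict out = b.data() + L * nx;
      for (int j = -r; j <= r; ++j) {
        T wj = w[j + r];
        int lo = std::max(0, -j), hi = std::min(nx, nx - j);
        for (int i = lo; i < hi; ++i) out[i] += wj * in[i + j];
        for (int i = 0; i < lo; ++i)
          out[i] += wj * in[reflect_index(i + j, nx)];
        for (int i = hi; i < nx; ++i)
          out[i] += wj * in[reflect_index(i + j, nx)];
      }
    }
  } else {
    R_xlen_t block = (axis == 1) ? nx : (R_xlen_t)nx * ny;
    R_xlen_t ngroup = (axis == 1) ? (R_xlen_t)nz * nf : nf;
    R_xlen_t span = block * n;
    std::vector<const T *> srcv(2 * r + 1);
    const T **src = srcv.data();
    for (R_xlen_t g = 0; g < ngroup; ++g) {
      const T *in = a.data() + g * span;
      T *out = b.data() + g * span;
      for (int i = 0; i < n; ++i) {
        T *__restrict o = out + (R_xlen_t)i * block;
        int ntap = 2 * r + 1;
        for (int j = -r; j <= r; ++j)
          src[j + r] = in + (R_xlen_t)reflect_index(i + j, n) * block;
        if (ntap == 9) {
          // single pass, 9 loads + 1 store per element (vectorizable)
          const T *q0 = src[0], *q1 = src[1], *q2 = src[2], *q3 = src[3],
                  *q4 = src[4], *q5 = src[5], *q6 = src[6], *q7 = src[7],
                  *q8 = src[8];
          for (R_xlen_t k = 0; k < block; ++k)
            o[k] = w[0] * q0[k] + w[1] * q1[k] + w[2] * q2[k] + w[3] * q3[k] +
                   w[4] * q4[k] + w[5] * q5[k] + w[6] * q6[k] + w[7] * q7[k] +
                   w[8] * q8[k];
        } else {
          for (R_xlen_t k = 0; k < block; ++k) {
            T acc = 0;
            for (int j = 0; j < ntap; ++j) acc += w[j] * src[j][k];
            o[k] = acc;
          }
        }
      }
    }
  }
  a.swap(b);
}



// neighbor offsets for 6 / 18 / 26 connectivity on a 3D grid
inline void make_offsets(int connectivity, std::vector<int> &dx, std::vector<int> &dy,
                  std::vector<int> &dz) {
  int max_manhattan = (connectivity == 6) ? 1 : (connectivity == 18 ? 2 : 3);
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        int m = std::abs(a) + std::abs(b) + std::abs(c);
        if (m == 0 || m > max_manhattan) continue;
        dx.push_back(a); dy.push_back(b); dz.push_back(c);
      }
}

// BFS labelling over an arbitrary predicate; shared by both entry points
template <typename Pred>
void label_bfs(const int *dims, Pred inside, int connectivity,
               std::vector<int> &labels, std::vector<int> &sizes) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<int> dx, dy, dz;
  make_offsets(connectivity, dx, dy, dz);
  int ndir = (int)dx.size();
  labels.assign(n, 0);
  sizes.clear();
  std::vector<int> stack;
  int next_label = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (labels[i] != 0 || !inside(i)) continue;
    ++next_label;
    int sz = 0;
    stack.clear();
    stack.push_back((int)i);
    labels[i] = next_label;
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      ++sz;
      int cz = cur / (nx * ny);
      int rem = cur - cz * nx * ny;
      int cy = rem / nx;
      int cx = rem - cy * nx;
      for (int dir = 0; dir < ndir; ++dir) {
        int px = cx + dx[dir], py = cy + dy[dir], pz = cz + dz[dir];
        if (px < 0 || px >= nx || py < 0 || py >= ny || pz < 0 || pz >= nz)
          continue;
        R_xlen_t nb = px + (R_xlen_t)py * nx + (R_xlen_t)pz * nx * ny;
        if (labels[nb] == 0 && inside(nb)) {
          labels[nb] = next_label;
          stack.push_back((int)nb);
        }
      }
    }
    sizes.push_back(sz);
  }
}

}  // namespace perafr_conv

#endif
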