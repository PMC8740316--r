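#include <Rcpp.h>
#include <vector>
#include "rng.h"
#include "conv.h"

using perafr_rng::NormalGen;
using perafr_rng::mix_seed;
using perafr_conv::conv_axis;
using perafr_conv::label_bfs;

// Entire Monte-Carlo extent-null loop in one call: per block of iterates,
// Gaussian white noise over the full grid (one RNG stream per block, seeded
// as mix_seed(seed, block_start+1)), separable smoothing, re-standardization
// over the in-mask voxels, two-tailed thresholding, and sign-split
// connected-component labelling. Draws one ziggurat normal per voxel in
// column-major order; all arithmetic in double precision. Lives in C++ so
// the loop is allocation-free at cohort scale.
// [[Rcpp::export]]
Rcpp::IntegerVector cpp_cluster_null_max_sizes(
    Rcpp::IntegerVector dims, Rcpp::IntegerVector maskidx,
    Rcpp::NumericVector sd_vox, double zthr, int connectivity,
    int n_iter, double seed, int block) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  int nm = maskidx.size();
  Rcpp::IntegerVector out(n_iter);
  static std::vector<double> A, B, zcol;
  std::vector<int> labels, sizes;
  int dlab[3] = {nx, ny, nz};
  zcol.assign(nvox, 0.0);
  int done = 0;
  while (done < n_iter) {
    int nb = std::min(block, n_iter - done);
    R_xlen_t n = nvox * (R_xlen_t)nb;
    A.resize(n);
    B.resize(n);
    NormalGen g(mix_seed(seed, done + 1));
    for (R_xlen_t i = 0; i < n; ++i) A[i] = g.next();
    int d4[4] = {nx, ny, nz, nb};
    for (int axis = 0; axis < 3; ++axis)
      if (sd_vox[axis] > 0) conv_axis(A, B, d4, axis, sd_vox[axis]);
    for (int it = 0; it < nb; ++it) {
      const double *col = A.data() + (R_xlen_t)it * nvox;
      double s = 0.0;
      for (int j = 0; j < nm; ++j) s += col[maskidx[j] - 1];
      double m = s / nm;
      double ss = 0.0;
      for (int j = 0; j < nm; ++j) {
        double dv = col[maskidx[j] - 1] - m;
        ss += dv * dv;
      }
      double sd = std::sqrt(ss / (nm - 1));
      for (int j = 0; j < nm; ++j)
        zcol[maskidx[j] - 1] = (col[maskidx[j] - 1] - m) / sd;
      const double *zc = zcol.data();
      int best = 0;
      for (int sign = -1; sign <= 1; sign += 2) {
        label_bfs(dlab,
                  [zc, zthr, sign](R_xlen_t i) {
                    return sign > 0 ? (zc[i] > zthr) : (zc[i] < -zthr);
                  },
                  connectivity, labels, sizes);
        for (size_t k = 0; k < sizes.size(); ++k)
          if (sizes[k] > best) best = sizes[k];
      }
      out[done + it] = best;
    }
    done += nb;
  }
  return out;
}
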