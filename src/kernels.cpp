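#include <Rcpp.h>
#include <vector>
#include "rng.h"
#include "conv.h"

using perafr_rng::NormalGen;
using perafr_rng::mix_seed;
using perafr_conv::conv_axis;
using perafr_conv::label_bfs;

// Stationary AR(1) noise, one ROW per voxel (n_vox x n_time):
// x_0 ~ N(0, sd^2), x_t = phi x_{t-1} + e_t, e_t ~ N(0, sd^2 (1 - phi^2)).
// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_ar1_matrix(int n_vox, int n_time, double phi, double sd,
                                   double seed, double stream) {
  NormalGen g(mix_seed(seed, stream));
  Rcpp::NumericMatrix out(n_vox, n_time);
  double innov_sd = sd * std::sqrt(1.0 - phi * phi);
  double *p = out.begin();
  for (int v = 0; v < n_vox; ++v) p[v] = sd * g.next();
  for (int t = 1; t < n_time; ++t) {
    double *cur = p + (R_xlen_t)t * n_vox;
    double *prev = cur - n_vox;
    for (int v = 0; v < n_vox; ++v) cur[v] = phi * prev[v] + innov_sd * g.next();
  }
  return out;
}

// Separable Gaussian smoothing of every frame of a flattened
// (nx, ny, nz, nframes) array; sd given in voxels per axis, sd <= 0 skips
// the axis. Half-sample reflection at boundaries (kernel mass conserved, so
// constants pass through unchanged).
// [[Rcpp::export]]
Rcpp::NumericVector cpp_smooth_frames(Rcpp::NumericVector data,
                                      Rcpp::IntegerVector dims,
                                      Rcpp::NumericVector sd_vox) {
  int d[4] = {dims[0], dims[1], dims[2], dims.size() > 3 ? dims[3] : 1};
  R_xlen_t n = (R_xlen_t)d[0] * d[1] * d[2] * d[3];
  if (n != data.size()) Rcpp::stop("dims do not match data length");
  static std::vector<double> a, b;   // reused scratch; R is single-threaded
  a.assign(data.begin(), data.end());
  b.resize(n);
  for (int axis = 0; axis < 3; ++axis)
    if (sd_vox[axis] > 0) conv_axis(a, b, d, axis, sd_vox[axis]);
  Rcpp::NumericVector out(a.begin(), a.end());
  return out;
}

// Connected components of a binary 3D field (passed flattened, Fortran order).
// Returns labels 0 = background, 1..k in scan order, with component sizes in
// attr "sizes".
// [[Rcpp::export]]
Rcpp::IntegerVector cpp_label_components(Rcpp::LogicalVector field,
                                         Rcpp::IntegerVector dims,
                                         int connectivity) {
  std::vector<int> labels, sizes;
  const int *f = LOGICAL(field);
  int d[3] = {dims[0], dims[1], dims[2]};
  label_bfs(d, [f](R_xlen_t i) { return f[i] == 1; }, connectivity, labels, sizes);
  Rcpp::IntegerVector out(labels.begin(), labels.end());
  out.attr("sizes") = Rcpp::IntegerVector(sizes.begin(), sizes.end());
  return out;
}

// Mean-preserving linear detrend of selected rows of an (nvox x nt) matrix
// (voxel-major layout of a 4D volume). Rows not selected pass through
// unchanged. Column-major streaming, branchless via zeroed slopes.
// [[Rcpp::export]]
Rcpp::NumericVector cpp_detrend_rows(Rcpp::NumericVector data, int nvox, int nt,
                                     Rcpp::IntegerVector rows) {
  std::vector<double> ttc(nt), slope(nvox, 0.0);
  double ss = 0.0;
  for (int t = 0; t < nt; ++t) {
    ttc[t] = (t + 1) - (nt + 1) / 2.0;
    ss += ttc[t] * ttc[t];
  }
  const double *x = data.begin();
  for (int t = 0; t < nt; ++t) {
    const double *col = x + (R_xlen_t)t * nvox;
    double w = ttc[t];
    for (int v = 0; v < nvox; ++v) slope[v] += w * col[v];
  }
  std::vector<char> sel(nvox, 0);
  for (int k = 0; k < rows.size(); ++k) sel[rows[k] - 1] = 1;
  for (int v = 0; v < nvox; ++v) slope[v] = sel[v] ? slope[v] / ss : 0.0;
  Rcpp::NumericVector out(data.size());
  double *o = out.begin();
  for (int t = 0; t < nt; ++t) {
    const double *col = x + (R_xlen_t)t * nvox;
    double *oc = o + (R_xlen_t)t * nvox;
    double w = ttc[t];
    for (int v = 0; v < nvox; ++v) oc[v] = col[v] - slope[v] * w;
  }
  return out;
}

// PerAF (percent) of selected rows of an (nvox x nt) matrix; NA elsewhere
// and for rows whose temporal mean is not strictly positive.
// [[Rcpp::export]]
Rcpp::NumericVector cpp_peraf_rows(Rcpp::NumericVector data, int nvox, int nt,
                                   Rcpp::IntegerVector rows) {
  const double *x = data.begin();
  std::vector<double> mu(nvox, 0.0), mad(nvox, 0.0);
  for (int t = 0; t < nt; ++t) {
    const double *col = x + (R_xlen_t)t * nvox;
    for (int v = 0; v < nvox; ++v) mu[v] += col[v];
  }
  for (int v = 0; v < nvox; ++v) mu[v] /= nt;
  for (int t = 0; t < nt; ++t) {
    const double *col = x + (R_xlen_t)t * nvox;
    for (int v = 0; v < nvox; ++v) mad[v] += std::fabs(col[v] - mu[v]);
  }
  Rcpp::NumericVector out(nvox, NA_REAL);
  for (int k = 0; k < rows.size(); ++k) {
    int v = rows[k] - 1;
    if (mu[v] > 0) out[v] = mad[v] / nt / mu[v] * 100.0;
  }
  return out;
}

// In-place signal assembly: X[vox, t] += m * (1 + a[vox] * s[t]) over the
// given (sorted, 1-based) voxel rows.
// [[Rcpp::export]]
void cpp_add_signal(Rcpp::NumericMatrix X, Rcpp::IntegerVector rows,
                    Rcpp::NumericVector a, Rcpp::NumericVector s, double m) {
  int nvox = X.nrow(), nt = X.ncol(), nr = rows.size();
  double *x = X.begin();
  for (int t = 0; t < nt; ++t) {
    double *col = x + (R_xlen_t)t * nvox;
    double st = s[t];
    for (int k = 0; k < nr; ++k) col[rows[k] - 1] += m * (1.0 + a[k] * st);
  }
}

namespace {

// persistent scratch (R is single-threaded); avoids re-faulting ~18 MB of
// pages on every subject in cohort-scale loops
std::vector<double> g_bufA, g_bufB;

void detrend_buffer(std::vector<double> &a, R_xlen_t nvox, int nt,
                    const int *rows, int nrows) {
  std::vector<double> ttc(nt), slope(nvox, 0.0);
  double ss = 0.0;
  for (int t = 0; t < nt; ++t) {
    ttc[t] = (t + 1) - (nt + 1) / 2.0;
    ss += ttc[t] * ttc[t];
  }
  for (int t = 0; t < nt; ++t) {
    const double *col = a.data() + (R_xlen_t)t * nvox;
    double w = ttc[t];
    for (R_xlen_t v = 0; v < nvox; ++v) slope[v] += w * col[v];
  }
  std::vector<char> sel(nvox, 0);
  for (int k = 0; k < nrows; ++k) sel[rows[k] - 1] = 1;
  for (R_xlen_t v = 0; v < nvox; ++v) slope[v] = sel[v] ? slope[v] / ss : 0.0;
  for (int t = 0; t < nt; ++t) {
    double *col = a.data() + (R_xlen_t)t * nvox;
    double w = ttc[t];
    for (R_xlen_t v = 0; v < nvox; ++v) col[v] -= slope[v] * w;
  }
}

} // namespace

// Fused per-subject chain: discard k leading frames, mean-preserving linear
// detrend of the in-mask voxels, separable Gaussian smoothing of every
// frame, then PerAF of the in-mask voxels. Bitwise-identical to composing
// the individual exported steps; exists to keep cohort-scale Monte-Carlo
// loops inside one allocation-free C++ pass.
// [[Rcpp::export]]
Rcpp::NumericVector cpp_subject_peraf(Rcpp::NumericVector data,
                                      Rcpp::IntegerVector dims, int k,
                                      Rcpp::IntegerVector maskidx,
                                      Rcpp::NumericVector sd_vox) {
  int d2[4] = {dims[0], dims[1], dims[2], dims[3] - k};
  R_xlen_t nvox = (R_xlen_t)d2[0] * d2[1] * d2[2];
  int nt = d2[3];
  if (nt < 3) Rcpp::stop("need at least 3 time points after discard");
  R_xlen_t n2 = nvox * nt;
  g_bufA.resize(n2);
  g_bufB.resize(n2);
  std::copy(data.begin() + k * nvox, data.end(), g_bufA.begin());
  detrend_buffer(g_bufA, nvox, nt, maskidx.begin(), maskidx.size());
  for (int axis = 0; axis < 3; ++axis)
    if (sd_vox[axis] > 0) conv_axis(g_bufA, g_bufB, d2, axis, sd_vox[axis]);
  // PerAF over the mask rows
  std::vector<double> mu(nvox, 0.0), mad(nvox, 0.0);
  for (int t = 0; t < nt; ++t) {
    const double *col = g_bufA.data() + (R_xlen_t)t * nvox;
    for (R_xlen_t v = 0; v < nvox; ++v) mu[v] += col[v];
  }
  for (R_xlen_t v = 0; v < nvox; ++v) mu[v] /= nt;
  for (int t = 0; t < nt; ++t) {
    const double *col = g_bufA.data() + (R_xlen_t)t * nvox;
    for (R_xlen_t v = 0; v < nvox; ++v) mad[v] += std::fabs(col[v] - mu[v]);
  }
  Rcpp::NumericVector out(nvox, NA_REAL);
  for (int j = 0; j < maskidx.size(); ++j) {
    R_xlen_t v = maskidx[j] - 1;
    if (mu[v] > 0) out[v] = mad[v] / nt / mu[v] * 100.0;
  }
  return out;
}

// Fully fused synthetic-subject chain: stationary AR(1) noise for every
// voxel (identical draw order to cpp_ar1_matrix), oscillatory signal added
// over the in-mask rows, then discard, mean-preserving detrend, smoothing,
// PerAF. Exists so cohort-scale Monte-Carlo loops allocate nothing per
// subject; single-precision working buffers (the composed double path is
// the reference; tests pin agreement at float tolerance). Discarded leading
// frames are generated (to keep the RNG stream identical to
// cpp_ar1_matrix) but never stored.
// [[Rcpp::export]]
Rcpp::NumericVector cpp_simulate_subject_peraf(
    Rcpp::IntegerVector dims, double phi, double noise_sd, double baseline,
    Rcpp::IntegerVector maskidx, Rcpp::NumericVector a_mask,
    Rcpp::NumericVector s, int k, Rcpp::NumericVector sd_vox,
    double seed, double stream) {
  int nt = dims[3];
  R_xlen_t nvox = (R_xlen_t)dims[0] * dims[1] * dims[2];
  int d2[4] = {dims[0], dims[1], dims[2], nt - k};
  int nt2 = d2[3];
  R_xlen_t n2 = nvox * (R_xlen_t)nt2;
  int nm = maskidx.size();
  static std::vector<float> bufA, bufB;
  static std::vector<double> state;
  bufA.resize(n2);
  bufB.resize(n2);
  state.assign(nvox, 0.0);
  NormalGen g(mix_seed(seed, stream));
  double innov_sd = noise_sd * std::sqrt(1.0 - phi * phi);
  for (int t = 0; t < nt; ++t) {
    if (noise_sd > 0) {
      if (t == 0)
        for (R_xlen_t v = 0; v < nvox; ++v) state[v] = noise_sd * g.next();
      else
        for (R_xlen_t v = 0; v < nvox; ++v)
          state[v] = phi * state[v] + innov_sd * g.next();
    }
    if (t < k) continue;                      // discarded frame: RNG only
    float *col = bufA.data() + (R_xlen_t)(t - k) * nvox;
    for (R_xlen_t v = 0; v < nvox; ++v) col[v] = (float)state[v];
    double st = s[t];
    for (int j = 0; j < nm; ++j)
      col[maskidx[j] - 1] += (float)(baseline * (1.0 + a_mask[j] * st));
  }
  // mean-preserving detrend of the in-mask rows (double accumulators)
  {
    std::vector<double> ttc(nt2), slope(nvox, 0.0);
    double ss = 0.0;
    for (int t = 0; t < nt2; ++t) {
      ttc[t] = (t + 1) - (nt2 + 1) / 2.0;
      ss += ttc[t] * ttc[t];
    }
    for (int t = 0; t < nt2; ++t) {
      const float *col = bufA.data() + (R_xlen_t)t * nvox;
      double w = ttc[t];
      for (R_xlen_t v = 0; v < nvox; ++v) slope[v] += w * col[v];
    }
    std::vector<char> sel(nvox, 0);
    for (int j = 0; j < nm; ++j) sel[maskidx[j] - 1] = 1;
    for (R_xlen_t v = 0; v < nvox; ++v) slope[v] = sel[v] ? slope[v] / ss : 0.0;
    for (int t = 0; t < nt2; ++t) {
      float *col = bufA.data() + (R_xlen_t)t * nvox;
      double w = ttc[t];
      for (R_xlen_t v = 0; v < nvox; ++v) col[v] -= (float)(slope[v] * w);
    }
  }
  for (int axis = 0; axis < 3; ++axis)
    if (sd_vox[axis] > 0) conv_axis(bufA, bufB, d2, axis, sd_vox[axis]);
  std::vector<double> mu(nvox, 0.0), mad(nvox, 0.0);
  for (int t = 0; t < nt2; ++t) {
    const float *col = bufA.data() + (R_xlen_t)t * nvox;
    for (R_xlen_t v = 0; v < nvox; ++v) mu[v] += col[v];
  }
  for (R_xlen_t v = 0; v < nvox; ++v) mu[v] /= nt2;
  for (int t = 0; t < nt2; ++t) {
    const float *col = bufA.data() + (R_xlen_t)t * nvox;
    for (R_xlen_t v = 0; v < nvox; ++v) mad[v] += std::fabs(col[v] - mu[v]);
  }
  Rcpp::NumericVector out(nvox, NA_REAL);
  for (int j = 0; j < nm; ++j) {
    R_xlen_t v = maskidx[j] - 1;
    if (mu[v] > 0) out[v] = mad[v] / nt2 / mu[v] * 100.0;
  }
  return out;
}
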