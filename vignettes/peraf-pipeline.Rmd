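---
title: "The PerAF group-analysis pipeline: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The PerAF group-analysis pipeline: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perafr)
```

## The metric

Percent amplitude of fluctuation (PerAF) summarizes a BOLD voxel time series
$x_1, \dots, x_n$ as the mean absolute deviation from its temporal mean,
expressed as a percentage of that mean:

$$\mathrm{PerAF} = \frac{1}{n}\sum_{i=1}^{n}\left|\frac{x_i - \mu}{\mu}\right|
\times 100, \qquad \mu = \frac{1}{n}\sum_{i=1}^n x_i.$$

Because the deviation is measured relative to the voxel's own mean, PerAF is
invariant to per-voxel scanner gain: `peraf_series(c * x)` equals
`peraf_series(x)` for any $c > 0$. It is *not* invariant to global
between-subject differences in fluctuation amplitude, which is the point —
those differences are the signal at the ROI level. For voxel-wise group
statistics we additionally offer the mean-standardized variant (mPerAF), the
map divided by its within-mask mean, which removes inter-subject global
amplitude offsets the way grand-mean scaling does in intensity-based
analyses.

A voxel whose temporal mean is not strictly positive has no meaningful PerAF;
such voxels are recorded as `NA`, dropped from the mask, and counted in the
run log. They are never imputed.

### Which variant feeds which analysis

`run_pipeline()` uses **mPerAF for the voxel-wise t contrast** (default
`use_mperaf = TRUE`) and **raw PerAF for ROI-level ROC and brain–behavior
correlation**. The split is deliberate. mPerAF removes exactly the global
per-subject amplitude factor; at the voxel level that factor is a nuisance
that would otherwise inflate between-subject variance everywhere. At the ROI
level, however, group discrimination and correlation with behavioral scores
run on between-subject amplitude differences — standardizing them away makes
the ROC degenerate (we measured AUC pinned at 1.0 under mPerAF, because the
only variance left is measurement noise) and destroys the correlation signal.

## The pipeline

For each subject, in a fixed order:

1. **Initial-volume discard** (`discard_k = 10`): the leading volumes are
   dropped so analysis starts at magnetization steady state.
2. **Motion screening** (`motion_thresh_mm = 3`): a subject whose per-volume
   maximum displacement strictly exceeds 3 mm is excluded. The rule is read
   as strict ("over 3 mm"), so a subject at exactly 3.0 mm is kept; the
   boundary behavior is pinned by a test. Realignment itself is out of scope
   — synthetic cohorts are motion-free and the trace is an input.
3. **Mean-preserving linear detrend**: the per-voxel OLS slope over time is
   removed, and only the slope. The trend component is constructed with zero
   temporal mean, so the voxel mean $\mu$ — the denominator of PerAF — is
   preserved exactly (assertable per voxel, and asserted).
   A conventional detrend that recenters the series to zero would make PerAF
   undefined.
4. **Gaussian smoothing** (`fwhm_mm = 6` at 3 mm voxels): separable Gaussian
   convolution per frame, kernel SD $= \mathrm{FWHM}/(2\sqrt{2\ln 2})$ per
   axis in mm, truncated at 4 SD and renormalized. Boundaries use
   half-sample reflection, which conserves kernel mass (constants pass
   through unchanged and the frame sum is conserved to 0.1%). Smoothing is
   applied to the 4D data before PerAF by default; `smooth_stage = "map"`
   smooths the subject maps instead.
5. **PerAF map**, optionally mean-standardized.

Group analysis then computes the pooled-variance two-sample t per voxel
(patients minus controls, so positive t means patients higher), estimates the
residual spatial smoothness, simulates the Monte-Carlo null distribution of
maximum cluster extent at the cluster-forming threshold, extracts signed
suprathreshold clusters, and keeps those reaching the extent threshold.

### Cluster-extent correction

The correction is the Monte-Carlo (AlphaSim-style) procedure: simulate
in-mask Gaussian white noise, smooth it to the estimated residual FWHM,
re-standardize within the mask, threshold two-tailed at the cluster-forming
p (`p_voxel = 0.005`), and record the maximum connected-component size over
both signs. The extent threshold at level $\alpha$ is
$\lceil q_{1-\alpha} \rceil + 1$ of these maxima — strictly larger than the
$(1-\alpha)$-quantile — so a surviving cluster occurs under the null with
probability at most $\alpha$. Corrected per-cluster p values are the
fraction of null maxima at least as large.

Choices worth stating:

* **Connectivity** defaults to 18 neighbors (faces + edges), the convention
  of the REST/AlphaSim family this pipeline descends from; 6 and 26 are
  available and the labelling is cross-checked against a flood-fill oracle
  for all three.
* **Signs are pooled into one null** (the maximum is taken over positive and
  negative excursions) because increases and decreases are reported at a
  single stated threshold; positive and negative clusters never merge.
* **Smoothness input**: the residual FWHM per axis is estimated from
  group-demeaned subject maps with the classical first-differences
  estimator
  $\mathrm{FWHM} = v\sqrt{-2\ln 2 / \ln(1 - \mathrm{var}(\Delta)/(2\,\mathrm{var}))}$.
  The estimate is floored at the voxel size: as data approach spatial
  whiteness the ratio approaches 1 and the formula collapses toward zero,
  but sub-voxel smoothness is not resolvable on the grid and would make the
  extent simulation anti-conservative in a meaningless regime. Rougher-than-
  white axes fall back to the voxel size with a warning.
* **Memoization**: the null depends on the analysis geometry, not the data,
  so `run_pipeline()` caches it per configuration with the smoothness input
  binned to 0.25 mm. This follows the lookup-table practice of the AlphaSim
  tables shipped with REST (binned per integer mm) while being finer; it
  makes repeated analyses over the same geometry pay for the Monte-Carlo
  null once. `simulate_cluster_null()` itself is exact and uncached.
* The t map is thresholded by its exact Student p values; the null field is
  Gaussian, per the AlphaSim convention.

### ROI-level statistics

`roi_mean()` averages the map over the labelled in-mask voxels. AUC is the
rank (Mann–Whitney) statistic with ties counted half, identical to the
trapezoidal area under the empirical ROC curve (both are tested against an
exhaustive pair-counting oracle). Scores are auto-oriented so the reported
AUC is at least 0.5, with the flip recorded — regions with decreased and
increased amplitude are both reported as discriminative, implying
direction-per-region orientation. The 95% CI is a stratified bootstrap
percentile interval (`n_boot = 2000`, seeded); DeLong's asymptotic interval
is available as `ci_method = "delong"`. Pearson correlations use the exact
t transform for the two-tailed p. Correlations default to the patient group
(`correlation_group = "patient"`), matching the clinical design in which
behavioral scores are analysed within patients.

The pooled (not Welch) two-sample t is used throughout, including
`summary_t()` for mean ± SD summary tables: pooled is the convention that
reproduces tabulated summary-table t values from printed group summaries.

## The synthetic cohort generator

No scan data are distributable, so `generate_cohort()` stands in for the
study cohort: two groups of 17, a 24 × 24 × 18 grid of 3 mm voxels, 240
volumes at TR = 2 s, an ellipsoidal brain mask, and three 27-voxel cubic
ROIs — two with amplitude reduced in patients (multiplier $1/1.5$) and one
increased ($1.5$), mirroring a study design with two hypoactive regions and
one hyperactive one.

Each in-mask voxel follows

$$x_t = m\,(1 + a_v\, s_t) + \varepsilon_t,$$

with baseline $m = 1000$, voxel amplitude fraction $a_v$ (base 0.03, times
the ROI multiplier, times a per-subject lognormal factor with
$\sigma_{\log} = 0.1$), a band-limited oscillation $s_t$ (default five
equal-amplitude sinusoids with frequencies uniform in 0.01–0.08 Hz and
random phases), and stationary AR(1) Gaussian noise $\varepsilon_t$
($\phi = 0.3$, SD 1% of baseline). Out-of-mask voxels carry zero-mean noise
only. Everything is a deterministic function of the configuration seed; each
subject has an independent derived stream.

Numerical and design notes:

* **Signal normalization.** The multi-sinusoid signal is normalized to the
  RMS of a unit-amplitude sinusoid ($1/\sqrt 2$), not to unit peak. Peak
  normalization ties the realized fluctuation amplitude to the random
  waveform's crest factor, which varies enough between subjects to swamp the
  deliberate 10% amplitude jitter — in measurements it pushed ROI AUC down
  to ~0.76 through pure waveform lottery and made phenotype correlations
  unrecoverable from measured PerAF. RMS normalization keeps amplitudes
  comparable across subjects; with `fixed_frequency_hz` set, the signal is a
  single pure sinusoid of unit amplitude and the noise-free analytic limit
  $\mathrm{PerAF} = 100\,a_v\,(2/\pi)$ holds.
* **Analytic limit discretization.** The $2/\pi$ limit is the continuous-time
  mean of $|\sin|$; sampling $m$ points per cycle leaves a deficit of
  $\pi^2/(3m^2)$ relative. At 100 samples per cycle this is 0.03%; tests of
  the limit use fine sampling over at least 10 full cycles so the deficit is
  far inside the 0.5% tolerance band. Coarse sampling (e.g. 10 samples per
  cycle) would by itself violate the band — a property of discretization,
  not of the implementation.
* **Per-subject amplitude jitter** exists so that group discrimination is
  non-degenerate: without between-subject amplitude variance the ROC would
  be trivially perfect. It multiplies $a_v$ globally, which is exactly why
  mPerAF (which cancels global factors) cannot feed the ROC.
* **Phenotypes.** A score linked to ROI $k$ with target correlation $r$ is
  $y_s = \mu_y + \sigma_y\,(r z_s + \sqrt{1-r^2}\,\eta_s)$, where $z_s$
  standardizes the subject's true ROI amplitude over the whole cohort and
  $\eta_s$ is independent Gaussian noise; integer rounding and range bounds
  (HADS subscores live in 0–21) are applied last. Default models use the
  questionnaire table shipped in `inst/extdata` for the anxiety/depression
  means and SDs, correlation magnitudes in the 0.73–0.81 range for the
  linked scores, and independent draws for demographics. Because $z_s$ is
  standardized cohort-wide while the linked ROI amplitude differs by group,
  the patients-only sample correlation is attenuated relative to the
  cohort-wide target — a structural property of the model, visible in the
  pipeline's patient-group correlation report.

### What the generator does and does not emulate

It emulates: group-wise regional amplitude effects of realistic spatial
extent (a 27-voxel cube smoothed at 6 mm yields surviving clusters of
roughly 100–190 voxels, the same order as typical reported cluster tables),
low-frequency band-limited oscillations, temporally autocorrelated noise,
between-subject amplitude variability, and behavioral scores with controlled
correlation to regional amplitude.

It does not emulate: hemodynamic response shape, cardiac/respiratory
physiological noise, motion inside the volumes (motion is a per-subject
scalar trace feeding the exclusion rule only), spatial normalization
artifacts, anatomical tissue contrast, or field inhomogeneity. Passing tests
therefore demonstrate the statistical machinery — calibration of the cluster
correction, recovery of planted effects, correctness of every estimator —
not robustness to the full physics of real acquisitions.

## Verification strategy and problem sizes

Every statistical primitive is pinned to an independent oracle: PerAF to a
literal term-by-term transcription of its definition (1e-12), the smoother
to a dense reflect-padded kernel matrix (1e-12), cluster labelling to a
flood-fill oracle, AUC to pair counting and trapezoid quadrature, the
voxel-wise t to the scalar pooled-summary formula at every voxel, and our
AUC/DeLong interval to an established ROC implementation.

The calibration suite runs at the study scale: family-wise error is
estimated over 200 independent null cohorts (no planted effects, defaults,
1000-iteration extent null, p < 0.005, α = 0.05) and must lie in
[0.01, 0.12]; planted-effect recovery uses 20 cohorts and requires the
increased ROI to host a surviving cluster peak in at least 90%; linked
phenotype recovery uses 400 generator draws. These sizes are the package's
chosen trade-off between Monte-Carlo resolution and suite runtime; the
measured false-positive rate in development was 0.055.

Two implementation paths exist for simulated subjects: the composed module
chain (`simulate_subject_bold()` → `discard_initial_volumes()` →
`detrend_linear()` → `smooth_gaussian()` → `peraf_map()`), all in double
precision, and a fused single-pass C++ chain used by `run_pipeline()` for
cohort-scale Monte-Carlo work, which keeps its working buffers in single
precision. The fused path is pinned to the composed path at float tolerance
(~1e-6 relative) by tests; all worked-example and oracle tests run through
the composed double path.

## Limitations

* The extent correction assumes stationary Gaussian-like residual
  smoothness; strongly non-stationary real data would need a non-stationary
  correction, which is out of scope.
* The smoothness estimator is the classical first-differences one; it floors
  at the voxel size and is not intended to resolve sub-voxel smoothness.
* The generator's phenotype link is linear-Gaussian; nonlinear
  brain–behavior relationships are not modelled.
* Spatial normalization, realignment and slice-timing are accepted as
  already done (or unnecessary, for synthetic data); the pipeline starts at
  volume discard.

## A worked run

```{r, eval = FALSE}
library(perafr)
cfg <- cohort_config(seed = 42)          # 17 + 17, three planted ROIs
res <- run_pipeline(cfg, pipeline_config(seed = 42))
res
res$clusters_corrected
subset(res$roi_report, roi_id == 1,
       select = c(auc, auc_ci_low, auc_ci_high, phenotype, r, p))
```
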