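#' Planted regional amplitude effect
#'
#' Describes one region of interest whose BOLD fluctuation amplitude is
#' multiplied by a constant in one group, emulating a regional increase
#' (multiplier > 1) or decrease (multiplier < 1) of spontaneous activity.
#'
#' @param roi_id Positive integer label, unique within a cohort.
#' @param roi_voxels Integer matrix (n x 3) of 1-based voxel coordinates.
#' @param group Which group carries the effect, `"patient"` or `"control"`.
#' @param amplitude_multiplier Positive real; 1.5 means 50% larger fluctuation
#'   amplitude in the affected group.
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(roi_id, roi_voxels, group = c("patient", "control"),
                        amplitude_multiplier = 1.5) {
  group <- match.arg(group)
  roi_voxels <- matrix(as.integer(round(roi_voxels)), ncol = 3)
  if (nrow(roi_voxels) == 0L) stop("'roi_voxels' must be non-empty")
  if (!is.numeric(roi_id) || length(roi_id) != 1L || roi_id < 1)
    stop("'roi_id' must be a single positive integer")
  if (!is.numeric(amplitude_multiplier) || amplitude_multiplier <= 0)
    stop("'amplitude_multiplier' must be positive")
  structure(list(roi_id = as.integer(roi_id), roi_voxels = roi_voxels,
                 group = group, amplitude_multiplier = amplitude_multiplier),
            class = "effect_spec")
}

#' Cubic ROI voxel set
#'
#' @param center Integer voxel coordinate (length 3) of the cube centre.
#' @param width Odd cube edge length in voxels (default 3, i.e. 27 voxels).
#' @return Integer matrix of voxel coordinates.
#' @export
cube_roi <- function(center, width = 3) {
  if (width %% 2 != 1) stop("'width' must be odd")
  h <- (width - 1) / 2
  g <- expand.grid(x = center[1] + (-h):h, y = center[2] + (-h):h,
                   z = center[3] + (-h):h)
  as.matrix(g)
}

#' Behavioral phenotype model
#'
#' Defines one per-subject score. When linked to an effect ROI, scores are
#' generated with a specified population correlation to the subject's true
#' regional fluctuation amplitude:
#' \eqn{y_s = \mu + \sigma (r z_s + \sqrt{1 - r^2}\, \eta_s)}, where
#' \eqn{z_s} is the standardized true ROI amplitude and \eqn{\eta_s} is
#' independent standard Gaussian noise. Rounding and bounds are applied last.
#'
#' @param name Column name, e.g. `"anxiety_score"`.
#' @param linked_roi_id ROI label the score tracks, or `NULL` for an
#'   independent draw.
#' @param target_r Population correlation in \[-1, 1\] with the linked ROI
#'   amplitude.
#' @param mean,sd Marginal mean and standard deviation (sd > 0).
#' @param rounding `"none"` or `"integer"`.
#' @param lower,upper Optional bounds applied after rounding.
#' @return An object of class `phenotype_model`.
#' @export
phenotype_model <- function(name, linked_roi_id = NULL, target_r = 0,
                            mean = 0, sd = 1,
                            rounding = c("none", "integer"),
                            lower = -Inf, upper = Inf) {
  rounding <- match.arg(rounding)
  if (abs(target_r) > 1) stop("'target_r' must lie in [-1, 1]")
  if (sd <= 0) stop("'sd' must be positive")
  structure(list(name = name, linked_roi_id = linked_roi_id,
                 target_r = target_r, mean = mean, sd = sd,
                 rounding = rounding, lower = lower, upper = upper),
            class = "phenotype_model")
}

#' Default planted effects
#'
#' Three 27-voxel cubic ROIs emulating the cohort design this generator stands
#' in for: two regions with reduced fluctuation amplitude in patients and one
#' with increased amplitude.
#'
#' @param grid_shape Voxel grid dimensions.
#' @param amplitude_multiplier Effect strength of the increased region; the
#'   decreased regions use its reciprocal.
#' @return List of [effect_spec()] objects with ROI ids 1-3.
#' @export
default_effects <- function(grid_shape = c(24, 24, 18),
                            amplitude_multiplier = 1.5) {
  ctr <- round(grid_shape / 2)
  off <- pmax(3L, round(grid_shape[1:2] * 0.19))
  list(
    effect_spec(1L, cube_roi(c(ctr[1] - off[1], ctr[2] - off[2], ctr[3])),
                group = "patient", amplitude_multiplier = 1 / amplitude_multiplier),
    effect_spec(2L, cube_roi(c(ctr[1] + off[1], ctr[2] - off[2], ctr[3])),
                group = "patient", amplitude_multiplier = 1 / amplitude_multiplier),
    effect_spec(3L, cube_roi(c(ctr[1], ctr[2] + off[2], ctr[3])),
                group = "patient", amplitude_multiplier = amplitude_multiplier)
  )
}

#' Default behavioral phenotype models
#'
#' Anxiety and depression scores (HADS-style, integer 0-21) and left/right
#' retinal nerve fiber layer thickness linked to ROI 1 with correlation
#' magnitudes in the 0.73-0.81 range typical of strong clinical
#' brain-behavior associations, plus independent demographic and ocular
#' covariates. HADS means and
#' standard deviations are taken from the packaged questionnaire table
#' ([hads_fixture()]).
#'
#' @return List of [phenotype_model()] objects.
#' @export
default_phenotypes <- function() {
  hads <- hads_fixture()
  list(
    phenotype_model("anxiety_score", linked_roi_id = 1L, target_r = -0.772,
                    mean = mean(hads$anxiety_score), sd = sd(hads$anxiety_score),
                    rounding = "integer", lower = 0, upper = 21),
    phenotype_model("depression_score", linked_roi_id = 1L, target_r = -0.806,
                    mean = mean(hads$depression_score), sd = sd(hads$depression_score),
                    rounding = "integer", lower = 0, upper = 21),
    phenotype_model("rnflt_left", linked_roi_id = 1L, target_r = 0.727,
                    mean = 126.09, sd = 18.95, lower = 0),
    phenotype_model("rnflt_right", linked_roi_id = 1L, target_r = 0.748,
                    mean = 127.91, sd = 18.47, lower = 0),
    phenotype_model("age", mean = 50.0, sd = 5.4, rounding = "integer",
                    lower = 18, upper = 60),
    phenotype_model("weight", mean = 60.7, sd = 7.4, lower = 30),
    phenotype_model("iop_left", mean = 15.0, sd = 1.5, lower = 5),
    phenotype_model("iop_right", mean = 15.6, sd = 1.6, lower = 5),
    phenotype_model("va_left", mean = 0.026, sd = 0.014, lower = 0),
    phenotype_model("va_right", mean = 0.064, sd = 0.019, lower = 0)
  )
}

#' Synthetic cohort configuration
#'
#' Full description of a two-group synthetic resting-state cohort: grid and
#' acquisition geometry, the voxel signal model, planted regional effects, and
#' behavioral phenotype models. Every in-mask voxel time series is
#' \deqn{x_t = m (1 + a_v s_t) + \epsilon_t,} where \eqn{m} is the baseline
#' mean, \eqn{s_t} a band-limited oscillation (sum of `n_oscillators`
#' equal-amplitude sinusoids with random frequencies in the band and random
#' phases, normalized to the RMS of a unit-amplitude sinusoid so realized
#' amplitudes are comparable across subjects; or a single unit-amplitude
#' fixed-frequency sinusoid),
#' \eqn{a_v} the voxel amplitude fraction (base fraction, times the effect
#' multiplier inside an affected ROI, times a per-subject lognormal factor),
#' and \eqn{\epsilon_t} stationary AR(1) Gaussian noise.
#'
#' @param n_per_group Subjects per group (default 17).
#' @param grid_shape Voxel grid (default 24 x 24 x 18).
#' @param voxel_size_mm Voxel size in mm (default 3).
#' @param n_timepoints Acquired volumes before any discard (default 240).
#' @param tr_seconds Repetition time (default 2).
#' @param baseline_mean Baseline BOLD intensity (default 1000).
#' @param oscillation_band_hz Low/high frequency bounds of the oscillatory
#'   signal (default 0.01-0.08 Hz); must satisfy
#'   `0 <= low < high < 1/(2 tr_seconds)`.
#' @param base_amplitude_fraction Oscillation amplitude as a fraction of
#'   baseline (default 0.03).
#' @param noise_sd_fraction Stationary noise SD as a fraction of baseline
#'   (default 0.01).
#' @param ar1_coefficient Temporal autocorrelation of the noise in \[0, 1)
#'   (default 0.3).
#' @param n_oscillators Sinusoids summed into the band-limited signal
#'   (default 5).
#' @param fixed_frequency_hz If non-`NULL`, replaces the random band-limited
#'   signal with a single zero-phase sinusoid at this frequency - the
#'   noise-free analytic limit in which PerAF equals
#'   \eqn{100 a_v \cdot 2/\pi}.
#' @param subject_amplitude_sdlog SD (log scale) of the per-subject lognormal
#'   amplitude factor (default 0.1); without between-subject variance, group
#'   discrimination would be degenerate.
#' @param effects List of [effect_spec()]; ROIs must lie inside the grid and
#'   not overlap.
#' @param phenotypes List of [phenotype_model()].
#' @param seed Integer seed; the entire cohort is a deterministic function of
#'   the configuration.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = 17,
                          grid_shape = c(24, 24, 18),
                          voxel_size_mm = c(3, 3, 3),
                          n_timepoints = 240,
                          tr_seconds = 2,
                          baseline_mean = 1000,
                          oscillation_band_hz = c(0.01, 0.08),
                          base_amplitude_fraction = 0.03,
                          noise_sd_fraction = 0.01,
                          ar1_coefficient = 0.3,
                          n_oscillators = 5,
                          fixed_frequency_hz = NULL,
                          subject_amplitude_sdlog = 0.1,
                          effects = default_effects(grid_shape),
                          phenotypes = default_phenotypes(),
                          seed = 1) {
  stopifnot(n_per_group >= 1, n_timepoints >= 2, all(grid_shape >= 1),
            length(grid_shape) == 3, all(voxel_size_mm > 0),
            tr_seconds > 0, baseline_mean > 0,
            base_amplitude_fraction >= 0, noise_sd_fraction >= 0,
            n_oscillators >= 1, subject_amplitude_sdlog >= 0)
  if (ar1_coefficient < 0 || ar1_coefficient >= 1)
    stop("'ar1_coefficient' must lie in [0, 1)")
  b <- oscillation_band_hz
  nyquist <- 1 / (2 * tr_seconds)
  if (length(b) != 2 || b[1] < 0 || b[1] >= b[2] || b[2] >= nyquist)
    stop("'oscillation_band_hz' must satisfy 0 <= low < high < 1/(2 TR); ",
         "Nyquist is ", signif(nyquist, 4), " Hz")
  if (!is.null(fixed_frequency_hz) &&
      (fixed_frequency_hz <= 0 || fixed_frequency_hz >= nyquist))
    stop("'fixed_frequency_hz' must lie in (0, Nyquist)")
  seen <- NULL
  for (ef in effects) {
    if (!inherits(ef, "effect_spec")) stop("'effects' must be effect_spec objects")
    v <- ef$roi_voxels
    if (any(v < 1) || any(v[, 1] > grid_shape[1]) || any(v[, 2] > grid_shape[2]) ||
        any(v[, 3] > grid_shape[3]))
      stop("ROI ", ef$roi_id, " extends outside the ",
           paste(grid_shape, collapse = "x"), " grid")
    lin <- v[, 1] + (v[, 2] - 1) * grid_shape[1] +
      (v[, 3] - 1) * grid_shape[1] * grid_shape[2]
    if (any(lin %in% seen)) stop("effect ROIs overlap")
    seen <- c(seen, lin)
  }
  ids <- vapply(effects, function(e) e$roi_id, integer(1))
  if (anyDuplicated(ids)) stop("duplicate effect ROI ids")
  for (ph in phenotypes) {
    if (!inherits(ph, "phenotype_model"))
      stop("'phenotypes' must be phenotype_model objects")
    if (!is.null(ph$linked_roi_id) && !(ph$linked_roi_id %in% ids))
      stop("phenotype '", ph$name, "' links to unknown ROI ", ph$linked_roi_id)
  }
  structure(list(n_per_group = as.integer(n_per_group),
                 grid_shape = as.integer(grid_shape),
                 voxel_size_mm = voxel_size_mm,
                 n_timepoints = as.integer(n_timepoints),
                 tr_seconds = tr_seconds, baseline_mean = baseline_mean,
                 oscillation_band_hz = b,
                 base_amplitude_fraction = base_amplitude_fraction,
                 noise_sd_fraction = noise_sd_fraction,
                 ar1_coefficient = ar1_coefficient,
                 n_oscillators = as.integer(n_oscillators),
                 fixed_frequency_hz = fixed_frequency_hz,
                 subject_amplitude_sdlog = subject_amplitude_sdlog,
                 effects = effects, phenotypes = phenotypes,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Label volume and brain mask for a synthetic cohort
#'
#' The "brain" is an ellipsoid inscribed in the grid (semi-axes
#' `(grid_shape - 3) / 2`), extended to contain every effect ROI; the label
#' volume is 0 outside ROIs and carries each `effect_spec` ROI id exactly
#' once.
#'
#' @param config A [cohort_config()].
#' @return List with `labels` (3D integer array) and `mask` (3D logical).
#' @export
generate_label_volume <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  d <- config$grid_shape
  ctr <- (d + 1) / 2
  semi <- pmax((d - 3) / 2, 1)
  gx <- ((seq_len(d[1]) - ctr[1]) / semi[1])^2
  gy <- ((seq_len(d[2]) - ctr[2]) / semi[2])^2
  gz <- ((seq_len(d[3]) - ctr[3]) / semi[3])^2
  mask <- outer(outer(gx, gy, "+"), gz, "+") <= 1
  labels <- array(0L, d)
  for (ef in config$effects) {
    v <- ef$roi_voxels
    labels[v] <- ef$roi_id
    mask[v] <- TRUE
  }
  list(labels = labels, mask = mask)
}

# unit-peak band-limited oscillation for one subject (deterministic given the
# derived seed)
make_oscillation <- function(config, stream) {
  t_sec <- (seq_len(config$n_timepoints) - 1) * config$tr_seconds
  if (!is.null(config$fixed_frequency_hz))
    return(sin(2 * pi * config$fixed_frequency_hz * t_sec))
  with_local_seed(derive_seed(config$seed, stream), {
    f <- runif(config$n_oscillators, config$oscillation_band_hz[1],
               config$oscillation_band_hz[2])
    ph <- runif(config$n_oscillators, 0, 2 * pi)
    s <- rowSums(sin(outer(t_sec, 2 * pi * f) +
                       matrix(ph, config$n_timepoints, length(ph), byrow = TRUE)))
    # normalize to the RMS of a unit-amplitude sinusoid (1/sqrt(2)) so the
    # realized fluctuation amplitude is comparable across subjects and does
    # not depend on the random waveform's crest factor
    s / (sqrt(mean(s^2)) * sqrt(2))
  })
}

# deterministic per-subject signal ingredients shared by the materialized and
# fused simulation paths: oscillation, amplitude field, true ROI amplitudes
subject_signal_params <- function(config, subject_index, group) {
  stream <- subject_index + config$n_per_group * (group == "control")
  s <- make_oscillation(config, stream * 7 + 1)
  factor_s <- if (config$subject_amplitude_sdlog > 0)
    with_local_seed(derive_seed(config$seed, stream * 7 + 2),
                    rlnorm(1, 0, config$subject_amplitude_sdlog))
  else 1
  d <- config$grid_shape
  a_v <- rep(config$base_amplitude_fraction * factor_s, prod(d))
  true_amp <- numeric(0)
  for (ef in config$effects) {
    mult <- if (ef$group == group) ef$amplitude_multiplier else 1
    v <- ef$roi_voxels
    lin <- v[, 1] + (v[, 2] - 1) * d[1] + (v[, 3] - 1) * d[1] * d[2]
    a_v[lin] <- config$base_amplitude_fraction * factor_s * mult
    true_amp[as.character(ef$roi_id)] <-
      config$base_amplitude_fraction * factor_s * mult
  }
  list(stream = stream, s = s, subject_factor = factor_s, a_v = a_v,
       true_roi_amplitude = true_amp)
}

#' Simulate one subject's 4D BOLD volume
#'
#' In-mask voxels follow the signal model described in [cohort_config()];
#' out-of-mask voxels contain zero-mean AR(1) noise only. Deterministic given
#' the configuration seed, subject index, and group.
#'
#' @param config A [cohort_config()].
#' @param subject_index Subject number within the group (1-based).
#' @param group `"patient"` or `"control"`.
#' @param geometry Optional precomputed [generate_label_volume()] output,
#'   to avoid recomputation across subjects.
#' @return List with `bold` ([bold4d()]), `true_roi_amplitude` (named vector
#'   of the subject's true amplitude fraction per effect ROI), and
#'   `subject_factor`.
#' @export
simulate_subject_bold <- function(config, subject_index,
                                  group = c("patient", "control"),
                                  geometry = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  group <- match.arg(group)
  subject_index <- as.integer(subject_index)
  if (subject_index < 1L || subject_index > config$n_per_group)
    stop("'subject_index' must be in 1..n_per_group")
  if (is.null(geometry)) geometry <- generate_label_volume(config)
  d <- config$grid_shape
  nt <- config$n_timepoints
  nvox <- prod(d)
  p <- subject_signal_params(config, subject_index, group)

  noise_sd <- config$noise_sd_fraction * config$baseline_mean
  X <- if (noise_sd > 0)
    cpp_ar1_matrix(nvox, nt, config$ar1_coefficient, noise_sd,
                   config$seed, p$stream * 7 + 3)
  else matrix(0, nvox, nt)
  inm <- which(geometry$mask)
  cpp_add_signal(X, as.integer(inm), p$a_v[inm], p$s, config$baseline_mean)
  dim(X) <- c(d, nt)
  list(bold = bold4d(X, tr_seconds = config$tr_seconds,
                     voxel_size_mm = config$voxel_size_mm),
       true_roi_amplitude = p$true_roi_amplitude,
       subject_factor = p$subject_factor)
}

#' Generate behavioral phenotypes for a cohort
#'
#' Scores linked to an effect ROI are drawn with the specified population
#' correlation to the subjects' true regional amplitudes (standardized over
#' the whole cohort); unlinked scores are independent Gaussian draws.
#' Rounding and bounds are applied last.
#'
#' @param config A [cohort_config()].
#' @param true_amplitudes Numeric matrix (subjects x ROIs, columns named by
#'   ROI id) of true amplitude fractions, as produced by [generate_cohort()].
#' @param subjects Data frame with columns `id` and `group`.
#' @return Data frame: `id`, `group`, `sex`, plus one column per phenotype
#'   model.
#' @export
generate_phenotypes <- function(config, true_amplitudes, subjects) {
  stopifnot(inherits(config, "cohort_config"))
  n <- nrow(subjects)
  out <- subjects
  npg <- config$n_per_group
  n_male <- max(1L, round(npg * 3 / 17))   # study-like ~3:14 sex ratio
  out$sex <- rep(c(rep("male", n_male), rep("female", npg - n_male)), 2)[seq_len(n)]
  for (k in seq_along(config$phenotypes)) {
    ph <- config$phenotypes[[k]]
    eta <- with_local_seed(derive_seed(config$seed, 9000 + k), rnorm(n))
    if (!is.null(ph$linked_roi_id)) {
      roi <- as.character(ph$linked_roi_id)
      if (!roi %in% colnames(true_amplitudes))
        stop("phenotype '", ph$name, "' links to unknown ROI ", roi)
      z <- as.vector(scale(true_amplitudes[, roi]))
      y <- ph$mean + ph$sd * (ph$target_r * z +
                                sqrt(1 - ph$target_r^2) * eta)
    } else {
      y <- ph$mean + ph$sd * eta
    }
    if (ph$rounding == "integer") y <- round(y)
    y <- pmin(pmax(y, ph$lower), ph$upper)
    out[[ph$name]] <- y
  }
  out
}

#' Generate a complete synthetic cohort
#'
#' Deterministic given the configuration: BOLD volumes for both groups, brain
#' mask and ROI label volume, behavioral phenotypes, and a truth record of the
#' planted effects for recovery testing.
#'
#' @param config A [cohort_config()].
#' @param keep_bold Keep the 4D volumes in memory (default `TRUE`); with
#'   `FALSE` only geometry, phenotypes, and the truth record are returned
#'   (per-subject volumes can be re-simulated on demand).
#' @return An object of class `peraf_cohort`: list with `config`, `subjects`,
#'   `bold` (list of [bold4d()] or `NULL`), `mask`, `labels`, `phenotypes`,
#'   `motion` (per-subject traces), and `truth`.
#' @export
generate_cohort <- function(config, keep_bold = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  geom <- generate_label_volume(config)
  npg <- config$n_per_group
  subjects <- data.frame(
    id = c(sprintf("patient%02d", seq_len(npg)), sprintf("hc%02d", seq_len(npg))),
    group = rep(c("patient", "control"), each = npg),
    stringsAsFactors = FALSE)
  roi_ids <- vapply(config$effects, function(e) e$roi_id, integer(1))
  amps <- matrix(NA_real_, nrow(subjects), length(roi_ids),
                 dimnames = list(subjects$id, as.character(roi_ids)))
  factors <- numeric(nrow(subjects))
  bold <- if (keep_bold) vector("list", nrow(subjects)) else NULL
  for (i in seq_len(nrow(subjects))) {
    sim <- simulate_subject_bold(config, (i - 1L) %% npg + 1L,
                                 subjects$group[i], geometry = geom)
    if (length(roi_ids)) amps[i, ] <- sim$true_roi_amplitude[as.character(roi_ids)]
    factors[i] <- sim$subject_factor
    if (keep_bold) bold[[i]] <- sim$bold
  }
  if (keep_bold) names(bold) <- subjects$id
  phen <- generate_phenotypes(config, amps, subjects)
  motion <- rep(list(numeric(config$n_timepoints)), nrow(subjects))
  names(motion) <- subjects$id
  structure(list(config = config, subjects = subjects, bold = bold,
                 mask = geom$mask, labels = geom$labels, phenotypes = phen,
                 motion = motion,
                 truth = list(true_roi_amplitudes = amps,
                              subject_factors = factors,
                              effects = config$effects)),
            class = "peraf_cohort")
}

#' @export
print.peraf_cohort <- function(x, ...) {
  cat("Synthetic PerAF cohort: ", x$config$n_per_group, " per group, grid ",
      paste(x$config$grid_shape, collapse = " x "), ", ",
      length(x$config$effects), " planted effect(s), seed ",
      x$config$seed, "\n", sep = "")
  invisible(x)
}
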