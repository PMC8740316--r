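test_that("label volume construction places disjoint ROIs inside the brain mask", {
  cfg <- cohort_config(
    n_per_group = 2, grid_shape = c(16, 16, 12), n_timepoints = 10,
    effects = list(effect_spec(1L, cube_roi(c(5, 5, 6)), "patient", 1.5),
                   effect_spec(2L, cube_roi(c(12, 12, 6)), "patient", 0.5)),
    phenotypes = list())
  geom <- generate_label_volume(cfg)
  expect_equal(sort(unique(as.vector(geom$labels))), c(0L, 1L, 2L))
  expect_equal(sum(geom$labels == 1L), 27)
  expect_equal(sum(geom$labels == 2L), 27)
  expect_true(all(geom$mask[geom$labels > 0]))

  cfg0 <- cohort_config(n_per_group = 2, grid_shape = c(16, 16, 12),
                        n_timepoints = 10, effects = list(), phenotypes = list())
  geom0 <- generate_label_volume(cfg0)
  expect_true(all(geom0$labels == 0L))
  expect_gt(sum(geom0$mask), 0)
})

test_that("invalid effect geometry is rejected at configuration time", {
  expect_error(
    cohort_config(grid_shape = c(10, 10, 8),
                  effects = list(effect_spec(1L, cube_roi(c(10, 5, 4)), "patient")),
                  phenotypes = list()),
    "outside")
  expect_error(
    cohort_config(grid_shape = c(16, 16, 12),
                  effects = list(effect_spec(1L, cube_roi(c(5, 5, 6))),
                                 effect_spec(2L, cube_roi(c(6, 6, 6)))),
                  phenotypes = list()),
    "overlap")
  expect_error(
    cohort_config(phenotypes = list(
      phenotype_model("x", linked_roi_id = 99L, target_r = 0.5))),
    "unknown ROI")
  expect_error(cohort_config(oscillation_band_hz = c(0.01, 0.3)), "Nyquist")
  expect_error(effect_spec(1L, cube_roi(c(3, 3, 3)), amplitude_multiplier = 0),
               "positive")
})

test_that("the same seed reproduces a subject's volume exactly", {
  cfg <- tiny_cohort_config(seed = 5)
  geom <- generate_label_volume(cfg)
  a <- simulate_subject_bold(cfg, 2, "patient", geom)
  b <- simulate_subject_bold(cfg, 2, "patient", geom)
  expect_identical(a$bold$data, b$bold$data)
  expect_identical(a$subject_factor, b$subject_factor)
  # a different subject or group gives a different realization
  c <- simulate_subject_bold(cfg, 3, "patient", geom)
  expect_false(identical(a$bold$data, c$bold$data))
  d <- simulate_subject_bold(cfg, 2, "control", geom)
  expect_false(identical(a$bold$data, d$bold$data))
})

test_that("noise-free single sinusoid reproduces the 2/pi analytic PerAF limit", {
  # 10 full cycles at 100 samples per cycle: discretization deficit
  # pi^2/(3 m^2) is far below the 0.5% relative band
  cfg <- cohort_config(
    n_per_group = 2, grid_shape = c(8, 8, 6), n_timepoints = 1000,
    tr_seconds = 1, fixed_frequency_hz = 0.01, noise_sd_fraction = 0,
    subject_amplitude_sdlog = 0, effects = list(), phenotypes = list(),
    base_amplitude_fraction = 0.03, seed = 2)
  geom <- generate_label_volume(cfg)
  sim <- simulate_subject_bold(cfg, 1, "patient", geom)
  vox <- which(geom$mask, arr.ind = TRUE)[1, ]
  pa <- peraf_series(sim$bold$data[vox[1], vox[2], vox[3], ])
  expect_equal(pa, 100 * 0.03 * 2 / pi, tolerance = 0.005)
})

test_that("amplitude multiplier 1 leaves ROI and non-ROI voxels equivalent", {
  cfg <- cohort_config(
    n_per_group = 2, grid_shape = c(10, 10, 8), n_timepoints = 500,
    tr_seconds = 1, fixed_frequency_hz = 0.01, noise_sd_fraction = 0,
    subject_amplitude_sdlog = 0,
    effects = list(effect_spec(1L, cube_roi(c(5, 5, 4)), "patient", 1)),
    phenotypes = list(), seed = 3)
  geom <- generate_label_volume(cfg)
  m <- peraf_map(simulate_subject_bold(cfg, 1, "patient", geom)$bold, geom$mask)
  inroi <- m$values[geom$labels == 1L]
  outroi <- m$values[geom$mask & geom$labels == 0L]
  expect_equal(mean(inroi), mean(outroi), tolerance = 1e-10)
})

test_that("phenotype generation hits its target correlation structure", {
  cfg <- tiny_cohort_config(seed = 9)
  subjects <- data.frame(id = sprintf("s%02d", 1:8),
                         group = rep(c("patient", "control"), each = 4))
  amps <- matrix(rnorm(8, 0.03, 0.005), 8, 1, dimnames = list(NULL, "1"))

  # noise-free limit: target_r = 1 reproduces the amplitudes up to affine map
  cfg1 <- tiny_cohort_config(seed = 9)
  cfg1$phenotypes <- list(phenotype_model("y", linked_roi_id = 1L,
                                          target_r = 1, mean = 5, sd = 1))
  ph <- generate_phenotypes(cfg1, amps, subjects)
  expect_equal(cor(ph$y, amps[, 1]), 1, tolerance = 1e-12)

  # unknown ROI link is a configuration error
  cfg_bad <- cfg1
  cfg_bad$phenotypes[[1]]$linked_roi_id <- 42L
  expect_error(generate_phenotypes(cfg_bad, amps, subjects), "unknown ROI")

  # unlinked scores are independent of amplitude: |r| < 0.4 for n = 34 in at
  # least 95% of seeds
  npg <- 17
  subjects34 <- data.frame(id = sprintf("s%02d", 1:34),
                           group = rep(c("patient", "control"), each = npg))
  ok <- 0; nrep <- 300
  for (s in seq_len(nrep)) {
    cfg0 <- cohort_config(n_per_group = npg, grid_shape = c(8, 8, 6),
                          n_timepoints = 10,
                          effects = list(effect_spec(1L, cube_roi(c(4, 4, 3)),
                                                     "patient", 1.5)),
                          phenotypes = list(phenotype_model("y", mean = 0, sd = 1)),
                          seed = s)
    amps34 <- matrix(rnorm(34, 0.03, 0.003), 34, 1, dimnames = list(NULL, "1"))
    ph0 <- generate_phenotypes(cfg0, amps34, subjects34)
    ok <- ok + (abs(cor(ph0$y, amps34[, 1])) < 0.4)
  }
  expect_gte(ok / nrep, 0.95)
})

test_that("HADS-style rounding and bounds are applied last", {
  cfg <- tiny_cohort_config(seed = 4)
  cfg$phenotypes <- list(phenotype_model("h", mean = 2, sd = 6,
                                         rounding = "integer",
                                         lower = 0, upper = 21))
  subjects <- data.frame(id = sprintf("s%02d", 1:8),
                         group = rep(c("patient", "control"), each = 4))
  ph <- generate_phenotypes(cfg, matrix(numeric(0), 8, 0), subjects)
  expect_true(all(ph$h == round(ph$h)))
  expect_true(all(ph$h >= 0 & ph$h <= 21))
})

test_that("generate_cohort bundles volumes, phenotypes and a truth record", {
  cfg <- tiny_cohort_config(seed = 6)
  coh <- generate_cohort(cfg)
  expect_s3_class(coh, "peraf_cohort")
  expect_length(coh$bold, 8)
  expect_equal(dim(coh$truth$true_roi_amplitudes), c(8, 1))
  # planted multiplier visible in the truth record
  pat <- coh$subjects$group == "patient"
  expect_equal(unname(coh$truth$true_roi_amplitudes[pat, "1"] /
                        (0.03 * coh$truth$subject_factors[pat])),
               rep(1.5, 4), tolerance = 1e-12)
  expect_equal(unname(coh$truth$true_roi_amplitudes[!pat, "1"] /
                        (0.03 * coh$truth$subject_factors[!pat])),
               rep(1, 4), tolerance = 1e-12)
  # regeneration is deterministic
  coh2 <- generate_cohort(tiny_cohort_config(seed = 6))
  expect_identical(coh$bold[["patient01"]]$data, coh2$bold[["patient01"]]$data)
  expect_identical(coh$phenotypes, coh2$phenotypes)
})
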