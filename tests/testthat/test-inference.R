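random_maps <- function(n, d = c(6, 6, 4), mu = 2, sd = 0.3, seed = 31) {
  set.seed(seed)
  lapply(seq_len(n), function(i) array(rnorm(prod(d), mu, sd), d))
}

test_that("voxelwise_t equals the pooled summary-statistic t at every voxel", {
  d <- c(6, 6, 4)
  a <- random_maps(5, d, seed = 31)
  b <- random_maps(6, d, mu = 2.2, seed = 32)
  mask <- array(TRUE, d)
  stat <- voxelwise_t(a, b, mask)
  expect_equal(stat$df, 9)
  A <- sapply(a, as.vector); B <- sapply(b, as.vector)
  for (v in sample(prod(d), 30)) {
    o <- summary_t(mean(A[v, ]), sd(A[v, ]), 5, mean(B[v, ]), sd(B[v, ]), 6)
    expect_equal(stat$t[v], o$t, tolerance = 1e-10)
    expect_equal(stat$p[v], o$p, tolerance = 1e-10)
  }
})

test_that("voxelwise_t handles degenerate and covariate cases", {
  d <- c(4, 4, 3)
  a <- random_maps(3, d, seed = 33)
  stat0 <- voxelwise_t(a, a, array(TRUE, d))
  expect_true(all(stat0$t[stat0$mask] == 0))

  # zero pooled variance is masked, not propagated
  a2 <- lapply(1:3, function(i) array(1, d))
  b2 <- lapply(1:3, function(i) array(1, d))
  statc <- voxelwise_t(a2, b2, array(TRUE, d))
  expect_equal(sum(statc$mask), 0)

  # covariate path: t of the group contrast from lm, df reduced
  set.seed(34)
  b <- random_maps(3, d, mu = 2.4, seed = 35)
  cov <- data.frame(age = rnorm(6, 50, 5))
  stat <- voxelwise_t(a, b, array(TRUE, d), covariates = cov)
  expect_equal(stat$df, 6 - 3)
  v <- 7
  y <- c(vapply(a, function(m) m[v], numeric(1)),
         vapply(b, function(m) m[v], numeric(1)))
  fit <- lm(y ~ g + age, data = cbind(data.frame(g = rep(0:1, each = 3)), cov))
  expect_equal(stat$t[v], summary(fit)$coefficients["g", "t value"],
               tolerance = 1e-8)
})

test_that("smoothness estimation recovers known FWHM", {
  d <- c(24, 24, 18)
  mask <- array(TRUE, d)
  set.seed(36)
  white <- lapply(1:10, function(i) array(rnorm(prod(d)), d))
  # at the white-noise boundary the estimator may warn and fall back
  fw <- suppressWarnings(estimate_smoothness(white, mask, c(3, 3, 3)))
  expect_true(all(abs(fw - 3) / 3 < 0.15))   # white noise: about voxel size

  smoothed <- lapply(white, smooth_gaussian, fwhm_mm = 6, voxel_size_mm = c(3, 3, 3))
  fw6 <- estimate_smoothness(smoothed, mask, c(3, 3, 3))
  expect_true(all(abs(fw6 - 6) < 1.5))

  const <- lapply(1:3, function(i) array(1, d))
  expect_error(estimate_smoothness(const, mask, c(3, 3, 3)), "degenerate")
})

test_that("cluster labelling agrees with a flood-fill oracle on random fields", {
  set.seed(37)
  for (rep in 1:40) {
    field <- array(runif(6^3) < 0.25, c(6, 6, 6))
    for (conn in c(6, 18, 26)) {
      got <- perafr:::cpp_label_components(as.logical(field), dim(field),
                                           as.integer(conn))
      ref <- floodfill_oracle(field, conn)
      # same partition: component count and matched memberships
      expect_equal(max(got), max(ref))
      expect_true(all(tapply(ref[field], got[field],
                             function(z) length(unique(z))) == 1))
      expect_equal(sort(attr(got, "sizes")), sort(unname(table(ref[ref > 0]))),
                   ignore_attr = TRUE)
    }
  }
})

test_that("extract_clusters separates signs and applies the declared connectivity", {
  d <- c(4, 4, 4)
  tmap <- array(0, d)
  tmap[1:2, 1, 1] <- 5          # blob A
  tmap[3, 2, 1] <- 5            # touches A only at an edge/corner
  mask <- array(TRUE, d)
  p <- 2 * pt(-abs(tmap), 10)
  stat <- structure(list(t = tmap, p = p, df = 10, mask = mask,
                         affine = diag(c(3, 3, 3, 1)), n1 = 6, n2 = 6),
                    class = "stat_map")
  c6 <- extract_clusters(stat, 0.005, 6)
  c26 <- extract_clusters(stat, 0.005, 26)
  expect_equal(nrow(c6), 2)
  expect_equal(nrow(c26), 1)
  expect_equal(sum(c26$n_voxels), 3)

  # signed blobs never merge even when adjacent
  tmap2 <- array(0, d)
  tmap2[1:2, 1, 1] <- 5
  tmap2[3, 1, 1] <- -5
  stat2 <- stat; stat2$t <- tmap2; stat2$p <- 2 * pt(-abs(tmap2), 10)
  cc <- extract_clusters(stat2, 0.005, 26)
  expect_equal(nrow(cc), 2)
  expect_setequal(cc$direction, c("increase", "decrease"))
  # peak coordinates are reported in mm via the affine (0-based voxel * 3)
  inc <- cc[cc$direction == "increase", ]
  expect_true(inc$peak_x_mm %in% c(0, 3))
  expect_equal(inc$peak_t, 5)

  empty <- stat; empty$t[] <- 0.1; empty$p[] <- 1
  expect_equal(nrow(extract_clusters(empty, 0.005, 18)), 0)
})

test_that("the extent null is deterministic, monotone in smoothness, and calibrated", {
  mask <- array(TRUE, c(24, 24, 18))
  n1 <- simulate_cluster_null(mask, c(3, 3, 3), c(3, 3, 3), 0.005, 18, 400, 7)
  n1b <- simulate_cluster_null(mask, c(3, 3, 3), c(3, 3, 3), 0.005, 18, 400, 7)
  expect_identical(n1$max_sizes, n1b$max_sizes)

  # unsmoothed field: independent voxels, tiny max clusters
  expect_lte(cluster_threshold(n1, 0.05), 5)
  expect_equal(cluster_threshold(n1, 1), 1L)

  n12 <- simulate_cluster_null(mask, c(12, 12, 12), c(3, 3, 3), 0.005, 18, 400, 7)
  expect_gt(cluster_threshold(n12, 0.05), cluster_threshold(n1, 0.05))
  expect_error(simulate_cluster_null(array(FALSE, c(4, 4, 4)), 6, 3, 0.005, 18, 10, 1),
               "empty mask")
})

test_that("cluster correction keeps only clusters at or over the extent threshold", {
  mask <- array(TRUE, c(10, 10, 8))
  null <- simulate_cluster_null(mask, c(6, 6, 6), c(3, 3, 3), 0.005, 18, 300, 8)
  thr <- cluster_threshold(null, 0.05)

  mk_stat <- function(sz) {
    tmap <- array(0, c(10, 10, 8))
    tmap[seq_len(sz) + 10] <- 6     # a contiguous run along x/y
    structure(list(t = tmap, p = 2 * pt(-abs(tmap), 20), df = 20, mask = mask,
                   affine = diag(c(3, 3, 3, 1)), n1 = 11, n2 = 11),
              class = "stat_map")
  }
  small <- extract_clusters(mk_stat(thr - 1), 0.005, 18)
  expect_equal(nrow(apply_cluster_correction(small, null, 0.05)), 0)
  big <- extract_clusters(mk_stat(thr), 0.005, 18)
  kept <- apply_cluster_correction(big, null, 0.05)
  expect_equal(nrow(kept), 1)
  expect_true(kept$corrected_p <= 0.05 + 1e-12)

  huge <- extract_clusters(mk_stat(max(null$max_sizes) + 1), 0.005, 18)
  keph <- apply_cluster_correction(huge, null, 0.05)
  expect_lte(keph$corrected_p, 1 / null$n_iter)

  expect_equal(nrow(apply_cluster_correction(small, null, 1)), nrow(small))
  wrong <- extract_clusters(mk_stat(thr), 0.01, 18)
  expect_error(apply_cluster_correction(wrong, null, 0.05), "does not match")
})
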