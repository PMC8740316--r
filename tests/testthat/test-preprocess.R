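make_bold <- function(d = c(4, 4, 3), nt = 20, fill = NULL) {
  if (is.null(fill)) {
    set.seed(21)
    fill <- rnorm(prod(d) * nt, 1000, 10)
  }
  bold4d(array(fill, c(d, nt)))
}

test_that("discard_initial_volumes drops exactly the leading frames", {
  b <- make_bold(nt = 240)
  out <- discard_initial_volumes(b, 10)
  expect_equal(dim(out$data)[4], 230)
  expect_equal(out$data[, , , 1], b$data[, , , 11])
  expect_equal(out$data[, , , 230], b$data[, , , 240])
  expect_identical(out$affine, b$affine)
  expect_identical(discard_initial_volumes(b, 0), b)
  expect_error(discard_initial_volumes(b, 240), "cannot discard")
})

test_that("motion screening excludes strictly over the threshold", {
  expect_false(motion_screen(c(0, 1.2, 3.1), 3)$include)
  expect_true(motion_screen(rep(0, 10), 3)$include)
  # the rule is strict 'over': exactly 3.0 mm is kept
  expect_true(motion_screen(c(1, 3.0), 3)$include)
  expect_error(motion_screen(numeric(0)), "empty")
  expect_error(motion_screen(c(-1, 2)), "non-negative")
})

test_that("detrend_linear removes the OLS slope and preserves the mean exactly", {
  d <- c(3, 3, 2); nt <- 40
  tt <- seq_len(nt)
  # a pure line becomes its own mean (PerAF 0)
  line <- 5 + 0.3 * tt
  b <- bold4d(array(rep(line, each = prod(d)), c(d, nt)))
  out <- detrend_linear(b)
  expect_equal(as.vector(out$data), rep(mean(line), prod(d) * nt),
               tolerance = 1e-10)
  expect_equal(peraf_series(out$data[1, 1, 1, ]), 0, tolerance = 1e-8)

  # closed-form four-point case
  b4 <- bold4d(array(rep(c(1, 2, 3, 4), each = prod(d)), c(d, 4)))
  expect_equal(as.vector(detrend_linear(b4)$data), rep(2.5, prod(d) * 4),
               tolerance = 1e-12)

  # trend-free series pass through; temporal mean preserved per voxel
  set.seed(22)
  arr <- array(rnorm(prod(d) * nt, 100, 5), c(d, nt))
  b2 <- bold4d(arr)
  out2 <- detrend_linear(b2)
  m_in <- apply(arr, 1:3, mean)
  m_out <- apply(out2$data, 1:3, mean)
  expect_equal(m_out, m_in, tolerance = 1e-12)
  detr <- detrend_linear(out2)
  expect_equal(detr$data, out2$data, tolerance = 1e-10)

  # out-of-mask voxels untouched
  mask <- array(TRUE, d); mask[1, 1, 1] <- FALSE
  out3 <- detrend_linear(b2, mask)
  expect_identical(out3$data[1, 1, 1, ], arr[1, 1, 1, ])
})

test_that("smooth_gaussian matches a dense separable-kernel oracle", {
  set.seed(23)
  arr <- array(rnorm(8 * 7 * 6), c(8, 7, 6))
  for (fw in list(c(6, 6, 6), c(4, 0, 9))) {
    got <- smooth_gaussian(arr, fw, c(3, 3, 3))
    expect_equal(got, smooth_oracle(arr, fw, c(3, 3, 3)), tolerance = 1e-12)
  }
  # anisotropic voxels through a bold4d affine
  b <- bold4d(array(rnorm(8 * 7 * 6 * 3), c(8, 7, 6, 3)),
              voxel_size_mm = c(2, 3, 4))
  got <- smooth_gaussian(b, 6)
  for (t in 1:3)
    expect_equal(got$data[, , , t],
                 smooth_oracle(b$data[, , , t], c(6, 6, 6), c(2, 3, 4)),
                 tolerance = 1e-12)
})

test_that("smoothing preserves constants, flux, and commutes with scaling", {
  expect_equal(smooth_gaussian(array(3.5, c(6, 6, 4)), 6, c(3, 3, 3)),
               array(3.5, c(6, 6, 4)), tolerance = 1e-12)
  imp <- array(0, c(15, 15, 11)); imp[8, 8, 6] <- 1
  sm <- smooth_gaussian(imp, 6, c(3, 3, 3))
  expect_equal(sum(sm), 1, tolerance = 1e-3)          # flux conservation
  sd_vox <- 6 / (2 * sqrt(2 * log(2))) / 3
  r <- ceiling(4 * sd_vox)
  w <- dnorm((-r):r, sd = sd_vox); w <- w / sum(w)
  expect_equal(sm[8, 8, 6], w[r + 1]^3, tolerance = 1e-10)  # central weight
  set.seed(24)
  arr <- array(rnorm(6 * 6 * 4), c(6, 6, 4))
  expect_equal(smooth_gaussian(5 * arr, 6, c(3, 3, 3)),
               5 * smooth_gaussian(arr, 6, c(3, 3, 3)), tolerance = 1e-12)
  expect_identical(smooth_gaussian(arr, 0, c(3, 3, 3)), arr)
  expect_error(smooth_gaussian(arr, -1, c(3, 3, 3)), "non-negative")
})
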