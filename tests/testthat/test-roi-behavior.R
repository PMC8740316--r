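test_that("roi_mean averages exactly the labelled in-mask voxels", {
  d <- c(5, 5, 4)
  vals <- array(7, d)
  labels <- array(0L, d)
  labels[1:3, 1, 1] <- 1L
  expect_equal(roi_mean(vals, labels, 1), 7)
  vals[1, 1, 1] <- 2; vals[2, 1, 1] <- 4; vals[3, 1, 1] <- 3
  expect_equal(roi_mean(vals, labels, 1), 3)
  # explicit-loop oracle on a random map
  set.seed(41)
  vals2 <- array(rnorm(prod(d)), d)
  labels2 <- array(sample(0:3, prod(d), replace = TRUE), d)
  for (r in 1:3) {
    acc <- 0; nn <- 0
    for (v in seq_len(prod(d))) if (labels2[v] == r) { acc <- acc + vals2[v]; nn <- nn + 1 }
    expect_equal(roi_mean(vals2, labels2, r), acc / nn, tolerance = 1e-12)
  }
  expect_error(roi_mean(vals, labels, 9), "no in-mask voxels")
})

test_that("AUC rank statistic equals trapezoid and exhaustive pair counting", {
  set.seed(42)
  for (i in 1:200) {
    n1 <- sample(3:15, 1); n0 <- sample(3:15, 1)
    scores <- c(rnorm(n1, 1), rnorm(n0))
    if (i %% 3 == 0) scores <- round(scores)     # force ties
    g <- rep(c("patient", "control"), c(n1, n0))
    r <- roc_auc(scores, g, positive = "patient", orientation = "as-is",
                 ci_method = "none")
    expect_equal(r$auc, auc_pairs_oracle(scores[g == "patient"],
                                         scores[g == "control"]),
                 tolerance = 1e-12)
    expect_equal(r$auc, auc_trapezoid_oracle(scores[g == "patient"],
                                             scores[g == "control"]),
                 tolerance = 1e-12)
  }
})

test_that("AUC worked examples and invariances hold", {
  g <- rep(c("patient", "control"), each = 2)
  expect_equal(roc_auc(c(10, 9, 1, 2), g, positive = "patient",
                       ci_method = "none")$auc, 1)
  expect_equal(roc_auc(c(3, 3, 3, 3), g, positive = "patient",
                       ci_method = "none")$auc, 0.5)
  expect_equal(roc_auc(c(2, 3, 1, 4), g, positive = "patient",
                       ci_method = "none")$auc, 0.5)
  # invariant under strictly monotone transforms
  set.seed(43)
  s <- rnorm(20); gg <- rep(c("patient", "control"), 10)
  a0 <- roc_auc(s, gg, positive = "patient", ci_method = "none")$auc
  expect_equal(roc_auc(exp(s), gg, positive = "patient", ci_method = "none")$auc, a0)
  expect_equal(roc_auc(atan(3 * s) + 5, gg, positive = "patient",
                       ci_method = "none")$auc, a0)
  # auto-orientation reports AUC >= 0.5 and records the flip
  r <- roc_auc(c(1, 2, 9, 10), g, positive = "patient", ci_method = "none")
  expect_true(r$flipped)
  expect_equal(r$auc, 1)
})

test_that("AUC and DeLong CI agree with an independent implementation", {
  set.seed(44)
  scores <- c(rnorm(17, 1.2), rnorm(17))
  g <- rep(c("patient", "control"), each = 17)
  ours <- roc_auc(scores, g, positive = "patient", orientation = "as-is",
                  ci_method = "delong")
  ref <- pROC::roc(response = g, predictor = scores, levels = c("control", "patient"),
                   direction = "<", quiet = TRUE)
  expect_equal(ours$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
  expect_equal(ours$ci95, ci[c(1, 3)], tolerance = 1e-6)
})

test_that("bootstrap CI is seeded, ordered, and contains the point estimate", {
  set.seed(45)
  scores <- c(rnorm(12, 1), rnorm(12))
  g <- rep(c("patient", "control"), each = 12)
  a <- roc_auc(scores, g, positive = "patient", n_boot = 500, seed = 7)
  b <- roc_auc(scores, g, positive = "patient", n_boot = 500, seed = 7)
  expect_identical(a$ci95, b$ci95)
  expect_true(a$ci95[1] <= a$auc && a$auc <= a$ci95[2])
  expect_error(roc_auc(scores, rep("patient", 24)), "two levels")
})

test_that("pearson_r reproduces exact limits and the t-transform p-value", {
  x <- c(1, 3, 4, 7, 9)
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  expect_equal(pearson_r(x, -x)$r, -1, tolerance = 1e-12)
  set.seed(46)
  y <- rnorm(20); z <- 0.5 * y + rnorm(20)
  res <- pearson_r(y, z)
  tstat <- res$r * sqrt((res$n - 2) / (1 - res$r^2))
  expect_equal(res$p, 2 * pt(-abs(tstat), res$n - 2), tolerance = 1e-12)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_r(c(1, 2), c(1, 2)), "at least 3")
  # missing pairs dropped
  expect_equal(pearson_r(c(y, NA), c(z, 1))$n, 20)
})

test_that("questionnaire-table correlation matches a covariance-formula oracle", {
  hads <- hads_fixture()
  pat <- hads[hads$group == "patient", ]
  x <- pat$anxiety_score; y <- pat$depression_score
  n <- length(x)
  # direct covariance-formula oracle, built independently of pearson_r
  r_oracle <- (sum(x * y) - n * mean(x) * mean(y)) /
    sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  res <- pearson_r(x, y)
  expect_equal(res$r, r_oracle, tolerance = 1e-12)
  expect_equal(res$n, 17)
  expect_lt(res$p, 0.01)
})

test_that("summary_t reproduces the clinical-table t values from printed summaries", {
  rt <- summary_t(117.06, 17.35, 17, 138.76, 12.07, 17)
  expect_equal(abs(rt$t), 4.235, tolerance = 0.01)
  expect_equal(rt$df, 32)
  lt <- summary_t(115.76, 19.22, 17, 136.41, 11.63, 17)
  expect_equal(abs(lt$t), 3.789, tolerance = 0.01)
  same <- summary_t(10, 2, 8, 10, 3, 9)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(summary_t(1, 0, 5, 2, 1, 5), "positive")
  # consistency with t.test on raw vectors sharing the same summaries
  set.seed(47)
  a <- rnorm(10); b <- rnorm(12, 0.5)
  o <- summary_t(mean(a), sd(a), 10, mean(b), sd(b), 12)
  ref <- t.test(b, a, var.equal = TRUE)
  expect_equal(o$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(o$p, ref$p.value, tolerance = 1e-10)
})

test_that("the packaged HADS table is intact", {
  hads <- hads_fixture()
  expect_equal(nrow(hads), 34)
  expect_equal(sum(hads$group == "patient"), 17)
  expect_equal(hads[hads$id == "patient1", c("anxiety_score", "depression_score")],
               data.frame(anxiety_score = 7, depression_score = 7,
                          row.names = 1L))
  expect_equal(unname(unlist(hads[hads$id == "hc9",
                                  c("anxiety_score", "depression_score")])),
               c(1, 1))
  expect_true(all(hads$anxiety_score >= 0 & hads$anxiety_score <= 21))
  expect_true(all(hads$depression_score >= 0 & hads$depression_score <= 21))
})
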