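# Independent oracles and small fixtures, deliberately written with different
# algorithms than the implementation they check.

# literal term-by-term transcription of the PerAF definition
peraf_literal <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  acc <- 0
  for (i in seq_len(n)) acc <- acc + abs((x[i] - mu) / mu)
  acc / n * 100
}

# dense Gaussian convolution matrix with half-sample reflection (one axis)
gauss_matrix_oracle <- function(n, sd_vox) {
  r <- max(1, ceiling(4 * sd_vox))
  w <- dnorm((-r):r, sd = sd_vox)
  w <- w / sum(w)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in (-r):r) {
      p <- i + j - 1
      while (p < 0 || p >= n) {
        if (p < 0) p <- -p - 1
        if (p >= n) p <- 2 * n - p - 1
      }
      K[i, p + 1] <- K[i, p + 1] + w[j + r + 1]
    }
  }
  K
}

smooth_oracle <- function(arr, fwhm_mm, voxel_mm) {
  sd_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm
  ref <- arr
  for (ax in 1:3) {
    if (sd_vox[ax] <= 0) next
    d <- dim(ref)
    K <- gauss_matrix_oracle(d[ax], sd_vox[ax])
    perm <- c(ax, setdiff(seq_along(d), ax))
    a2 <- aperm(ref, perm)
    a2 <- array(K %*% matrix(a2, d[ax]), d[perm])
    ref <- aperm(a2, order(perm))
  }
  ref
}

# recursive flood fill over a binary 3D field
floodfill_oracle <- function(field, connectivity) {
  d <- dim(field)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  m <- rowSums(abs(offs))
  keep <- switch(as.character(connectivity),
                 "6" = m == 1, "18" = m >= 1 & m <= 2, "26" = m >= 1)
  offs <- offs[keep, , drop = FALSE]
  labels <- array(0L, d)
  cur <- 0L
  for (start in which(field)) {
    if (labels[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    labels[start] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      ijk <- arrayInd(v, d)
      for (o in seq_len(nrow(offs))) {
        nb <- ijk + offs[o, ]
        if (any(nb < 1) || any(nb > d)) next
        lin <- nb[1] + (nb[2] - 1) * d[1] + (nb[3] - 1) * d[1] * d[2]
        if (field[lin] && labels[lin] == 0L) {
          labels[lin] <- cur
          queue <- c(queue, lin)
        }
      }
    }
  }
  labels
}

# AUC by exhaustive pair counting (ties count half)
auc_pairs_oracle <- function(pos, neg) {
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# AUC as the trapezoidal area under the empirical ROC curve
auc_trapezoid_oracle <- function(pos, neg) {
  thr <- c(Inf, sort(unique(c(pos, neg)), decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(h) mean(pos >= h), numeric(1))
  fpr <- vapply(thr, function(h) mean(neg >= h), numeric(1))
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# small, fast cohort for pipeline-level tests
tiny_cohort_config <- function(seed = 1, effects = tiny_effects(), ...) {
  cohort_config(n_per_group = 4, grid_shape = c(12, 12, 8),
                n_timepoints = 60, effects = effects,
                phenotypes = list(
                  phenotype_model("score", linked_roi_id = if (length(effects)) 1L else NULL,
                                  target_r = if (length(effects)) -0.8 else 0,
                                  mean = 10, sd = 2)),
                seed = seed, ...)
}

tiny_effects <- function() {
  list(effect_spec(1L, cube_roi(c(4, 4, 4)), "patient", 1.5))
}
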