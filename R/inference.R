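maps_to_matrix <- function(maps, mask) {
  cols <- lapply(maps, function(m) {
    v <- if (inherits(m, "peraf_map")) m$values else m
    if (!identical(dim(v), dim(mask))) stop("map/mask shape mismatch")
    v[mask]
  })
  do.call(cbind, cols)
}

#' Voxel-wise two-sample t contrast between groups
#'
#' Per in-mask voxel, the pooled-variance two-sample t statistic of group B
#' minus group A (positive t means B larger). With covariates, the t of the
#' group contrast from a per-voxel least-squares linear model is returned and
#' the degrees of freedom reduced accordingly. Voxels with zero pooled
#' variance are undefined and removed from the output mask.
#'
#' @param maps_a,maps_b Lists of `peraf_map` objects (or 3D arrays) for the
#'   two groups, at least 2 subjects each, identical shape.
#' @param mask 3D logical array; defaults to the intersection of the map
#'   masks.
#' @param covariates Optional data frame / matrix of per-subject nuisance
#'   covariates, rows ordered as `c(maps_a, maps_b)`.
#' @return An object of class `stat_map`: `t` and `p` (two-tailed) 3D arrays,
#'   `df`, `mask`, `affine`, and group sizes.
#' @export
voxelwise_t <- function(maps_a, maps_b, mask = NULL, covariates = NULL) {
  n1 <- length(maps_a); n2 <- length(maps_b)
  if (n1 < 2 || n2 < 2) stop("need at least 2 subjects per group")
  affine <- NULL
  all_maps <- c(maps_a, maps_b)
  if (inherits(all_maps[[1]], "peraf_map")) affine <- all_maps[[1]]$affine
  if (is.null(mask)) {
    mk <- lapply(all_maps, function(m)
      if (inherits(m, "peraf_map")) m$mask else !is.na(m))
    mask <- Reduce("&", mk)
  }
  mask <- array(as.logical(mask), dim(mask))
  Y <- maps_to_matrix(all_maps, mask)        # voxels x subjects
  if (anyNA(Y)) {
    bad <- rowSums(is.na(Y)) > 0
    Y[bad, ] <- 0                            # masked out below
  } else bad <- rep(FALSE, nrow(Y))
  g <- rep(c(0, 1), c(n1, n2))
  if (is.null(covariates)) {
    m1 <- rowMeans(Y[, g == 0, drop = FALSE])
    m2 <- rowMeans(Y[, g == 1, drop = FALSE])
    ss1 <- rowSums((Y[, g == 0, drop = FALSE] - m1)^2)
    ss2 <- rowSums((Y[, g == 1, drop = FALSE] - m2)^2)
    df <- n1 + n2 - 2
    sp2 <- (ss1 + ss2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    tv <- (m2 - m1) / se
  } else {
    X <- cbind(intercept = 1, group = g, as.matrix(covariates))
    q <- qr(X)
    if (q$rank < ncol(X)) stop("rank-deficient design (collinear covariates)")
    df <- n1 + n2 - ncol(X)
    if (df < 1) stop("not enough subjects for the covariate design")
    XtXinv <- chol2inv(qr.R(q))
    B <- XtXinv %*% crossprod(X, t(Y))       # coefficients x voxels
    res <- t(Y) - X %*% B
    sigma2 <- colSums(res^2) / df
    se <- sqrt(sigma2 * XtXinv[2, 2])
    tv <- B[2, ] / se
  }
  undef <- bad | !is.finite(tv)
  tv[undef] <- NA_real_
  pv <- 2 * pt(-abs(tv), df)
  t3 <- array(NA_real_, dim(mask)); p3 <- t3
  idx <- which(mask)
  t3[idx] <- tv; p3[idx] <- pv
  mask[idx[undef]] <- FALSE
  structure(list(t = t3, p = p3, df = df, mask = mask, affine = affine,
                 n1 = n1, n2 = n2),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat("Voxel-wise t map (", x$n1, " vs ", x$n2, " subjects, df = ", x$df,
      "), ", sum(x$mask), " in-mask voxels\n", sep = "")
  invisible(x)
}

#' Spatial smoothness (FWHM) of residual maps
#'
#' Classical random-field smoothness estimator from the variance of first
#' spatial differences of the residual maps: per axis,
#' \deqn{\mathrm{FWHM} = v \sqrt{-2\ln 2 / \ln(1 - \mathrm{var}(\Delta) /
#'   (2\,\mathrm{var}))},}
#' where \eqn{v} is the voxel size, \eqn{\mathrm{var}} the in-mask variance
#' and \eqn{\mathrm{var}(\Delta)} the variance of differences of in-mask
#' neighbor pairs, pooled over maps. The estimate is floored at the voxel
#' size: sub-voxel smoothness cannot be resolved on the grid (white noise
#' reports the voxel size). Axes where the data are rougher than white noise
#' (\eqn{\mathrm{var}(\Delta) \ge 2\,\mathrm{var}}) fall back to the voxel
#' size with a warning.
#'
#' @param residual_maps List (length >= 2) of 3D arrays or `peraf_map`s, e.g.
#'   group-mean-removed subject maps.
#' @param mask 3D logical array.
#' @param voxel_size_mm Voxel size per axis in mm.
#' @return Numeric length-3 vector of per-axis FWHM in mm.
#' @export
estimate_smoothness <- function(residual_maps, mask, voxel_size_mm = c(3, 3, 3)) {
  if (length(residual_maps) < 2) stop("need at least 2 residual maps")
  if (length(voxel_size_mm) == 1) voxel_size_mm <- rep(voxel_size_mm, 3)
  d <- dim(mask)
  fwhm <- numeric(3)
  vals <- lapply(residual_maps, function(m) {
    v <- if (inherits(m, "peraf_map")) m$values else m
    if (!identical(dim(v), d)) stop("map/mask shape mismatch")
    v
  })
  shift_pairs <- function(axis) {
    idx <- seq_len(d[axis] - 1)
    a <- switch(axis,
                list(idx, TRUE, TRUE), list(TRUE, idx, TRUE), list(TRUE, TRUE, idx))
    b <- switch(axis,
                list(idx + 1, TRUE, TRUE), list(TRUE, idx + 1, TRUE),
                list(TRUE, TRUE, idx + 1))
    list(a = a, b = b)
  }
  for (axis in 1:3) {
    sp <- shift_pairs(axis)
    pair_ok <- do.call(`[`, c(list(mask), sp$a)) & do.call(`[`, c(list(mask), sp$b))
    ssd <- 0; nd <- 0; ssv <- 0; nv <- 0
    for (v in vals) {
      x <- v[mask]
      x <- x[is.finite(x)]
      ssv <- ssv + sum((x - mean(x))^2); nv <- nv + length(x) - 1
      dd <- do.call(`[`, c(list(v), sp$b)) - do.call(`[`, c(list(v), sp$a))
      dd <- dd[pair_ok]
      dd <- dd[is.finite(dd)]
      ssd <- ssd + sum((dd - mean(dd))^2); nd <- nd + length(dd) - 1
    }
    varv <- ssv / nv; vard <- ssd / nd
    if (!is.finite(varv) || varv <= 0) stop("degenerate (constant) residual maps")
    ratio <- vard / (2 * varv)
    if (ratio >= 1) {
      warning("residuals rougher than white noise along axis ", axis,
              "; falling back to voxel-size FWHM")
      fwhm[axis] <- voxel_size_mm[axis]
    } else {
      # sub-voxel smoothness cannot be resolved on the grid and is
      # meaningless to the extent simulation: floor at the voxel size
      fwhm[axis] <- max(voxel_size_mm[axis] *
                          sqrt(-2 * log(2) / log(1 - ratio)),
                        voxel_size_mm[axis])
    }
  }
  fwhm
}

#' Monte-Carlo null distribution of maximum cluster extent
#'
#' AlphaSim-style calibration of a minimum cluster size: in each iteration,
#' in-mask Gaussian white noise is smoothed to the given FWHM,
#' re-standardized within the mask, thresholded two-tailed at `p_thresh`, and
#' the maximum connected-component size over both signs is recorded. The
#' extent threshold at level `alpha` is the `ceil((1 - alpha) quantile) + 1`
#' of these maxima, so that clusters at least that large occur under the null
#' with probability at most `alpha`.
#'
#' @param mask 3D logical array (non-empty).
#' @param fwhm_mm Per-axis smoothness (mm) of the maps being thresholded,
#'   e.g. from [estimate_smoothness()].
#' @param voxel_size_mm Voxel size in mm.
#' @param p_thresh Two-tailed voxel-wise threshold (cluster-forming p).
#' @param connectivity 6, 18 or 26 (default 18).
#' @param n_iter Monte-Carlo iterations (1000 or more recommended).
#' @param seed Integer seed; the distribution is deterministic given it.
#' @return An object of class `cluster_null` with the multiset `max_sizes`
#'   and the calibration parameters.
#' @seealso [cluster_threshold()], [apply_cluster_correction()]
#' @export
simulate_cluster_null <- function(mask, fwhm_mm, voxel_size_mm = c(3, 3, 3),
                                  p_thresh = 0.005, connectivity = 18,
                                  n_iter = 1000, seed = 1) {
  if (!is.array(mask) || length(dim(mask)) != 3) stop("'mask' must be a 3D array")
  idx <- which(mask)
  if (length(idx) == 0) stop("empty mask")
  if (p_thresh <= 0 || p_thresh >= 1) stop("'p_thresh' must be in (0, 1)")
  if (!connectivity %in% c(6, 18, 26)) stop("'connectivity' must be 6, 18, or 26")
  if (length(fwhm_mm) == 1) fwhm_mm <- rep(fwhm_mm, 3)
  if (length(voxel_size_mm) == 1) voxel_size_mm <- rep(voxel_size_mm, 3)
  d <- dim(mask)
  zthr <- qnorm(1 - p_thresh / 2)
  sd_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  # one allocation-free C++ pass: per 250-iterate block, white noise,
  # separable smoothing, in-mask re-standardization, two-tailed threshold,
  # sign-split labelling, maximum component extent
  max_sizes <- cpp_cluster_null_max_sizes(as.integer(d), as.integer(idx),
                                          sd_vox, zthr,
                                          as.integer(connectivity),
                                          as.integer(n_iter), seed, 250L)
  structure(list(max_sizes = max_sizes, n_iter = n_iter, p_thresh = p_thresh,
                 connectivity = connectivity, fwhm_mm = fwhm_mm,
                 voxel_size_mm = voxel_size_mm, seed = seed),
            class = "cluster_null")
}

# Memoized extent null, with the smoothness input binned to 0.25 mm: the
# AlphaSim lookup-table convention (the REST toolkit tabulates per integer-mm
# FWHM). The cache makes repeated analyses over the same geometry pay for
# the Monte-Carlo null once.
.null_cache <- new.env(parent = emptyenv())

cluster_null_cached <- function(mask, fwhm_mm, voxel_size_mm, p_thresh,
                                connectivity, n_iter, seed, bin_mm = 0.25) {
  fw <- round(fwhm_mm / bin_mm) * bin_mm
  key <- rlang::hash(list(dim(mask), which(mask), fw, voxel_size_mm,
                          p_thresh, connectivity, n_iter, seed))
  hit <- .null_cache[[key]]
  if (!is.null(hit)) return(hit)
  null <- simulate_cluster_null(mask, fw, voxel_size_mm, p_thresh,
                                connectivity, n_iter, seed)
  .null_cache[[key]] <- null
  null
}

#' Cluster-extent threshold at a family-wise error level
#'
#' @param null A `cluster_null` from [simulate_cluster_null()].
#' @param alpha Family-wise error level (default 0.05). `alpha >= 1` gives a
#'   threshold of 1 voxel (everything survives).
#' @return Minimum surviving cluster size in voxels.
#' @export
cluster_threshold <- function(null, alpha = 0.05) {
  stopifnot(inherits(null, "cluster_null"))
  if (alpha >= 1) return(1L)
  if (alpha <= 0) stop("'alpha' must be in (0, 1]")
  q <- quantile(null$max_sizes, 1 - alpha, type = 1, names = FALSE)
  as.integer(ceiling(q)) + 1L
}

#' @export
print.cluster_null <- function(x, ...) {
  cat("Monte-Carlo cluster-extent null: ", x$n_iter, " iterations, p < ",
      x$p_thresh, ", connectivity ", x$connectivity, ", FWHM ",
      paste(signif(x$fwhm_mm, 3), collapse = "/"), " mm\n",
      "extent threshold at alpha = 0.05: ", cluster_threshold(x, 0.05),
      " voxels\n", sep = "")
  invisible(x)
}

#' Extract suprathreshold clusters from a t map
#'
#' Connected components of the voxels with two-tailed p below the
#' cluster-forming threshold; positive and negative t excursions are labelled
#' separately. Peak coordinates are reported in world (mm) space via the
#' affine.
#'
#' @param stat A `stat_map` from [voxelwise_t()].
#' @param p_thresh Cluster-forming voxel-wise p (two-tailed).
#' @param connectivity 6, 18 or 26 (default 18).
#' @return A data frame of class `cluster_set` with one row per cluster:
#'   `cluster_id`, `direction` (`"increase"`/`"decrease"`, sign of t for
#'   group B minus group A), `n_voxels`, `peak_t`, peak voxel indices and mm
#'   coordinates. Voxel membership is kept in `attr(, "voxels")`.
#' @export
extract_clusters <- function(stat, p_thresh = 0.005, connectivity = 18) {
  stopifnot(inherits(stat, "stat_map"))
  if (!connectivity %in% c(6, 18, 26)) stop("'connectivity' must be 6, 18, or 26")
  d <- dim(stat$t)
  supra <- stat$mask & !is.na(stat$p) & stat$p < p_thresh
  affine <- if (is.null(stat$affine)) diag(4) else stat$affine
  rows <- list(); vox_list <- list()
  cid <- 0L
  for (sgn in c(1, -1)) {
    field <- supra & !is.na(stat$t) & (if (sgn > 0) stat$t > 0 else stat$t < 0)
    lab <- cpp_label_components(as.logical(field), d, as.integer(connectivity))
    k <- max(lab)
    if (k == 0) next
    for (comp in seq_len(k)) {
      cid <- cid + 1L
      vox <- which(lab == comp)
      tvals <- stat$t[vox]
      pk <- vox[which.max(abs(tvals))]
      ijk <- arrayInd(pk, d)
      mm <- voxel_to_mm(affine, ijk)
      rows[[cid]] <- data.frame(
        cluster_id = cid,
        direction = if (sgn > 0) "increase" else "decrease",
        n_voxels = length(vox),
        peak_t = tvals[which.max(abs(tvals))],
        peak_i = ijk[1], peak_j = ijk[2], peak_k = ijk[3],
        peak_x_mm = mm[1], peak_y_mm = mm[2], peak_z_mm = mm[3])
      vox_list[[cid]] <- vox
    }
  }
  out <- if (cid == 0) data.frame(
    cluster_id = integer(0), direction = character(0), n_voxels = integer(0),
    peak_t = numeric(0), peak_i = integer(0), peak_j = integer(0),
    peak_k = integer(0), peak_x_mm = numeric(0), peak_y_mm = numeric(0),
    peak_z_mm = numeric(0))
  else do.call(rbind, rows)
  if (cid > 0) {                           # largest first, field convention
    ord <- order(-out$n_voxels)
    out <- out[ord, , drop = FALSE]
    out$cluster_id <- seq_len(nrow(out))
    vox_list <- vox_list[ord]
    rownames(out) <- NULL
  }
  attr(out, "voxels") <- vox_list
  attr(out, "p_thresh") <- p_thresh
  attr(out, "connectivity") <- connectivity
  class(out) <- c("cluster_set", "data.frame")
  out
}

#' Apply Monte-Carlo cluster-extent correction
#'
#' Keeps clusters whose size reaches the extent threshold at the requested
#' family-wise error level and attaches a per-cluster corrected p (the
#' fraction of null maximum extents at least as large). Refuses nulls
#' computed at a different cluster-forming threshold or connectivity.
#'
#' @param clusters A `cluster_set` from [extract_clusters()].
#' @param null A `cluster_null` from [simulate_cluster_null()].
#' @param alpha Family-wise error level (default 0.05).
#' @return The surviving subset of `clusters` with a `corrected_p` column;
#'   the extent threshold is attached as `attr(, "extent_threshold")`.
#' @export
apply_cluster_correction <- function(clusters, null, alpha = 0.05) {
  stopifnot(inherits(clusters, "cluster_set"), inherits(null, "cluster_null"))
  if (!isTRUE(all.equal(attr(clusters, "p_thresh"), null$p_thresh)))
    stop("cluster-forming p of the null (", null$p_thresh,
         ") does not match the extracted clusters (",
         attr(clusters, "p_thresh"), ")")
  if (attr(clusters, "connectivity") != null$connectivity)
    stop("connectivity of the null does not match the extracted clusters")
  thr <- cluster_threshold(null, alpha)
  corrected_p <- vapply(clusters$n_voxels,
                        function(sz) mean(null$max_sizes >= sz), numeric(1))
  keep <- clusters$n_voxels >= thr
  out <- clusters[keep, , drop = FALSE]
  out$corrected_p <- corrected_p[keep]
  attr(out, "voxels") <- attr(clusters, "voxels")[keep]
  attr(out, "p_thresh") <- null$p_thresh
  attr(out, "connectivity") <- null$connectivity
  attr(out, "extent_threshold") <- thr
  class(out) <- c("cluster_set", "data.frame")
  out
}
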