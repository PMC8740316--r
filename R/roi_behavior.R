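#' Mean map value over an ROI
#'
#' Arithmetic mean of the in-mask map values carrying the given label,
#' the standard way a regional summary is extracted from a voxel-wise map.
#'
#' @param map A `peraf_map` or 3D numeric array.
#' @param labels 3D integer label array (0 = background).
#' @param roi_id Label to average over.
#' @return Mean value (scalar).
#' @export
roi_mean <- function(map, labels, roi_id) {
  v <- if (inherits(map, "peraf_map")) map$values else map
  mk <- if (inherits(map, "peraf_map")) map$mask else !is.na(v)
  if (!identical(dim(v), dim(labels))) stop("map/label shape mismatch")
  sel <- mk & labels == roi_id
  if (!any(sel)) stop("ROI ", roi_id, " has no in-mask voxels")
  mean(v[sel])
}

#' ROC curve and AUC for two-group discrimination
#'
#' AUC computed by the rank (Mann-Whitney) statistic with ties counted half,
#' which equals the trapezoidal area under the empirical ROC curve. With
#' `orientation = "auto"` scores are oriented so the reported AUC is at least
#' 0.5 and the applied flip is recorded. The 95% confidence interval uses a
#' stratified bootstrap percentile method by default, or DeLong's asymptotic
#' variance.
#'
#' @param scores Numeric score per subject (e.g. ROI mean PerAF).
#' @param groups Group label per subject (two levels).
#' @param positive Which level counts as the positive class; default: the
#'   second level in sorted order.
#' @param orientation `"auto"` (default, AUC >= 0.5) or `"as-is"`.
#' @param ci_method `"bootstrap"` (stratified percentile), `"delong"`, or
#'   `"none"`.
#' @param n_boot Bootstrap replicates (default 2000).
#' @param seed Seed for the bootstrap (default 1).
#' @return An object of class `roc_result`: `auc`, `ci95`, `flipped`,
#'   `positive`, `curve` (data frame of FPR/TPR), and group sizes.
#' @export
roc_auc <- function(scores, groups, positive = NULL,
                    orientation = c("auto", "as-is"),
                    ci_method = c("bootstrap", "delong", "none"),
                    n_boot = 2000, seed = 1) {
  orientation <- match.arg(orientation)
  ci_method <- match.arg(ci_method)
  groups <- as.character(groups)
  lev <- sort(unique(groups))
  if (length(lev) != 2) stop("'groups' must have exactly two levels")
  if (is.null(positive)) positive <- lev[2]
  if (!positive %in% lev) stop("'positive' is not a group level")
  pos <- groups == positive
  if (!any(pos) || all(pos)) stop("both groups must be non-empty")
  if (anyNA(scores)) stop("'scores' contains missing values")

  auc_rank <- function(s, p) {
    r <- rank(s)
    n1 <- sum(p); n0 <- sum(!p)
    (sum(r[p]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  auc <- auc_rank(scores, pos)
  flipped <- FALSE
  if (orientation == "auto" && auc < 0.5) {
    scores <- -scores
    auc <- 1 - auc
    flipped <- TRUE
  }
  # empirical curve over all distinct thresholds
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(h) mean(scores[pos] >= h), numeric(1))
  fpr <- vapply(thr, function(h) mean(scores[!pos] >= h), numeric(1))
  curve <- data.frame(fpr = fpr, tpr = tpr)

  ci95 <- c(NA_real_, NA_real_)
  if (ci_method == "bootstrap") {
    ip <- which(pos); in_ <- which(!pos)
    boots <- with_local_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        bi <- c(sample(ip, length(ip), replace = TRUE),
                sample(in_, length(in_), replace = TRUE))
        auc_rank(scores[bi], pos[bi])
      }, numeric(1))
    })
    ci95 <- unname(quantile(boots, c(0.025, 0.975)))
  } else if (ci_method == "delong") {
    # placements: per-case probability of exceeding a control and vice versa
    sx <- scores[pos]; sy <- scores[!pos]
    m <- length(sx); n <- length(sy)
    v10 <- vapply(sx, function(x) (sum(x > sy) + 0.5 * sum(x == sy)) / n,
                  numeric(1))
    v01 <- vapply(sy, function(y) (sum(sx > y) + 0.5 * sum(sx == y)) / m,
                  numeric(1))
    vr <- var(v10) / m + var(v01) / n
    half <- qnorm(0.975) * sqrt(vr)
    ci95 <- c(max(0, auc - half), min(1, auc + half))
  }
  structure(list(auc = auc, ci95 = ci95, flipped = flipped,
                 positive = positive, curve = curve,
                 n_pos = sum(pos), n_neg = sum(!pos),
                 ci_method = ci_method),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC = %.3f", x$auc))
  if (!anyNA(x$ci95))
    cat(sprintf(" (95%% CI %.3f-%.3f, %s)", x$ci95[1], x$ci95[2], x$ci_method))
  cat(if (x$flipped) ", orientation flipped" else "",
      sprintf("; positive = %s (%d vs %d)\n", x$positive, x$n_pos, x$n_neg),
      sep = "")
  invisible(x)
}

#' Pearson correlation with two-tailed p
#'
#' Product-moment correlation; the p-value comes from the exact t transform
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}} with \eqn{n-2} degrees of freedom
#' (computed via [stats::cor.test()]). Pairs with missing values are dropped.
#'
#' @param x,y Numeric vectors; at least 3 complete pairs, both with nonzero
#'   variance.
#' @return An object of class `correlation_result`: `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance input")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(r = unname(ct$estimate), p = ct$p.value, n = n),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f, p = %.4g, n = %d\n", x$r, x$p, x$n))
  invisible(x)
}

#' Pooled two-sample t test from summary statistics
#'
#' The pooled-variance independent-samples t statistic from group means,
#' standard deviations and sizes, as used for demographic and ocular
#' comparisons reported as mean +/- SD:
#' \deqn{t = \frac{m_2 - m_1}{\sqrt{s_p^2 (1/n_1 + 1/n_2)}},\qquad
#'  s_p^2 = \frac{(n_1-1) s_1^2 + (n_2-1) s_2^2}{n_1 + n_2 - 2}.}
#'
#' @param mean1,sd1,n1 Summary of group 1 (sd > 0, n >= 2).
#' @param mean2,sd2,n2 Summary of group 2.
#' @return List with `t`, `df`, and two-tailed `p`.
#' @export
summary_t <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (any(c(sd1, sd2) <= 0)) stop("standard deviations must be positive")
  if (any(c(n1, n2) < 2)) stop("group sizes must be at least 2")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  tv <- (mean2 - mean1) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = tv, df = df, p = 2 * pt(-abs(tv), df))
}

#' Packaged HADS questionnaire table
#'
#' The 34 anxiety/depression subscore pairs (17 patients, 17 controls) of the
#' study's questionnaire table, as shipped in `inst/extdata/hads_table3.tsv`.
#'
#' @return Data frame with columns `id`, `group`, `anxiety_score`,
#'   `depression_score` (34 rows).
#' @export
hads_fixture <- function() {
  path <- system.file("extdata", "hads_table3.tsv", package = "perafr",
                      mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}
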