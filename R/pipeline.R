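#' Pipeline configuration
#'
#' All tunable parameters of the end-to-end analysis, with the defaults the
#' pipeline is calibrated around: discard the first 10 volumes, exclude
#' subjects moving over 3 mm, smooth at 6 mm FWHM before PerAF, form clusters
#' at two-tailed voxel-wise p < 0.005, and keep clusters that survive the
#' Monte-Carlo extent threshold at family-wise alpha = 0.05 under 18-neighbor
#' connectivity.
#'
#' @param discard_k Leading volumes to discard (default 10).
#' @param motion_thresh_mm Motion exclusion threshold in mm (default 3).
#' @param fwhm_mm Gaussian smoothing FWHM in mm (default 6).
#' @param smooth_stage `"bold"` (smooth the 4D data before PerAF, default) or
#'   `"map"` (smooth the subject PerAF maps instead).
#' @param p_voxel Two-tailed cluster-forming voxel p (default 0.005).
#' @param alpha Family-wise error level for cluster extent (default 0.05).
#' @param connectivity Cluster connectivity, 6/18/26 (default 18).
#' @param n_iter Monte-Carlo iterations for the extent null (default 1000).
#' @param use_mperaf Use mean-standardized maps for group statistics
#'   (default `TRUE`); raw PerAF ROI means are reported alongside.
#' @param ci_method AUC confidence interval method (`"bootstrap"`,
#'   `"delong"`, `"none"`).
#' @param n_boot Bootstrap replicates for the AUC CI (default 2000).
#' @param correlation_group Which subjects enter brain-behavior correlations
#'   (`"patient"` by default, matching the clinical design; `"all"` uses the
#'   whole cohort).
#' @param seed Integer seed for every stochastic stage (extent null, AUC
#'   bootstrap).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(discard_k = 10, motion_thresh_mm = 3, fwhm_mm = 6,
                            smooth_stage = c("bold", "map"), p_voxel = 0.005,
                            alpha = 0.05, connectivity = 18, n_iter = 1000,
                            use_mperaf = TRUE,
                            ci_method = c("bootstrap", "delong", "none"),
                            n_boot = 2000,
                            correlation_group = c("patient", "control", "all"),
                            seed = 1) {
  smooth_stage <- match.arg(smooth_stage)
  ci_method <- match.arg(ci_method)
  correlation_group <- match.arg(correlation_group)
  stopifnot(discard_k >= 0, motion_thresh_mm > 0, all(fwhm_mm >= 0),
            p_voxel > 0, p_voxel < 1, alpha > 0, alpha <= 1,
            connectivity %in% c(6, 18, 26), n_iter >= 1, n_boot >= 1)
  structure(list(discard_k = as.integer(discard_k),
                 motion_thresh_mm = motion_thresh_mm, fwhm_mm = fwhm_mm,
                 smooth_stage = smooth_stage, p_voxel = p_voxel, alpha = alpha,
                 connectivity = as.integer(connectivity),
                 n_iter = as.integer(n_iter), use_mperaf = use_mperaf,
                 ci_method = ci_method, n_boot = as.integer(n_boot),
                 correlation_group = correlation_group,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys match the arguments of [pipeline_config()]; unknown keys are
#' rejected rather than silently ignored.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

subject_peraf <- function(bold, mask, trace, config, stage_id) {
  step <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop("[", stage_id, "/", what, "] ", conditionMessage(e), call. = FALSE))
  }
  scr <- step("motion_screen", motion_screen(trace, config$motion_thresh_mm))
  if (!scr$include)
    return(list(map = NULL, excluded = TRUE, max_motion = scr$max_mm))
  if (config$smooth_stage == "bold") {
    # fused C++ path: identical to discard -> detrend -> smooth -> peraf
    # (pinned by tests), one pass with reusable buffers
    map <- step("peraf", {
      bold <- as_bold4d(bold)
      dims <- dim(bold$data)
      if (config$discard_k >= dims[4])
        stop("cannot discard ", config$discard_k,
             " volumes from a series of length ", dims[4])
      fw <- if (length(config$fwhm_mm) == 1) rep(config$fwhm_mm, 3)
        else config$fwhm_mm
      vs <- sqrt(colSums(bold$affine[1:3, 1:3]^2))
      sd_vox <- fw / (2 * sqrt(2 * log(2))) / vs
      idx <- which(mask)
      pa <- cpp_subject_peraf(bold$data, as.integer(dims),
                              config$discard_k, as.integer(idx), sd_vox)
      values <- array(NA_real_, dims[1:3])
      undef <- idx[is.na(pa[idx])]
      values[idx] <- pa[idx]
      mk <- array(as.logical(mask), dims[1:3])
      mk[undef] <- FALSE
      new_peraf_map(values, mk, bold$affine, length(undef))
    })
  } else {
    b <- step("discard", discard_initial_volumes(bold, config$discard_k))
    b <- step("detrend", detrend_linear(b, mask))
    map <- step("peraf", peraf_map(b, mask))
  }
  if (config$smooth_stage == "map") {
    v <- map$values
    v[!map$mask] <- 0
    vs <- sqrt(colSums(map$affine[1:3, 1:3]^2))
    map$values <- smooth_gaussian(v, config$fwhm_mm, vs)
    map$values[!map$mask] <- NA_real_
  }
  raw_map <- map
  if (config$use_mperaf) map <- step("mperaf", mperaf_standardize(map))
  list(map = map, raw_map = raw_map, excluded = FALSE,
       max_motion = scr$max_mm, n_undefined = map$n_undefined)
}

load_cohort_inputs <- function(cohort) {
  if (inherits(cohort, "cohort_config")) {
    geom <- generate_label_volume(cohort)
    npg <- cohort$n_per_group
    subjects <- data.frame(
      id = c(sprintf("patient%02d", seq_len(npg)), sprintf("hc%02d", seq_len(npg))),
      group = rep(c("patient", "control"), each = npg),
      stringsAsFactors = FALSE)
    roi_ids <- vapply(cohort$effects, function(e) e$roi_id, integer(1))
    amps <- matrix(NA_real_, nrow(subjects), length(roi_ids),
                   dimnames = list(subjects$id, as.character(roi_ids)))
    get_bold <- function(i) {
      sim <- simulate_subject_bold(cohort, (i - 1L) %% npg + 1L,
                                   subjects$group[i], geometry = geom)
      amps[i, ] <<- sim$true_roi_amplitude[colnames(amps)]
      sim$bold
    }
    phen_fun <- function() generate_phenotypes(cohort, amps, subjects)
    idx <- which(geom$mask)
    # allocation-free fused chain for simulated subjects (agrees with the
    # composed module path at single-float tolerance; pinned by tests)
    fused_map <- function(i, pcfg) {
      si <- (i - 1L) %% npg + 1L
      p <- subject_signal_params(cohort, si, subjects$group[i])
      amps[i, ] <<- p$true_roi_amplitude[colnames(amps)]
      fw <- if (length(pcfg$fwhm_mm) == 1) rep(pcfg$fwhm_mm, 3) else pcfg$fwhm_mm
      sd_vox <- fw / (2 * sqrt(2 * log(2))) / cohort$voxel_size_mm
      if (pcfg$discard_k >= cohort$n_timepoints)
        stop("cannot discard ", pcfg$discard_k, " volumes from a series of length ",
             cohort$n_timepoints)
      pa <- cpp_simulate_subject_peraf(
        as.integer(c(cohort$grid_shape, cohort$n_timepoints)),
        cohort$ar1_coefficient,
        cohort$noise_sd_fraction * cohort$baseline_mean,
        cohort$baseline_mean, as.integer(idx), p$a_v[idx], p$s,
        pcfg$discard_k, sd_vox, cohort$seed, p$stream * 7 + 3)
      values <- array(NA_real_, cohort$grid_shape)
      undef <- idx[is.na(pa[idx])]
      values[idx] <- pa[idx]
      mk <- geom$mask
      mk[undef] <- FALSE
      new_peraf_map(values, mk, diag(c(cohort$voxel_size_mm, 1)), length(undef))
    }
    list(subjects = subjects, mask = geom$mask, labels = geom$labels,
         get_bold = get_bold, get_motion = function(i) numeric(cohort$n_timepoints),
         fused_map = fused_map,
         phenotypes = phen_fun, source = "cohort_config")
  } else if (inherits(cohort, "peraf_cohort")) {
    if (is.null(cohort$bold)) return(load_cohort_inputs(cohort$config))
    list(subjects = cohort$subjects, mask = cohort$mask, labels = cohort$labels,
         get_bold = function(i) cohort$bold[[i]],
         get_motion = function(i) cohort$motion[[i]],
         phenotypes = function() cohort$phenotypes, source = "peraf_cohort")
  } else if (is.character(cohort) && length(cohort) == 1 && dir.exists(cohort)) {
    phen_path <- file.path(cohort, "phenotypes.tsv")
    if (!file.exists(phen_path))
      stop("[input] no phenotypes.tsv in '", cohort, "'")
    phen <- read.delim(phen_path, stringsAsFactors = FALSE)
    for (col in c("id", "group"))
      if (!col %in% names(phen))
        stop("[input] phenotype table lacks required column '", col, "'")
    mask <- read_volume_nifti(file.path(cohort, "mask.nii.gz"), "logical")
    lab_path <- file.path(cohort, "labels.nii.gz")
    labels <- if (file.exists(lab_path))
      read_volume_nifti(lab_path, "integer")$values
    else array(0L, dim(mask$values))
    list(subjects = phen[c("id", "group")], mask = mask$values, labels = labels,
         get_bold = function(i) read_bold_nifti(
           file.path(cohort, paste0(phen$id[i], "_bold.nii.gz"))),
         get_motion = function(i) {
           mp <- file.path(cohort, paste0(phen$id[i], "_motion.tsv"))
           if (file.exists(mp)) read_motion_tsv(mp) else 0
         },
         phenotypes = function() phen, source = cohort)
  } else {
    stop("'cohort' must be a cohort_config, a peraf_cohort, or a directory")
  }
}

#' Run the full PerAF group-analysis pipeline
#'
#' For every subject: motion screening, initial-volume discard,
#' mean-preserving detrend, Gaussian smoothing, PerAF map (optionally
#' mean-standardized). Then: voxel-wise two-sample t (patients minus
#' controls), residual smoothness estimation, Monte-Carlo cluster-extent
#' null, cluster extraction and correction, and per-ROI AUC and
#' brain-behavior correlations.
#'
#' @param cohort A [cohort_config()] (subjects are simulated on the fly, one
#'   at a time), a `peraf_cohort`, or a directory written by
#'   [write_cohort()].
#' @param config A [pipeline_config()].
#' @param keep_maps Keep the subject-level maps in the result (default
#'   `FALSE`).
#' @return An object of class `peraf_pipeline_result`: `stat` (t map),
#'   `clusters` (all suprathreshold), `clusters_corrected` (surviving),
#'   `null`, `smoothness_fwhm_mm`, `roi_report` (one row per ROI x phenotype
#'   with AUC, CI and Pearson r/p), `phenotypes`, and `log`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(), keep_maps = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  inp <- load_cohort_inputs(cohort)
  subjects <- inp$subjects
  n <- nrow(subjects)
  maps <- vector("list", n); raw_maps <- vector("list", n)
  excluded <- logical(n); max_motion <- numeric(n); n_undef <- integer(n)
  use_fused <- !is.null(inp$fused_map) && config$smooth_stage == "bold"
  for (i in seq_len(n)) {
    res <- if (use_fused) {
      raw <- inp$fused_map(i, config)
      list(map = if (config$use_mperaf) mperaf_standardize(raw) else raw,
           raw_map = raw, excluded = FALSE, max_motion = 0,
           n_undefined = raw$n_undefined)
    } else {
      subject_peraf(inp$get_bold(i), inp$mask, inp$get_motion(i),
                    config, subjects$id[i])
    }
    excluded[i] <- res$excluded
    max_motion[i] <- res$max_motion
    if (!res$excluded) {
      maps[[i]] <- res$map
      raw_maps[[i]] <- res$raw_map
      n_undef[i] <- res$n_undefined
    }
  }
  keep <- !excluded
  grp <- subjects$group[keep]
  maps_a <- maps[keep][grp == "control"]
  maps_b <- maps[keep][grp == "patient"]
  if (length(maps_a) < 2 || length(maps_b) < 2)
    stop("[group] fewer than 2 usable subjects in a group after motion screening")
  stat <- voxelwise_t(maps_a, maps_b)

  # residuals: group-demeaned subject maps
  res_maps <- local({
    am <- Reduce(`+`, lapply(maps_a, function(m) m$values)) / length(maps_a)
    bm <- Reduce(`+`, lapply(maps_b, function(m) m$values)) / length(maps_b)
    c(lapply(maps_a, function(m) m$values - am),
      lapply(maps_b, function(m) m$values - bm))
  })
  vs <- sqrt(colSums(stat$affine[1:3, 1:3]^2))
  fwhm <- estimate_smoothness(res_maps, stat$mask, vs)
  null <- cluster_null_cached(stat$mask, fwhm, vs, config$p_voxel,
                              config$connectivity, config$n_iter,
                              seed = derive_seed(config$seed, 71))
  clusters <- extract_clusters(stat, config$p_voxel, config$connectivity)
  surviving <- apply_cluster_correction(clusters, null, config$alpha)

  phen <- inp$phenotypes()
  phen <- phen[keep, , drop = FALSE]
  roi_ids <- sort(setdiff(unique(as.vector(inp$labels)), 0L))
  meta_cols <- c("id", "group", "sex")
  ph_cols <- setdiff(names(phen)[vapply(phen, is.numeric, logical(1))], meta_cols)
  corr_sel <- if (config$correlation_group == "all") rep(TRUE, nrow(phen))
    else phen$group == config$correlation_group
  # ROI-level discrimination and brain-behavior correlation use the raw PerAF
  # regional means: mPerAF standardization removes exactly the global
  # between-subject amplitude variation these analyses rely on
  roi_report <- NULL
  roi_means <- list()
  for (rid in roi_ids) {
    raw_mns <- vapply(raw_maps[keep], roi_mean, numeric(1), labels = inp$labels,
                      roi_id = rid)
    roi_means[[as.character(rid)]] <- raw_mns
    roc <- roc_auc(raw_mns, grp, positive = "patient",
                   ci_method = config$ci_method, n_boot = config$n_boot,
                   seed = derive_seed(config$seed, 100 + rid))
    for (pc in ph_cols) {
      ct <- tryCatch(pearson_r(raw_mns[corr_sel], phen[[pc]][corr_sel]),
                     error = function(e) list(r = NA_real_, p = NA_real_,
                                              n = sum(corr_sel)))
      roi_report <- rbind(roi_report, data.frame(
        roi_id = rid, n_voxels = sum(inp$labels == rid & inp$mask),
        mean_peraf_patient = mean(raw_mns[grp == "patient"]),
        mean_peraf_control = mean(raw_mns[grp == "control"]),
        auc = roc$auc, auc_ci_low = roc$ci95[1], auc_ci_high = roc$ci95[2],
        auc_flipped = roc$flipped,
        phenotype = pc, r = ct$r, p = ct$p, n = ct$n))
    }
  }
  log <- list(config = unclass(config), config_hash = config_hash(config),
              source = inp$source, n_subjects = n,
              excluded_ids = subjects$id[excluded],
              max_motion_mm = stats::setNames(max_motion, subjects$id),
              undefined_voxels = stats::setNames(n_undef, subjects$id),
              smoothness_fwhm_mm = fwhm,
              extent_threshold = attr(surviving, "extent_threshold"))
  structure(list(stat = stat, clusters = clusters,
                 clusters_corrected = surviving, null = null,
                 smoothness_fwhm_mm = fwhm, roi_report = roi_report,
                 roi_means = roi_means, phenotypes = phen,
                 maps = if (keep_maps) maps[keep] else NULL,
                 subjects = subjects, log = log),
            class = "peraf_pipeline_result")
}

#' @export
print.peraf_pipeline_result <- function(x, ...) {
  cat("PerAF pipeline result\n",
      "  subjects: ", x$log$n_subjects, " (",
      length(x$log$excluded_ids), " excluded)\n",
      "  residual smoothness FWHM: ",
      paste(signif(x$smoothness_fwhm_mm, 3), collapse = "/"), " mm\n",
      "  extent threshold: ", x$log$extent_threshold, " voxels; ",
      nrow(x$clusters_corrected), " of ", nrow(x$clusters),
      " clusters survive\n", sep = "")
  if (!is.null(x$roi_report)) {
    aucs <- unique(x$roi_report[c("roi_id", "auc")])
    cat("  ROI AUCs:", paste(sprintf("ROI %d = %.3f", aucs$roi_id, aucs$auc),
                             collapse = ", "), "\n")
  }
  invisible(x)
}
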