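#' Read a 4D BOLD NIfTI file
#'
#' @param path NIfTI-1 file (`.nii` or `.nii.gz`).
#' @return A [bold4d()] with the file's affine and TR.
#' @export
read_bold_nifti <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("cannot read NIfTI file '", path,
                                           "': ", conditionMessage(e)))
  if (length(dim(img)) != 4L)
    stop("'", path, "' is ", length(dim(img)), "D; a 4D BOLD series was expected")
  tr <- RNifti::pixdim(img)[4]
  if (!is.finite(tr) || tr <= 0) tr <- 2
  bold4d(as.array(img), affine = unclass(RNifti::xform(img)), tr_seconds = tr)
}

#' Write a 4D BOLD volume to NIfTI
#'
#' @param bold A [bold4d()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param description Free-text header description (80 bytes max), used for
#'   provenance.
#' @return `path`, invisibly.
#' @export
write_bold_nifti <- function(bold, path, description = "") {
  bold <- as_bold4d(bold)
  img <- RNifti::asNifti(bold$data)
  vs <- sqrt(colSums(bold$affine[1:3, 1:3]^2))
  RNifti::pixdim(img) <- c(vs, bold$tr_seconds)
  RNifti::sform(img) <- structure(bold$affine, code = 2L)
  RNifti::qform(img) <- structure(bold$affine, code = 2L)
  img$descrip <- substr(description, 1, 79)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a 3D map (or mask / labels) to NIfTI
#'
#' @param values 3D array or `peraf_map` (its `values` are written, with
#'   undefined voxels as `NaN`).
#' @param path Output path.
#' @param affine Voxel-to-mm affine; taken from a `peraf_map` input.
#' @param description Header description text.
#' @return `path`, invisibly.
#' @export
write_map_nifti <- function(values, path, affine = diag(c(3, 3, 3, 1)),
                            description = "") {
  if (inherits(values, "peraf_map")) {
    affine <- values$affine
    description <- if (nzchar(description)) description
      else paste0("PerAF map (", values$standardized, ", percent units)")
    values <- values$values
  }
  img <- RNifti::asNifti(values * 1)
  vs <- sqrt(colSums(affine[1:3, 1:3]^2))
  RNifti::pixdim(img) <- vs
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::qform(img) <- structure(affine, code = 2L)
  img$descrip <- substr(description, 1, 79)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 3D NIfTI volume
#'
#' @param path NIfTI file.
#' @param as `"numeric"`, `"logical"` (mask: nonzero is `TRUE`), or
#'   `"integer"` (label atlas).
#' @return List with `values` (3D array) and `affine`.
#' @export
read_volume_nifti <- function(path, as = c("numeric", "logical", "integer")) {
  as <- match.arg(as)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("cannot read NIfTI file '", path,
                                           "': ", conditionMessage(e)))
  if (length(dim(img)) != 3L)
    stop("'", path, "' is not a 3D volume")
  v <- as.array(img)
  v <- switch(as, numeric = v, logical = array(v != 0, dim(v)),
              integer = array(as.integer(round(v)), dim(v)))
  list(values = v, affine = unclass(RNifti::xform(img)))
}

#' Read / write a single-column motion trace
#'
#' Per-volume maximum head displacement in mm, one value per line, with a
#' `displacement_mm` header.
#'
#' @param path TSV file.
#' @return Numeric vector.
#' @export
read_motion_tsv <- function(path) {
  df <- read.delim(path)
  as.numeric(df[[1]])
}

#' @rdname read_motion_tsv
#' @param trace Numeric vector of displacements.
#' @export
write_motion_tsv <- function(trace, path) {
  write.table(data.frame(displacement_mm = trace), path, sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a synthetic cohort to disk
#'
#' One 4D NIfTI per subject, the brain mask and ROI label volume, the
#' phenotype table as TSV, per-subject motion traces, and a JSON truth record
#' of the planted effects. Every NIfTI header carries the configuration hash
#' and seed in its description field.
#'
#' @param cohort A `peraf_cohort` from [generate_cohort()] with
#'   `keep_bold = TRUE`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "peraf_cohort"))
  if (is.null(cohort$bold))
    stop("cohort was generated with keep_bold = FALSE; re-generate to export")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prov <- sprintf("perafr cfg %s seed %d", config_hash(cohort$config),
                  cohort$config$seed)
  affine <- cohort$bold[[1]]$affine
  for (id in cohort$subjects$id) {
    write_bold_nifti(cohort$bold[[id]], file.path(dir, paste0(id, "_bold.nii.gz")),
                     description = prov)
    write_motion_tsv(cohort$motion[[id]],
                     file.path(dir, paste0(id, "_motion.tsv")))
  }
  write_map_nifti(cohort$mask * 1, file.path(dir, "mask.nii.gz"),
                  affine = affine, description = prov)
  write_map_nifti(cohort$labels * 1, file.path(dir, "labels.nii.gz"),
                  affine = affine, description = prov)
  write.table(cohort$phenotypes, file.path(dir, "phenotypes.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  truth <- list(
    provenance = prov, seed = cohort$config$seed,
    true_roi_amplitudes = as.data.frame(cohort$truth$true_roi_amplitudes),
    subject_factors = cohort$truth$subject_factors,
    effects = lapply(cohort$truth$effects, function(e)
      list(roi_id = e$roi_id, group = e$group,
           amplitude_multiplier = e$amplitude_multiplier,
           n_voxels = nrow(e$roi_voxels))))
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Write a cluster report TSV
#'
#' Columns mirror the conventional cluster table of a voxel-wise group
#' analysis: id, peak mm coordinates, extent, peak t, corrected p (when
#' present), and direction.
#'
#' @param clusters A `cluster_set`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_cluster_report <- function(clusters, path) {
  cols <- c("cluster_id", "peak_x_mm", "peak_y_mm", "peak_z_mm", "n_voxels",
            "peak_t", "corrected_p", "direction")
  df <- as.data.frame(clusters)
  df <- df[, intersect(cols, names(df)), drop = FALSE]
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

config_hash <- function(config) substr(rlang::hash(config), 1, 12)
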