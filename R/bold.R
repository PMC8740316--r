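#' 4D BOLD volume container
#'
#' Minimal in-memory representation of a resting-state BOLD acquisition: the
#' 4D intensity array (x, y, z, t), a 4x4 voxel-to-world affine, and the
#' repetition time.
#'
#' @param data 4D numeric array with time as the 4th dimension (t >= 2).
#' @param affine 4x4 invertible voxel-to-mm matrix. Defaults to a scaling
#'   matrix built from `voxel_size_mm` (0-based voxel indices map to mm).
#' @param tr_seconds Repetition time in seconds.
#' @param voxel_size_mm Voxel edge lengths in mm, used only when `affine` is
#'   not given.
#' @return An object of class `bold4d`.
#' @export
bold4d <- function(data, affine = NULL, tr_seconds = 2,
                   voxel_size_mm = c(3, 3, 3)) {
  if (length(dim(data)) != 4L)
    stop("'data' must be a 4D array (x, y, z, t)")
  if (dim(data)[4] < 2L) stop("a BOLD series needs at least 2 time points")
  if (!is.numeric(tr_seconds) || tr_seconds <= 0)
    stop("'tr_seconds' must be positive")
  if (is.null(affine)) affine <- diag(c(voxel_size_mm, 1))
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)) ||
      abs(det(affine)) < .Machine$double.eps)
    stop("'affine' must be an invertible 4x4 matrix")
  structure(list(data = data, affine = affine, tr_seconds = tr_seconds),
            class = "bold4d")
}

as_bold4d <- function(x, ...) {
  if (inherits(x, "bold4d")) return(x)
  if (is.array(x) && length(dim(x)) == 4L) return(bold4d(x, ...))
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as a 4D BOLD volume")
}

#' @export
print.bold4d <- function(x, ...) {
  d <- dim(x$data)
  cat("BOLD 4D volume ", paste(d[1:3], collapse = " x "), " voxels, ",
      d[4], " time points, TR ", x$tr_seconds, " s\n", sep = "")
  invisible(x)
}

# world-space (mm) coordinates of 1-based voxel indices under an affine that
# maps 0-based indices to mm
voxel_to_mm <- function(affine, ijk) {
  ijk <- matrix(ijk, ncol = 3)
  hom <- cbind(ijk - 1, 1)
  t(affine %*% t(hom))[, 1:3, drop = FALSE]
}
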