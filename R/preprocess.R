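#' Discard the initial volumes of a BOLD run
#'
#' The first few volumes of a resting-state acquisition are routinely deleted
#' so that analysis starts after longitudinal magnetization has reached steady
#' state (10 volumes by pipeline default).
#'
#' @param bold A [bold4d()] object.
#' @param k Number of leading volumes to drop; must be smaller than the number
#'   of time points.
#' @return A `bold4d` with `t - k` time points; affine and TR unchanged.
#' @export
discard_initial_volumes <- function(bold, k) {
  bold <- as_bold4d(bold)
  nt <- dim(bold$data)[4]
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 0L)
    stop("'k' must be a single non-negative integer")
  if (k >= nt)
    stop("cannot discard ", k, " volumes from a series of length ", nt)
  if (k == 0L) return(bold)
  d <- dim(bold$data)
  nvox <- prod(d[1:3])
  kept <- bold$data[(k * nvox + 1L):(nvox * nt)]   # time-contiguous slice
  dim(kept) <- c(d[1:3], nt - k)
  bold$data <- kept
  bold
}

#' Motion-based subject exclusion
#'
#' Applies the head-motion exclusion rule: a subject is excluded when the
#' maximum per-volume displacement strictly exceeds the threshold (an
#' exclusion rule of "over 3 mm" keeps a subject at exactly 3.0 mm).
#'
#' @param trace Numeric vector of per-volume maximum displacements in mm.
#' @param threshold_mm Exclusion threshold in mm (default 3).
#' @return List with `include` (logical), `max_mm`, and `threshold_mm`.
#' @export
motion_screen <- function(trace, threshold_mm = 3) {
  if (length(trace) == 0L) stop("empty motion trace")
  if (!is.numeric(trace) || any(!is.finite(trace)) || any(trace < 0))
    stop("motion trace must be finite and non-negative")
  if (!is.numeric(threshold_mm) || threshold_mm <= 0)
    stop("'threshold_mm' must be positive")
  mx <- max(trace)
  list(include = mx <= threshold_mm, max_mm = mx, threshold_mm = threshold_mm)
}

#' Mean-preserving linear detrend
#'
#' Removes the ordinary-least-squares linear trend from every in-mask voxel
#' time series while keeping the temporal mean unchanged. PerAF divides by the
#' temporal mean, so detrending must not recenter the series: only the slope
#' component (which has zero mean over the scan) is subtracted.
#'
#' @param bold A [bold4d()] object with at least 3 time points.
#' @param mask Optional 3D logical array; out-of-mask voxels are untouched.
#' @return A `bold4d` with per-voxel linear trends removed.
#' @export
detrend_linear <- function(bold, mask = NULL) {
  bold <- as_bold4d(bold)
  dims <- dim(bold$data)
  nt <- dims[4]
  if (nt < 3L) stop("linear detrending needs at least 3 time points")
  if (is.null(mask)) mask <- array(TRUE, dims[1:3])
  if (!identical(as.integer(dim(mask)), as.integer(dims[1:3])))
    stop("mask dimensions do not match volume")
  idx <- which(mask)
  if (length(idx) == 0L) return(bold)
  nvox <- prod(dims[1:3])
  # centred-time OLS slope removed per voxel; the trend component has zero
  # temporal mean, so the voxel mean is preserved exactly
  out <- cpp_detrend_rows(bold$data, nvox, nt, as.integer(idx))
  dim(out) <- dims
  bold$data <- out
  bold
}

#' Separable Gaussian spatial smoothing
#'
#' Convolves each time frame (or a single 3D map) with a separable Gaussian
#' kernel of the given full width at half maximum per axis, with half-sample
#' reflection at the volume boundary. The kernel standard deviation per axis
#' is \eqn{\mathrm{FWHM} / (2\sqrt{2\ln 2})} in mm, converted to voxels via
#' the voxel size.
#'
#' @param x A [bold4d()] object or a 3D numeric array.
#' @param fwhm_mm FWHM in mm; length 1 (isotropic) or 3. `0` disables
#'   smoothing along that axis.
#' @param voxel_size_mm Voxel size in mm; taken from the affine for `bold4d`
#'   input.
#' @return Object of the same type, smoothed.
#' @export
smooth_gaussian <- function(x, fwhm_mm, voxel_size_mm = c(3, 3, 3)) {
  if (length(fwhm_mm) == 1L) fwhm_mm <- rep(fwhm_mm, 3)
  if (length(fwhm_mm) != 3L || any(!is.finite(fwhm_mm)) || any(fwhm_mm < 0))
    stop("'fwhm_mm' must be 3 non-negative values")
  is_bold <- inherits(x, "bold4d")
  if (is_bold) {
    voxel_size_mm <- sqrt(colSums(x$affine[1:3, 1:3]^2))
    arr <- x$data
  } else {
    if (!is.array(x) || !(length(dim(x)) %in% c(3L, 4L)))
      stop("'x' must be a bold4d or a 3D/4D array")
    arr <- x
  }
  sd_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  if (any(sd_vox > 0)) {
    d <- dim(arr)
    dims4 <- if (length(d) == 3L) c(d, 1L) else d
    arr <- cpp_smooth_frames(arr, as.integer(dims4), sd_vox)
    dim(arr) <- d
  }
  if (is_bold) { x$data <- arr; x } else arr
}
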