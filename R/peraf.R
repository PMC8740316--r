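#' Percent amplitude of fluctuation of a single BOLD time series
#'
#' PerAF expresses the mean absolute deviation of a voxel's BOLD signal from
#' its temporal mean as a percentage of that mean:
#' \deqn{\mathrm{PerAF} = \frac{1}{n}\sum_{i=1}^{n}
#'   \left|\frac{x_i - \mu}{\mu}\right| \times 100,\qquad
#'   \mu = \frac{1}{n}\sum_{i=1}^{n} x_i.}
#' Because the deviation is taken relative to the voxel's own mean, PerAF is
#' invariant to the arbitrary scanner gain of the raw signal (scaling the
#' series by any positive constant leaves it unchanged).
#'
#' @param x Numeric vector of BOLD intensities, length at least 2, all finite.
#' @return PerAF in percent. If the temporal mean is not strictly positive the
#'   metric is undefined and `NA_real_` is returned (such voxels are masked
#'   out, never imputed).
#' @examples
#' peraf_series(c(1, 2, 3))  # 100/3
#' peraf_series(c(5, 5, 5))  # 0
#' @export
peraf_series <- function(x) {
  if (!is.numeric(x) || length(x) < 2)
    stop("'x' must be a numeric series with at least 2 time points")
  if (!all(is.finite(x)))
    stop("'x' contains non-finite values")
  mu <- mean(x)
  if (mu <= 0) return(NA_real_)
  mean(abs(x - mu)) / mu * 100
}

#' Voxel-wise PerAF map of a 4D BOLD volume
#'
#' Applies [peraf_series()] to every in-mask voxel. Voxels whose temporal mean
#' is not strictly positive are undefined: they are recorded as `NA`, removed
#' from the output mask, and counted in `n_undefined`.
#'
#' @param bold A [bold4d()] object or a 4D numeric array (x, y, z, t).
#' @param mask 3D logical array matching the spatial dimensions, or `NULL` to
#'   use all voxels.
#' @return An object of class `peraf_map`: list with `values` (3D array, %),
#'   `mask` (3D logical, undefined voxels removed), `standardized`
#'   (`"raw"` or `"mperaf"`), `affine`, and `n_undefined`.
#' @seealso [mperaf_standardize()]
#' @export
peraf_map <- function(bold, mask = NULL) {
  bold <- as_bold4d(bold)
  dims <- dim(bold$data)
  sdim <- dims[1:3]
  if (is.null(mask)) mask <- array(TRUE, sdim)
  if (!identical(as.integer(dim(mask)), as.integer(sdim)))
    stop("mask dimensions ", paste(dim(mask), collapse = "x"),
         " do not match volume spatial dimensions ", paste(sdim, collapse = "x"))
  mask <- array(as.logical(mask), sdim)
  values <- array(NA_real_, sdim)
  idx <- which(mask)
  if (length(idx) == 0L) {
    warning("empty mask: PerAF map contains no defined voxels")
    return(new_peraf_map(values, mask, bold$affine, 0L))
  }
  pa <- cpp_peraf_rows(bold$data, prod(sdim), dims[4], as.integer(idx))
  undef <- idx[is.na(pa[idx])]
  values[idx] <- pa[idx]
  mask[undef] <- FALSE
  new_peraf_map(values, mask, bold$affine, length(undef))
}

new_peraf_map <- function(values, mask, affine, n_undefined,
                          standardized = "raw") {
  structure(list(values = values, mask = mask, standardized = standardized,
                 affine = affine, n_undefined = as.integer(n_undefined)),
            class = "peraf_map")
}

#' Mean-standardize a PerAF map (mPerAF)
#'
#' Divides every in-mask PerAF value by the in-mask mean, so the standardized
#' map has in-mask mean exactly 1. This removes between-subject differences in
#' global fluctuation amplitude before group statistics; per-voxel scanner gain
#' is already removed by PerAF itself.
#'
#' @param map A `peraf_map`.
#' @return A `peraf_map` with `standardized = "mperaf"`. Idempotent.
#' @export
mperaf_standardize <- function(map) {
  stopifnot(inherits(map, "peraf_map"))
  idx <- which(map$mask)
  if (length(idx) == 0L) stop("cannot standardize a map with an empty mask")
  m <- mean(map$values[idx])
  if (!is.finite(m) || m <= 0)
    stop("in-mask mean must be strictly positive for mPerAF standardization")
  map$values[idx] <- map$values[idx] / m
  map$standardized <- "mperaf"
  map
}

#' @export
print.peraf_map <- function(x, ...) {
  cat("PerAF map (", x$standardized, "), ",
      paste(dim(x$values), collapse = " x "),
      ", ", sum(x$mask), " in-mask voxels, ",
      x$n_undefined, " undefined\n", sep = "")
  invisible(x)
}
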