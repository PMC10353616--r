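#' Drop initial volumes from a run
#'
#' Removes the first `k` volumes (scanner equilibration period).
#'
#' @param run A [bold_run()].
#' @param k Number of leading volumes to remove (default 10).
#' @return The shortened [bold_run()].
#' @export
drop_initial_volumes <- function(run, k = 10L) {
  n_t <- dim(run$data)[4]
  if (k < 0) stop("`k` must be nonnegative")
  if (k >= n_t)
    stop(sprintf("cannot drop %d volumes from a run of %d", k, n_t))
  if (k == 0L) return(run)
  bold_run(run$data[, , , (k + 1):n_t, drop = FALSE], tr_s = run$tr_s,
           affine = run$affine, mask = run$mask)
}

# Flatten a 4D run to a T x V matrix and back.
run_as_matrix <- function(run) {
  d <- dim(run$data)
  t(matrix(run$data, prod(d[1:3]), d[4]))
}
matrix_as_run <- function(y, run) {
  d <- dim(run$data)
  bold_run(array(t(y), dim = d), tr_s = run$tr_s, affine = run$affine,
           mask = run$mask)
}

#' Remove the linear trend from every voxel series
#'
#' Subtracts the per-voxel least-squares line `a + b t`; residual series
#' have exactly zero mean and zero linear trend.
#'
#' @param run A [bold_run()] with at least 3 volumes.
#' @return The detrended [bold_run()].
#' @export
detrend_linear <- function(run) {
  n_t <- dim(run$data)[4]
  if (n_t < 3) stop("linear detrending needs at least 3 time points")
  x <- cbind(1, seq_len(n_t))
  y <- run_as_matrix(run)
  beta <- solve(crossprod(x), crossprod(x, y))
  matrix_as_run(y - x %*% beta, run)
}

#' Regress nuisance signals out of every voxel series
#'
#' Per voxel, returns the OLS residual of the series on
#' `[intercept | regressors]`; residuals are orthogonal to every design
#' column.
#'
#' @param run A [bold_run()].
#' @param regressors Time x regressor numeric matrix (rows must match the
#'   run's length); column names are used in error messages.
#' @return The residual [bold_run()].
#' @export
regress_nuisance <- function(run, regressors) {
  n_t <- dim(run$data)[4]
  regressors <- as.matrix(regressors)
  if (nrow(regressors) != n_t)
    stop(sprintf("regressor rows (%d) must match run length (%d)",
                 nrow(regressors), n_t))
  if (any(!is.finite(regressors))) stop("regressors contain non-finite values")
  zero_col <- colSums(abs(regressors)) == 0
  if (any(zero_col))
    stop("all-zero regressor column(s): ",
         paste(colnames(regressors)[zero_col], collapse = ", "))
  x <- cbind(intercept = 1, regressors)
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    dropped <- colnames(x)[qx$pivot[(qx$rank + 1):ncol(x)]]
    stop("design is rank deficient; offending column(s): ",
         paste(dropped, collapse = ", "))
  }
  y <- run_as_matrix(run)
  matrix_as_run(y - x %*% solve(crossprod(x), crossprod(x, y)), run)
}

# Normalised 1D Gaussian kernel for a FWHM given in voxels; radius 4 sigma.
gaussian_kernel_1d <- function(fwhm_vox) {
  if (fwhm_vox <= 0) return(1)
  sigma <- fwhm_vox / (2 * sqrt(2 * log(2)))
  r <- max(1L, ceiling(4 * sigma))
  w <- exp(-((-r):r)^2 / (2 * sigma^2))
  w / sum(w)
}

# Convolve a 3D or 4D array along one spatial axis with zero padding
# outside the grid (time, if present, rides along as columns).
convolve_axis <- function(a, kernel, axis) {
  if (length(kernel) == 1L) return(a)
  d <- dim(a)
  nd <- length(d)
  perm <- c(axis, setdiff(seq_len(nd), axis))
  b <- aperm(a, perm)
  m <- dim(b)[1]
  bm <- matrix(b, m)
  r <- (length(kernel) - 1L) / 2L
  bp <- rbind(matrix(0, r, ncol(bm)), bm, matrix(0, r, ncol(bm)))
  out <- matrix(0, m, ncol(bm))
  for (k in seq_along(kernel))
    out <- out + kernel[k] * bp[(k - 1) + seq_len(m), , drop = FALSE]
  aperm(array(out, dim(b)), order(perm))
}

#' Spatial Gaussian smoothing
#'
#' Separable Gaussian convolution with per-axis
#' `sigma = FWHM / (2 sqrt(2 log 2))`, converted to voxel units via the
#' affine's scales; kernel truncated at 4 sigma and normalised to unit
#' sum; zero padding outside the grid.
#'
#' @param x A [bold_run()] (each volume smoothed) or [scalar_map()].
#' @param fwhm_mm Full width at half maximum in mm; scalar or length 3.
#' @return Same type as `x`.
#' @export
smooth_gaussian <- function(x, fwhm_mm = 6) {
  if (length(fwhm_mm) == 1L) fwhm_mm <- rep(fwhm_mm, 3)
  if (any(!is.finite(fwhm_mm)) || any(fwhm_mm < 0))
    stop("`fwhm_mm` must be finite and nonnegative")
  vs <- affine_voxel_sizes(x$affine)
  kernels <- lapply(1:3, function(ax) gaussian_kernel_1d(fwhm_mm[ax] / vs[ax]))
  smooth_arr <- function(a) {
    for (ax in 1:3) a <- convolve_axis(a, kernels[[ax]], ax)
    a
  }
  if (inherits(x, "bold_run")) {
    bold_run(smooth_arr(x$data), tr_s = x$tr_s, affine = x$affine,
             mask = x$mask)
  } else if (inherits(x, "scalar_map")) {
    scalar_map(smooth_arr(x$values), x$mask, x$affine, x$kind)
  } else stop("`x` must be a bold_run or scalar_map")
}

#' Mean framewise displacement from motion regressors
#'
#' Power-style FD: sum of absolute volume-to-volume differences of the six
#' rigid-body series, rotations (radians) converted to mm on a 50 mm
#' sphere. Reported for quality control; no censoring is applied.
#'
#' @param motion Time x 6 matrix (3 translations mm, 3 rotations rad).
#' @param radius_mm Head radius used for rotation conversion.
#' @return Mean FD in mm.
#' @export
mean_framewise_displacement <- function(motion, radius_mm = 50) {
  motion <- as.matrix(motion)
  if (ncol(motion) < 6) stop("`motion` needs 6 columns")
  d <- abs(diff(motion[, 1:6, drop = FALSE]))
  d[, 4:6] <- d[, 4:6] * radius_mm
  mean(rowSums(d))
}

#' Run the full preprocessing chain
#'
#' Applies, in order: initial-volume removal, linear detrending, nuisance
#' regression and Gaussian spatial smoothing. Regressor rows beyond the
#' retained volumes are trimmed to match.
#'
#' @param run A [bold_run()].
#' @param regressors Time x regressor matrix aligned to the *acquired*
#'   run (rows are trimmed along with the dropped volumes), or `NULL` to
#'   skip nuisance regression.
#' @param drop_k Leading volumes to discard (default 10).
#' @param fwhm_mm Smoothing kernel FWHM in mm (default 6); 0 disables.
#' @return The preprocessed [bold_run()].
#' @export
preprocess_run <- function(run, regressors = NULL, drop_k = 10L, fwhm_mm = 6) {
  out <- drop_initial_volumes(run, drop_k)
  out <- detrend_linear(out)
  if (!is.null(regressors)) {
    regressors <- as.matrix(regressors)
    if (nrow(regressors) == dim(run$data)[4] && drop_k > 0)
      regressors <- regressors[-seq_len(drop_k), , drop = FALSE]
    out <- regress_nuisance(out, regressors)
  }
  if (any(fwhm_mm > 0)) out <- smooth_gaussian(out, fwhm_mm)
  out
}
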