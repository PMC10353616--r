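#' Construct a BOLD run
#'
#' A `bold_run` bundles one subject's 4D BOLD time series with its sampling
#' interval and voxel-to-world geometry. The data array is ordered
#' (x, y, z, t); intensities are in arbitrary BOLD units.
#'
#' @param data 4D numeric array (x, y, z, t).
#' @param tr_s Sampling interval (repetition time) in seconds.
#' @param affine 4x4 voxel-to-world matrix (mm); defaults to a diagonal
#'   affine built from `voxel_size_mm`.
#' @param voxel_size_mm Length-3 voxel edge lengths in mm, used only when
#'   `affine` is missing.
#' @param mask Optional binary 3D array matching the spatial grid.
#' @return An object of class `bold_run`.
#' @export
bold_run <- function(data, tr_s, affine = NULL, voxel_size_mm = c(3, 3, 3),
                     mask = NULL) {
  if (length(dim(data)) != 4L)
    stop("`data` must be a 4D array (x, y, z, t)")
  if (dim(data)[4] < 2L)
    stop("a BOLD run needs at least 2 time points")
  if (!is.numeric(tr_s) || length(tr_s) != 1L || !is.finite(tr_s) || tr_s <= 0)
    stop("`tr_s` must be a single positive number (seconds)")
  if (is.null(affine)) affine <- diag(c(voxel_size_mm, 1))
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < .Machine$double.eps)
    stop("`affine` must be an invertible 4x4 matrix")
  if (!is.null(mask)) {
    if (!all(dim(mask)[1:3] == dim(data)[1:3]))
      stop("`mask` spatial shape must match `data`")
    mask <- array(as.numeric(mask != 0), dim = dim(data)[1:3])
  }
  structure(list(data = data, tr_s = tr_s, affine = affine, mask = mask),
            class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_run> %d x %d x %d grid, %d volumes, TR = %g s\n",
              d[1], d[2], d[3], d[4], x$tr_s))
  cat(sprintf("  voxel size: %s mm\n",
              paste(signif(affine_voxel_sizes(x$affine), 4), collapse = " x ")))
  invisible(x)
}

#' Construct a per-voxel scalar map
#'
#' A `scalar_map` is a 3D map of a voxelwise statistic (ALFF, mALFF,
#' dALFF-CV, t or z) together with the analysis mask and geometry.
#' Out-of-mask voxels are conventionally 0.
#'
#' @param values 3D numeric array.
#' @param mask Binary 3D array of the same shape.
#' @param affine 4x4 voxel-to-world matrix (mm).
#' @param kind One of `"alff"`, `"malff"`, `"dalff_cv"`, `"tstat"`,
#'   `"zstat"`, `"generic"`.
#' @return An object of class `scalar_map`.
#' @export
scalar_map <- function(values, mask, affine,
                       kind = c("generic", "alff", "malff", "dalff_cv",
                                "tstat", "zstat")) {
  kind <- match.arg(kind)
  if (length(dim(values)) != 3L) stop("`values` must be a 3D array")
  if (!all(dim(values) == dim(mask))) stop("`mask` shape must match `values`")
  mask <- array(as.numeric(mask != 0), dim = dim(values))
  if (any(!is.finite(values[mask > 0])))
    stop("scalar map has non-finite values inside the mask")
  structure(list(values = values, mask = mask, affine = as.matrix(affine),
                 kind = kind),
            class = "scalar_map")
}

#' @export
print.scalar_map <- function(x, ...) {
  v <- x$values[x$mask > 0]
  cat(sprintf("<scalar_map:%s> %s grid, %d in-mask voxels, range [%.4g, %.4g]\n",
              x$kind, paste(dim(x$values), collapse = " x "),
              sum(x$mask > 0), min(v), max(v)))
  invisible(x)
}

# Voxel edge lengths (mm) encoded in an affine.
affine_voxel_sizes <- function(affine) {
  sqrt(colSums(affine[1:3, 1:3]^2))
}

#' Map 1-based voxel indices to world (mm) coordinates
#'
#' Uses the NIfTI convention that the affine maps 0-based voxel indices,
#' so voxel (1,1,1) maps to the affine's translation column.
#'
#' @param ijk Integer vector of length 3 (1-based voxel indices) or an
#'   n x 3 matrix.
#' @param affine 4x4 voxel-to-world matrix.
#' @return Numeric world coordinates, same shape as `ijk`.
#' @export
voxel_to_world <- function(ijk, affine) {
  ijk <- rbind(ijk)
  xyz <- t(affine %*% rbind(t(ijk) - 1, 1))[, 1:3, drop = FALSE]
  if (nrow(xyz) == 1L) drop(xyz) else xyz
}

#' Map world (mm) coordinates back to 1-based voxel indices
#'
#' @param xyz Numeric vector of length 3 or an n x 3 matrix of world
#'   coordinates.
#' @param affine 4x4 voxel-to-world matrix.
#' @return Voxel indices (1-based, not rounded).
#' @export
world_to_voxel <- function(xyz, affine) {
  xyz <- rbind(xyz)
  ijk <- t(solve(affine) %*% rbind(t(xyz), 1))[, 1:3, drop = FALSE] + 1
  if (nrow(ijk) == 1L) drop(ijk) else ijk
}
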