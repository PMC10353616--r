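#' Generate an ellipsoidal brain mask
#'
#' Builds a deterministic, axis-aligned ellipsoid inscribed in the grid,
#' with semi-axes 0.45 of each grid extent, centred on the grid centre.
#' Serves as the analysis "brain" for synthetic cohorts.
#'
#' @param grid_shape Integer vector of 3 voxel counts, each >= 8.
#' @param voxel_size_mm Length-3 voxel edge lengths (mm); recorded in the
#'   returned affine, the ellipsoid itself is defined in voxel units.
#' @return A `scalar_map` of kind `"generic"` whose values (and mask) are
#'   the binary ellipsoid.
#' @export
generate_brain_mask <- function(grid_shape, voxel_size_mm = c(3, 3, 3)) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 8L))
    stop("`grid_shape` must be 3 voxel counts, all >= 8 (got: ",
         paste(grid_shape, collapse = ", "), ")")
  centre <- (grid_shape + 1) / 2
  semi <- 0.45 * grid_shape
  i <- ((seq_len(grid_shape[1]) - centre[1]) / semi[1])^2
  j <- ((seq_len(grid_shape[2]) - centre[2]) / semi[2])^2
  k <- ((seq_len(grid_shape[3]) - centre[3]) / semi[3])^2
  r2 <- outer(outer(i, j, `+`), k, `+`)
  m <- array(as.numeric(r2 <= 1), dim = grid_shape)
  scalar_map(m, m, diag(c(voxel_size_mm, 1)))
}

#' Define a spherical region of interest
#'
#' @param center_voxel 1-based voxel indices of the sphere centre.
#' @param radius_mm Sphere radius in mm.
#' @param label Region name used in reports.
#' @return An object of class `roi_sphere`.
#' @export
roi_sphere <- function(center_voxel, radius_mm, label) {
  if (length(center_voxel) != 3L) stop("`center_voxel` must have length 3")
  if (!is.finite(radius_mm) || radius_mm <= 0)
    stop("`radius_mm` must be positive")
  structure(list(center_voxel = as.numeric(center_voxel),
                 radius_mm = as.numeric(radius_mm),
                 label = as.character(label)),
            class = "roi_sphere")
}

#' Rasterise a spherical ROI onto a grid
#'
#' @param roi An `roi_sphere`.
#' @param grid_shape Integer vector of 3 voxel counts.
#' @param voxel_size_mm Length-3 voxel edges (mm).
#' @param brain_mask Optional binary 3D array; the sphere is intersected
#'   with it and the intersection must be nonempty.
#' @return Binary 3D array.
#' @export
roi_mask <- function(roi, grid_shape, voxel_size_mm = c(3, 3, 3),
                     brain_mask = NULL) {
  if (roi$radius_mm < min(voxel_size_mm))
    stop("ROI radius must be at least one voxel edge")
  dx <- (seq_len(grid_shape[1]) - roi$center_voxel[1]) * voxel_size_mm[1]
  dy <- (seq_len(grid_shape[2]) - roi$center_voxel[2]) * voxel_size_mm[2]
  dz <- (seq_len(grid_shape[3]) - roi$center_voxel[3]) * voxel_size_mm[3]
  r2 <- outer(outer(dx^2, dy^2, `+`), dz^2, `+`)
  m <- array(as.numeric(r2 <= roi$radius_mm^2), dim = grid_shape)
  if (!is.null(brain_mask)) {
    m <- m * (brain_mask != 0)
    if (sum(m) == 0)
      stop("ROI '", roi$label, "' does not intersect the brain mask")
  }
  m
}
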