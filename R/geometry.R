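#' Grid geometry of a voxel volume
#'
#' Describes the sampling grid shared by all volumes in an analysis: voxel
#' counts per axis, voxel size in mm, and the affine mapping 0-based voxel
#' indices to world coordinates in mm (RAS convention: world x increases to
#' the subject's right, so the right hemisphere has x > 0). All cross-volume
#' operations in the package require *identical* grids; there is no on-the-fly
#' resampling, because registration to the template is upstream of this
#' pipeline.
#'
#' @param dims Integer vector of length 3, voxels per axis (all >= 1).
#' @param voxel_size Numeric length 3 (or 1, recycled), mm per voxel (> 0).
#' @param affine 4x4 voxel-index-to-world matrix; default centers the grid at
#'   the world origin with axis-aligned spacing `voxel_size`.
#' @param space_label Free-text space tag, e.g. `"MNI-152 1 mm"` or `"toy"`.
#' @return An object of class `grid_geometry`.
#' @export
grid_geometry <- function(dims, voxel_size = 1,
                          affine = NULL, space_label = "unspecified") {
  dims <- as.integer(dims)
  assert_that(length(dims) == 3 && all(dims >= 1L), "dims must be 3 values >= 1")
  voxel_size <- rep_len(as.numeric(voxel_size), 3)
  assert_that(all(voxel_size > 0), "voxel_size must be positive")
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
    affine[1:3, 4] <- -voxel_size * (dims - 1) / 2
  }
  affine <- unname(as.matrix(affine))
  assert_that(all(dim(affine) == c(4, 4)), "affine must be 4x4")
  assert_that(abs(det(affine)) > .Machine$double.eps, "affine must be invertible")
  structure(
    list(dims = dims, voxel_size = voxel_size, affine = affine,
         space_label = space_label),
    class = "grid_geometry"
  )
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("<grid_geometry> %s: %s voxels, %s mm\n",
              x$space_label, paste(x$dims, collapse = "x"),
              paste(signif(x$voxel_size, 4), collapse = "x")))
  invisible(x)
}

#' Compare two grids within an affine tolerance
#'
#' @param a,b `grid_geometry` objects.
#' @param tol Absolute per-element tolerance on the affine (mm); guards
#'   against float drift without masking real mismatches.
#' @return `TRUE`/`FALSE`.
#' @export
grids_equal <- function(a, b, tol = 1e-4) {
  identical(a$dims, b$dims) &&
    all(abs(a$voxel_size - b$voxel_size) <= tol) &&
    all(abs(a$affine - b$affine) <= tol)
}

check_same_grid <- function(a, b, what = "volume", tol = 1e-4) {
  if (!grids_equal(a, b, tol = tol)) {
    stop_fm("grid mismatch for %s: [%s @ %s mm] vs [%s @ %s mm]", what,
            paste(a$dims, collapse = "x"), paste(signif(a$voxel_size, 4), collapse = "x"),
            paste(b$dims, collapse = "x"), paste(signif(b$voxel_size, 4), collapse = "x"))
  }
  invisible(TRUE)
}

#' Volume of one voxel in millilitres
#'
#' 1000 mm^3 = 1 ml, so a 1 mm isotropic voxel is 0.001 ml.
#'
#' @param grid A `grid_geometry`.
#' @return Scalar, ml per voxel.
#' @export
voxel_volume_ml <- function(grid) prod(grid$voxel_size) / 1000

# world-mm coordinates of every voxel along one axis (0-based indices)
axis_world <- function(grid, axis) {
  idx <- seq_len(grid$dims[axis]) - 1
  grid$affine[axis, axis] * idx + grid$affine[axis, 4]
}

# 3D array of world x-coordinates (for laterality); vectorized over the grid
world_x_array <- function(grid) {
  x <- axis_world(grid, 1)
  array(rep(x, times = prod(grid$dims[2:3])), dim = grid$dims)
}
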