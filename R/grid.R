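# Sampling-grid geometry shared by every volume in a study.
#
# Convention: RAS world axes (x = right, y = anterior, z = superior),
# 0-based voxel indices in the affine sense but 1-based R arrays; the
# affine maps voxel index (i-1, j-1, k-1) to mm.

#' Define a regular axis-aligned sampling grid
#'
#' A `grid_spec` fixes the sampling lattice shared by all volumes of an
#' analysis: array shape, isotropic or anisotropic voxel size, and the
#' world (mm) coordinate of the first voxel. The derived affine is
#' diagonal-plus-translation and RAS-oriented (world x > 0 is the
#' subject's right). Mirroring about the midsagittal plane is only
#' defined on grids whose x extent is symmetric about world x = 0; see
#' [is_x_symmetric()].
#'
#' @param shape integer vector of length 3, array dimensions (all >= 1).
#' @param voxel_mm positive numeric vector of length 3, voxel edge
#'   lengths in mm.
#' @param origin_mm numeric vector of length 3, world coordinate of the
#'   voxel at array index (1,1,1). Defaults to centring the grid on the
#'   world origin, which makes every axis extent symmetric.
#' @return An object of class `grid_spec`.
#' @seealso [default_grid()] for the standard normalized-space grid.
#' @export
#' @examples
#' g <- grid_spec(c(9, 9, 9), c(2, 2, 2))
#' coords_mm(g, 1)
grid_spec <- function(shape, voxel_mm = c(2, 2, 2), origin_mm = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("'shape' must be 3 integers, all >= 1", call. = FALSE)
  voxel_mm <- as.numeric(voxel_mm)
  if (length(voxel_mm) != 3L || any(!is.finite(voxel_mm)) || any(voxel_mm <= 0))
    stop("'voxel_mm' must be 3 positive reals", call. = FALSE)
  if (is.null(origin_mm))
    origin_mm <- -(shape - 1L) * voxel_mm / 2
  origin_mm <- as.numeric(origin_mm)
  if (length(origin_mm) != 3L || any(!is.finite(origin_mm)))
    stop("'origin_mm' must be 3 finite reals", call. = FALSE)
  structure(list(shape = shape, voxel_mm = voxel_mm, origin_mm = origin_mm),
            class = "grid_spec")
}

#' The default normalized-space grid
#'
#' 91 x 109 x 91 voxels at 2 mm isotropic with origin (-90, -126, -72) mm:
#' the common 2-mm grid of anatomically normalized brain images. Its x
#' extent runs from -90 to +90 mm and is symmetric about the midline, so
#' left-right mirroring is a pure index flip.
#'
#' @return A `grid_spec`.
#' @export
default_grid <- function() {
  grid_spec(c(91L, 109L, 91L), c(2, 2, 2), c(-90, -126, -72))
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid: %d x %d x %d voxels, %.3g x %.3g x %.3g mm, origin (%g, %g, %g) mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$voxel_mm[1], x$voxel_mm[2], x$voxel_mm[3],
              x$origin_mm[1], x$origin_mm[2], x$origin_mm[3]))
  invisible(x)
}

#' Voxel-to-world affine of a grid
#'
#' @param grid a `grid_spec`.
#' @return A 4x4 matrix mapping 0-based voxel indices to world mm.
#' @export
grid_affine <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  aff <- diag(4)
  diag(aff)[1:3] <- grid$voxel_mm
  aff[1:3, 4] <- grid$origin_mm
  aff
}

#' World coordinates of voxel centres along one axis
#'
#' @param grid a `grid_spec`.
#' @param axis 1 (x), 2 (y) or 3 (z).
#' @return Numeric vector of world mm coordinates, one per voxel.
#' @export
coords_mm <- function(grid, axis) {
  stopifnot(inherits(grid, "grid_spec"), axis %in% 1:3)
  grid$origin_mm[axis] + (seq_len(grid$shape[axis]) - 1) * grid$voxel_mm[axis]
}

#' Test whether a grid's x extent is symmetric about the midline
#'
#' Mirroring about world x = 0 is an exact index flip only when the first
#' and last voxel-centre x coordinates are opposite; otherwise flipping
#' the array would silently shift the anatomy.
#'
#' @param grid a `grid_spec`.
#' @param tol absolute tolerance in mm.
#' @return Logical scalar.
#' @export
is_x_symmetric <- function(grid, tol = 1e-6) {
  x <- coords_mm(grid, 1)
  abs(x[1] + x[length(x)]) <= tol
}

check_x_symmetric <- function(grid) {
  if (!is_x_symmetric(grid))
    stop("grid x extent is not symmetric about world x = 0; ",
         "mirroring would change world coordinates", call. = FALSE)
  invisible(grid)
}

#' Compare two grids for equality
#'
#' @param a,b `grid_spec` objects.
#' @param tol absolute tolerance on voxel size and origin, mm.
#' @return Logical scalar.
#' @export
grids_equal <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) &&
    all(abs(a$voxel_mm - b$voxel_mm) <= tol) &&
    all(abs(a$origin_mm - b$origin_mm) <= tol)
}

check_same_grid <- function(a, b) {
  if (!grids_equal(a, b))
    stop("volumes are defined on different grids; resampling is never ",
         "done implicitly", call. = FALSE)
  invisible(a)
}

# Reconstruct a grid_spec from an axis-aligned RAS affine.
grid_from_affine <- function(affine, shape) {
  rot <- affine[1:3, 1:3]
  if (max(abs(rot - diag(diag(rot)))) > 1e-4)
    stop("oblique or rotated affines are not supported; volumes must be ",
         "axis-aligned in RAS orientation", call. = FALSE)
  if (any(diag(rot) <= 0))
    stop("affine is not RAS-oriented (non-positive axis scale)", call. = FALSE)
  grid_spec(shape, diag(rot), affine[1:3, 4])
}
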