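# 3D scalar volumes: container, NIfTI-1 / Analyze 7.5 I/O, midline flip.

VALUE_KINDS <- c("counts", "sbg_ratio", "label")

#' Construct a 3D volume on a grid
#'
#' The basic container of the package: a 3D scalar array plus its
#' sampling grid and a value kind. `counts` volumes hold reconstructed
#' tracer counts, `sbg_ratio` volumes hold dimensionless
#' specific-to-background ratios (cortex around 1), and `label` volumes
#' hold non-negative integer region codes (0 = background).
#'
#' @param data a numeric or logical 3D array; dimensions must match
#'   `grid$shape`. Logical arrays are stored as 0/1 integers.
#' @param grid a [grid_spec()].
#' @param kind one of `"counts"`, `"sbg_ratio"`, `"label"`.
#' @return An object of class `volume3d` with fields `data`, `grid`,
#'   `affine` (4x4 voxel-to-world transform) and `kind`.
#' @export
volume3d <- function(data, grid, kind = c("counts", "sbg_ratio", "label")) {
  kind <- match.arg(kind)
  stopifnot(inherits(grid, "grid_spec"))
  if (is.logical(data)) {
    storage.mode(data) <- "integer"
  }
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must have exactly 3 axes", call. = FALSE)
  if (!all(dim(data) == grid$shape))
    stop("data dimensions do not match the grid shape", call. = FALSE)
  if (kind == "label") {
    v <- data[data != 0]
    if (length(v) && (any(v < 0) || any(v != round(v))))
      stop("label volumes must contain non-negative integers", call. = FALSE)
  }
  structure(list(data = data, grid = grid, affine = grid_affine(grid),
                 kind = kind),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  cat(sprintf("volume3d [%s]: %d x %d x %d voxels, range [%.4g, %.4g]\n",
              x$kind, dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              min(x$data), max(x$data)))
  print(x$grid)
  invisible(x)
}

# Coerce a mask argument (volume3d label volume or logical/0-1 array)
# to a plain logical array, checking the grid when one is carried.
as_mask_array <- function(mask, grid = NULL) {
  if (inherits(mask, "volume3d")) {
    if (!is.null(grid)) check_same_grid(mask$grid, grid)
    return(mask$data != 0)
  }
  if (is.array(mask) && length(dim(mask)) == 3L) {
    if (!is.null(grid) && !all(dim(mask) == grid$shape))
      stop("mask dimensions do not match the grid", call. = FALSE)
    return(mask != 0)
  }
  stop("mask must be a volume3d or a 3D array", call. = FALSE)
}

#' Wrap a binary mask as a label volume
#'
#' @param mask logical or 0/1 3D array.
#' @param grid the [grid_spec()] the mask lives on.
#' @return A `volume3d` of kind `"label"` with values 0/1.
#' @export
mask_volume <- function(mask, grid) {
  volume3d(array(as.integer(mask != 0), dim(mask)), grid, "label")
}

flip_x_array <- function(a) {
  a[dim(a)[1]:1, , , drop = FALSE]
}

#' Mirror a volume about the midsagittal plane
#'
#' Reflects the volume about world x = 0 by reversing the x index — no
#' interpolation ever occurs. Requires a grid whose x extent is
#' symmetric about the midline (see [is_x_symmetric()]); on such a grid
#' a voxel at world (+x, y, z) lands exactly on the voxel at (-x, y, z).
#' `flip_lr` is an involution and preserves the multiset of voxel
#' values.
#'
#' @param vol a `volume3d`.
#' @return The mirrored `volume3d` on the same grid.
#' @export
flip_lr <- function(vol) {
  stopifnot(inherits(vol, "volume3d"))
  check_x_symmetric(vol$grid)
  volume3d(flip_x_array(vol$data), vol$grid, vol$kind)
}

#' Read a volume from NIfTI-1 or Analyze 7.5
#'
#' NIfTI-1 (`.nii` / `.nii.gz`) is read through its sform/qform affine,
#' which must be axis-aligned RAS. Analyze 7.5 (`.hdr` / `.img`,
#' optionally gzipped) carries no orientation; files are assumed LAS —
#' the historically common dialect — and converted to RAS by flipping
#' the first axis, with the grid origin placed so every axis extent is
#' centred on the world origin. This assumption is fixed and documented
#' rather than guessed per file.
#'
#' The value kind is recovered from the NIfTI `intent_name` field when
#' the file was written by [write_volume()]; otherwise pass `kind`.
#'
#' @param path path to a `.nii`, `.nii.gz`, `.hdr` or `.img` file.
#' @param kind optional override for the value kind.
#' @return A `volume3d`.
#' @export
read_volume <- function(path, kind = NULL) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- tryCatch(RNifti::readNifti(path),
                    error = function(e) stop("unreadable NIfTI file: ", path,
                                             " (", conditionMessage(e), ")",
                                             call. = FALSE))
    if (length(dim(img)) != 3L)
      stop("expected a 3D volume, got ", length(dim(img)), " axes",
           call. = FALSE)
    grid <- grid_from_affine(structure(RNifti::xform(img), dim = c(4, 4)),
                             dim(img))
    if (is.null(kind)) {
      intent <- RNifti::niftiHeader(img)$intent_name
      kind <- if (intent %in% VALUE_KINDS) intent else "counts"
    }
    dat <- array(as.vector(img), dim(img))
    return(volume3d(dat, grid, kind))
  }
  if (grepl("\\.(hdr|img)(\\.gz)?$", path)) {
    stem <- sub("\\.(hdr|img)(\\.gz)?$", "", path)
    img <- tryCatch(oro.nifti::readANALYZE(stem),
                    error = function(e) stop("unreadable Analyze file: ", path,
                                             " (", conditionMessage(e), ")",
                                             call. = FALSE))
    dat <- img@.Data
    if (length(dim(dat)) == 4L && dim(dat)[4] == 1L)
      dat <- array(dat, dim(dat)[1:3])
    if (length(dim(dat)) != 3L)
      stop("expected a 3D volume, got ", length(dim(dat)), " axes",
           call. = FALSE)
    vox <- img@pixdim[2:4]
    vox[vox <= 0] <- 1
    grid <- grid_spec(dim(dat), vox)      # centred; x symmetric by design
    dat <- flip_x_array(dat)              # LAS -> RAS
    if (is.null(kind)) kind <- "counts"
    return(volume3d(array(as.numeric(dat), dim(dat)), grid, kind))
  }
  stop("unrecognized volume format: ", path,
       " (expected .nii, .nii.gz, .hdr or .img)", call. = FALSE)
}

#' Write a volume as NIfTI-1
#'
#' Label volumes are stored losslessly as 32-bit integers; counts and
#' S/BG ratio volumes at 32-bit float precision. The value kind is
#' recorded in the NIfTI `intent_name` field so [read_volume()] can
#' recover it. Analyze 7.5 is read-only in this package.
#'
#' @param vol a `volume3d`.
#' @param path output path ending in `.nii` or `.nii.gz`; the parent
#'   directory must exist.
#' @return Invisibly, `path`.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume3d"))
  if (!grepl("\\.nii(\\.gz)?$", path))
    stop("volumes are written as NIfTI-1 (.nii or .nii.gz); got: ", path,
         call. = FALSE)
  if (!dir.exists(dirname(path)))
    stop("cannot write '", path, "': parent directory does not exist",
         call. = FALSE)
  dat <- vol$data
  storage.mode(dat) <- if (vol$kind == "label") "integer" else "double"
  img <- RNifti::asNifti(dat)
  RNifti::pixdim(img) <- vol$grid$voxel_mm
  RNifti::sform(img) <- structure(vol$affine, code = 2L)
  RNifti::qform(img) <- structure(vol$affine, code = 2L)
  hdr <- RNifti::niftiHeader(img)
  hdr$intent_name <- vol$kind
  dtype <- if (vol$kind == "label") "int32" else "float"
  img <- RNifti::asNifti(dat, reference = hdr, datatype = dtype)
  RNifti::writeNifti(img, path)
  invisible(path)
}
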