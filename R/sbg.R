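# Background normalization: count volumes -> S/BG ratio images, and
# cohort template averaging.
#
# The S/BG (specific-to-background) ratio is defined as voxel value
# divided by the mean cerebral-cortex background, so cortex sits near 1
# and normal striatum near 4-7. The alternative (S - BG)/BG definition
# is NOT used: threshold cutoffs in the 3-5 range refer to the pure
# ratio scale.

#' Define a background ROI
#'
#' A binary mask of nonspecific (cerebral-cortex) voxels over which the
#' background level is measured as the mean voxel value.
#'
#' @param mask a `volume3d` label volume or logical array; must be
#'   nonempty.
#' @param grid the [grid_spec()] (ignored if `mask` is a `volume3d`).
#' @param definition `"cortex_label"` (ground-truth or drawn cortex
#'   mask) or `"auto_lowuptake"` (built by [build_auto_background()]).
#' @param exclusion_margin_mm striatal safety margin used in auto mode
#'   (recorded for provenance).
#' @return An object of class `background_roi`.
#' @export
background_roi <- function(mask, grid = NULL,
                           definition = c("cortex_label", "auto_lowuptake"),
                           exclusion_margin_mm = NA_real_) {
  definition <- match.arg(definition)
  if (inherits(mask, "volume3d")) grid <- mask$grid
  stopifnot(inherits(grid, "grid_spec"))
  m <- as_mask_array(mask, grid)
  if (!any(m)) stop("background ROI is empty", call. = FALSE)
  structure(list(mask = m, grid = grid, definition = definition,
                 exclusion_margin_mm = exclusion_margin_mm),
            class = "background_roi")
}

#' Build the cortex-label background ROI of a phantom
#'
#' @param labels anatomy label `volume3d` (cortex coded 1).
#' @return A `background_roi` with definition `"cortex_label"`.
#' @export
cortex_background <- function(labels) {
  stopifnot(inherits(labels, "volume3d"), labels$kind == "label")
  background_roi(labels$data == 1L, labels$grid, "cortex_label")
}

#' Measure the background level of a count volume
#'
#' Mean voxel value inside the background ROI — the divisor of the S/BG
#' normalization.
#'
#' @param vol a `volume3d`.
#' @param bg a [background_roi()] on the same grid.
#' @return Scalar mean background value.
#' @export
measure_background <- function(vol, bg) {
  stopifnot(inherits(vol, "volume3d"), inherits(bg, "background_roi"))
  check_same_grid(vol$grid, bg$grid)
  mean(vol$data[bg$mask])
}

#' Automatically construct a low-uptake cortical background ROI
#'
#' Selects nonspecific brain voxels without any anatomical input:
#' brain voxels (value above `brain_fraction` of the volume maximum) are
#' eroded by `erode_mm` to discard partial-volume-contaminated edge
#' voxels, then the striatal mask dilated by `margin_mm` is excluded
#' (guarding against specific-signal spill-over), and finally
#' ventricle-dark voxels below `dark_fraction` of the brain median are
#' dropped.
#'
#' @param template a `volume3d` (counts or S/BG ratio) to threshold.
#' @param striatal_mask binary striatal mask (`volume3d` or array);
#'   nonempty.
#' @param margin_mm exclusion margin around the striatum, mm.
#' @param brain_fraction brain mask threshold as fraction of the max.
#' @param dark_fraction dark-voxel threshold as fraction of the brain
#'   median.
#' @param erode_mm edge erosion of the brain mask, mm.
#' @return A `background_roi` with definition `"auto_lowuptake"`.
#' @export
build_auto_background <- function(template, striatal_mask, margin_mm = 20,
                                  brain_fraction = 0.1, dark_fraction = 0.5,
                                  erode_mm = 8) {
  stopifnot(inherits(template, "volume3d"))
  grid <- template$grid
  sm <- as_mask_array(striatal_mask, grid)
  if (!any(sm)) stop("striatal mask is empty", call. = FALSE)
  dat <- template$data
  brain <- dat > brain_fraction * max(dat)
  if (!any(brain)) stop("brain mask is empty", call. = FALSE)
  core <- erode_mask(brain, grid, erode_mm)
  med <- stats::median(dat[brain])
  dark <- dat < dark_fraction * med
  excl <- dilate_mask(sm, grid, margin_mm)
  m <- core & !excl & !dark
  if (!any(m))
    stop("automatic background ROI is empty (margin or erosion exhausted ",
         "the brain)", call. = FALSE)
  background_roi(m, grid, "auto_lowuptake", exclusion_margin_mm = margin_mm)
}

#' Normalize a count volume to an S/BG ratio image
#'
#' Voxelwise division by the measured background level. The operation is
#' scale-invariant (scaling the input counts rescales the background
#' identically) and idempotent once the image is on the ratio scale.
#'
#' @param vol a `volume3d` (counts, or an S/BG image to renormalize).
#' @param background positive scalar, e.g. from [measure_background()].
#' @return A `volume3d` of kind `"sbg_ratio"`.
#' @export
normalize_sbg <- function(vol, background) {
  stopifnot(inherits(vol, "volume3d"))
  if (!is.numeric(background) || length(background) != 1 ||
      !is.finite(background) || background <= 0)
    stop("'background' must be a positive scalar", call. = FALSE)
  volume3d(vol$data / background, vol$grid, "sbg_ratio")
}

#' Average normalized subjects into a cohort template
#'
#' Voxelwise arithmetic mean of S/BG ratio images on a shared grid —
#' the cohort template from which uptake-based ROIs are extracted.
#'
#' @param subjects nonempty list of `volume3d` objects on one grid.
#' @return A `volume3d` of the same kind as the inputs.
#' @export
average_template <- function(subjects) {
  if (!is.list(subjects) || length(subjects) == 0)
    stop("'subjects' must be a nonempty list of volumes", call. = FALSE)
  stopifnot(all(vapply(subjects, inherits, TRUE, "volume3d")))
  grid <- subjects[[1]]$grid
  kind <- subjects[[1]]$kind
  for (s in subjects[-1]) {
    check_same_grid(grid, s$grid)
    if (s$kind != kind)
      stop("subjects mix value kinds (", kind, " vs ", s$kind, ")",
           call. = FALSE)
  }
  acc <- Reduce(`+`, lapply(subjects, `[[`, "data"))
  volume3d(acc / length(subjects), grid, kind)
}

#' Normalize one phantom subject by its automatically measured background
#'
#' Convenience wrapper chaining [build_auto_background()] (or
#' [cortex_background()]), [measure_background()] and [normalize_sbg()]
#' for a single subject, as each subject is normalized by its own
#' individually measured cortical background.
#'
#' @param vol counts `volume3d`.
#' @param striatal_mask striatal exclusion mask for the auto method.
#' @param method `"auto"` or `"cortex_label"`.
#' @param labels anatomy labels, required for `method = "cortex_label"`.
#' @param ... further arguments to [build_auto_background()].
#' @return A `volume3d` of kind `"sbg_ratio"`.
#' @export
normalize_subject <- function(vol, striatal_mask = NULL,
                              method = c("auto", "cortex_label"),
                              labels = NULL, ...) {
  method <- match.arg(method)
  bg <- if (method == "auto") {
    build_auto_background(vol, striatal_mask, ...)
  } else {
    cortex_background(labels)
  }
  normalize_sbg(vol, measure_background(vol, bg))
}
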