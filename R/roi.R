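# ROI template construction: cutoff thresholding of the S/BG template,
# mirror fusion, unilateral mirroring of drawn masks, and subdivision of
# the striatum into caudate / anterior putamen / posterior putamen.

REGIONS <- c("caudate", "ant_putamen", "post_putamen")
SIDES <- c("R", "L")

#' Extract the striatal region from an S/BG template by cutoff
#'
#' Thresholds the averaged S/BG ratio image at a striatal-to-background
#' cutoff (comparison is inclusive, `value >= cutoff`) and removes
#' 26-connected components smaller than `min_component_voxels` (speckle
#' from noise in the averaged template). If nothing survives, an empty
#' mask is returned with a warning.
#'
#' @param template_img a `volume3d` of kind `"sbg_ratio"`.
#' @param cutoff ratio cutoff, must exceed 1 (the background level).
#' @param min_component_voxels minimum connected-component size kept.
#' @return A `volume3d` label mask (0/1).
#' @export
extract_striatum <- function(template_img, cutoff, min_component_voxels = 10) {
  stopifnot(inherits(template_img, "volume3d"))
  if (template_img$kind != "sbg_ratio")
    stop("striatal extraction operates on S/BG ratio images; normalize first",
         call. = FALSE)
  if (cutoff <= 1)
    stop("'cutoff' must exceed 1 (the background ratio level)", call. = FALSE)
  m <- template_img$data >= cutoff
  if (any(m) && min_component_voxels > 1) {
    lab <- label_components_26(m)
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= min_component_voxels)
    m <- array(lab %in% keep, dim(m))
  }
  if (!any(m))
    warning("no voxels at or above cutoff ", cutoff,
            " survive component filtering; returning an empty mask",
            call. = FALSE)
  mask_volume(m, template_img$grid)
}

#' Symmetrize a mask by fusion with its mirror image
#'
#' Returns the union of the mask and its left-right flip, so the result
#' is exactly equal to its own mirror image. This is how an uptake-based
#' striatal ROI extracted from a (slightly asymmetric) cohort template
#' is forced to be bilaterally symmetric.
#'
#' @param mask a `volume3d` label mask or logical array plus `grid`.
#' @param grid required if `mask` is a plain array.
#' @return A `volume3d` label mask satisfying `flip_lr(out) == out`.
#' @export
symmetrize <- function(mask, grid = NULL) {
  if (inherits(mask, "volume3d")) grid <- mask$grid
  stopifnot(inherits(grid, "grid_spec"))
  check_x_symmetric(grid)
  m <- as_mask_array(mask, grid)
  mask_volume(m | flip_x_array(m), grid)
}

#' Mirror a unilateral (right-hemisphere) mask to both sides
#'
#' For externally drawn ROIs placed on the right hemisphere only: the
#' bilateral mask is the union of the mask and its mirror image. Voxels
#' at or across the midline (world x <= 0) are rejected, since the
#' drawing workflow presumes strictly unilateral input.
#'
#' @param right_mask a `volume3d` label mask or logical array.
#' @param grid required if `right_mask` is a plain array.
#' @return A `volume3d` label mask covering both hemispheres.
#' @export
mirror_from_right <- function(right_mask, grid = NULL) {
  if (inherits(right_mask, "volume3d")) grid <- right_mask$grid
  stopifnot(inherits(grid, "grid_spec"))
  check_x_symmetric(grid)
  m <- as_mask_array(right_mask, grid)
  if (any(m)) {
    wx <- coords_mm(grid, 1)[which(m, arr.ind = TRUE)[, 1]]
    if (any(wx <= 0))
      stop("right-hemisphere mask has voxels at or across the midline ",
           "(world x <= 0)", call. = FALSE)
  }
  mask_volume(m | flip_x_array(m), grid)
}

#' Specify the striatal subdivision geometry
#'
#' The caudate-putamen border is a plane through the internal-capsule
#' gap, given for the right hemisphere as a point and unit normal (the
#' normal points toward the caudate, i.e. medially/anteriorly); the left
#' hemisphere uses its exact mirror. `caudal_shift_mm` displaces the
#' effective border posteriorly, enlarging the caudate ROI toward the
#' caudal portion of the striatum where the apparent caudate peak sits
#' at SPECT resolution. The anterior/posterior putamen border is fixed
#' by rule: each axial slice is split at the midpoint of the putamen's
#' anteroposterior extent in that slice, ties going anterior.
#'
#' @param plane_point point on the right caudate-putamen plane, mm.
#' @param plane_normal plane normal (normalized internally), pointing
#'   toward the caudate side.
#' @param caudal_shift_mm posterior displacement of the caudate border,
#'   mm (>= 0). Default 4 mm.
#' @return An object of class `subdivision_spec`.
#' @export
subdivision_spec <- function(plane_point = c(18.2, 6, 2),
                             plane_normal = c(-1, 0.25, 0),
                             caudal_shift_mm = 4) {
  plane_point <- as.numeric(plane_point)
  plane_normal <- as.numeric(plane_normal)
  stopifnot(length(plane_point) == 3L, length(plane_normal) == 3L)
  nn <- sqrt(sum(plane_normal^2))
  if (nn == 0) stop("plane normal must be nonzero", call. = FALSE)
  if (caudal_shift_mm < 0)
    stop("'caudal_shift_mm' must be >= 0", call. = FALSE)
  structure(list(point = plane_point, normal = plane_normal / nn,
                 caudal_shift_mm = caudal_shift_mm),
            class = "subdivision_spec")
}

#' Bundle six region masks into an ROI template
#'
#' Validates the template invariants: the six masks (three regions x
#' two sides) are pairwise disjoint, and each right mask mirrors exactly
#' onto its left counterpart.
#'
#' @param masks named list `caudate`, `ant_putamen`, `post_putamen`,
#'   each a list with logical arrays `R` and `L`.
#' @param grid the shared [grid_spec()].
#' @param source `"fpcit_based"` (uptake-derived) or `"mri_based"`
#'   (anatomy-derived).
#' @param cutoff the extraction cutoff (uptake-based templates only).
#' @return An object of class `roi_template`.
#' @export
roi_template <- function(masks, grid,
                         source = c("fpcit_based", "mri_based"),
                         cutoff = NULL) {
  source <- match.arg(source)
  stopifnot(inherits(grid, "grid_spec"),
            setequal(names(masks), REGIONS))
  flat <- list()
  for (r in REGIONS) for (s in SIDES) {
    m <- masks[[r]][[s]]
    if (!is.logical(m) || !all(dim(m) == grid$shape))
      stop("mask ", r, "/", s, " is not a logical array on the grid",
           call. = FALSE)
    flat[[paste(r, s, sep = "_")]] <- m
  }
  tot <- Reduce(`+`, flat)
  if (any(tot > 1))
    stop("region masks overlap; the template must partition the striatum",
         call. = FALSE)
  for (r in REGIONS) {
    if (!identical(flip_x_array(masks[[r]]$R), masks[[r]]$L))
      stop("template is not left-right symmetric for region ", r,
           call. = FALSE)
  }
  structure(list(masks = masks, grid = grid, source = source,
                 cutoff = cutoff),
            class = "roi_template")
}

#' @export
print.roi_template <- function(x, ...) {
  cat(sprintf("roi_template (%s%s)\n", x$source,
              if (!is.null(x$cutoff)) sprintf(", cutoff %.2g", x$cutoff) else ""))
  print(roi_sizes(x))
  invisible(x)
}

# Parent striatal mask of a template (union of the six region masks).
template_parent_mask <- function(template) {
  Reduce(`|`, lapply(template$masks, function(rs) rs$R | rs$L))
}

#' Subdivide a symmetric striatal mask into three bilateral regions
#'
#' Per hemisphere, voxels on the caudate side of the (caudally shifted)
#' caudate-putamen plane form the caudate ROI; the remainder is the
#' putamen, which is split per axial slice at the midpoint of its
#' anteroposterior (world y) extent in that slice — voxels at or
#' anterior to the midpoint become anterior putamen, the rest posterior
#' putamen. Left-hemisphere voxels are classified through the mirrored
#' plane, so a symmetric input yields an exactly symmetric template.
#'
#' @param striatal_mask a symmetric bilateral striatal mask
#'   (`volume3d` or logical array with `grid`).
#' @param spec a [subdivision_spec()].
#' @param grid required if `striatal_mask` is a plain array.
#' @param source template provenance, `"fpcit_based"` or `"mri_based"`.
#' @param cutoff extraction cutoff to record (optional).
#' @return An [roi_template()].
#' @export
subdivide <- function(striatal_mask, spec = subdivision_spec(), grid = NULL,
                      source = c("fpcit_based", "mri_based"), cutoff = NULL) {
  source <- match.arg(source)
  stopifnot(inherits(spec, "subdivision_spec"))
  if (inherits(striatal_mask, "volume3d")) grid <- striatal_mask$grid
  stopifnot(inherits(grid, "grid_spec"))
  check_x_symmetric(grid)
  m <- as_mask_array(striatal_mask, grid)
  if (!any(m)) stop("striatal mask is empty", call. = FALSE)
  if (!identical(m, flip_x_array(m)))
    stop("striatal mask is not left-right symmetric; symmetrize() or ",
         "mirror_from_right() it first", call. = FALSE)

  vox <- which(m, arr.ind = TRUE)
  wx <- coords_mm(grid, 1)[vox[, 1]]
  wy <- coords_mm(grid, 2)[vox[, 2]]
  wz <- coords_mm(grid, 3)[vox[, 3]]
  if (any(wx == 0))
    stop("striatal mask touches the midsagittal plane; hemispheres are ",
         "not separable", call. = FALSE)

  # classify through the right-hemisphere plane using |x| (left voxels
  # are mirrored into the right half-space -> exact symmetry)
  p <- spec$point - c(0, spec$caudal_shift_mm, 0)
  nrm <- spec$normal
  d <- nrm[1] * (abs(wx) - p[1]) + nrm[2] * (wy - p[2]) + nrm[3] * (wz - p[3])
  is_cau <- d >= 0
  side <- ifelse(wx > 0, "R", "L")

  for (s in SIDES) {
    if (!any(is_cau & side == s))
      warning("caudate part is empty on side ", s, call. = FALSE)
    if (!any(!is_cau & side == s))
      warning("putamen part is empty on side ", s, call. = FALSE)
  }

  # anterior/posterior split of the putamen, per axial slice and side
  part <- character(nrow(vox))
  part[is_cau] <- "caudate"
  put <- which(!is_cau)
  if (length(put)) {
    key <- paste(side[put], vox[put, 3])
    for (k in unique(key)) {
      rows <- put[key == k]
      mid <- (min(wy[rows]) + max(wy[rows])) / 2
      part[rows] <- ifelse(wy[rows] >= mid - 1e-9, "ant_putamen",
                           "post_putamen")
    }
  }

  masks <- list()
  for (r in REGIONS) {
    masks[[r]] <- list()
    for (s in SIDES) {
      mm <- array(FALSE, grid$shape)
      rows <- which(part == r & side == s)
      if (length(rows)) mm[vox[rows, , drop = FALSE]] <- TRUE
      masks[[r]][[s]] <- mm
    }
  }
  roi_template(masks, grid, source = source, cutoff = cutoff)
}

#' Build an ROI template from a labelled anatomy volume
#'
#' Accepts an integer label volume coding right/left caudate, anterior
#' putamen and posterior putamen as 3/4/5 and 6/7/8 (the phantom
#' anatomy convention, also the package's interchange coding for
#' externally drawn templates).
#'
#' @param labels a `volume3d` of kind `"label"`.
#' @param source template provenance; anatomy-drawn templates are
#'   `"mri_based"`.
#' @return An [roi_template()].
#' @export
template_from_labels <- function(labels, source = "mri_based") {
  stopifnot(inherits(labels, "volume3d"), labels$kind == "label")
  codes <- list(caudate = c(R = 3L, L = 6L),
                ant_putamen = c(R = 4L, L = 7L),
                post_putamen = c(R = 5L, L = 8L))
  masks <- lapply(codes, function(cs)
    list(R = labels$data == cs["R"], L = labels$data == cs["L"]))
  roi_template(masks, labels$grid, source = source)
}

#' Convert an ROI template to a single label volume
#'
#' Region x side codes follow the interchange convention of
#' [template_from_labels()].
#'
#' @param template an [roi_template()].
#' @return A `volume3d` of kind `"label"`.
#' @export
template_to_labels <- function(template) {
  stopifnot(inherits(template, "roi_template"))
  lab <- array(0L, template$grid$shape)
  code <- c(caudate_R = 3L, ant_putamen_R = 4L, post_putamen_R = 5L,
            caudate_L = 6L, ant_putamen_L = 7L, post_putamen_L = 8L)
  for (r in REGIONS) for (s in SIDES)
    lab[template$masks[[r]][[s]]] <- code[paste(r, s, sep = "_")]
  volume3d(lab, template$grid, "label")
}

#' Tabulate ROI template voxel counts
#'
#' Voxel counts per region and side, with putamen and whole-striatum
#' totals. Additivity (totals equal the sum of their parts) is checked
#' internally.
#'
#' @param template an [roi_template()].
#' @return A data frame with columns `region`, `left`, `right`, `total`.
#' @export
roi_sizes <- function(template) {
  stopifnot(inherits(template, "roi_template"))
  cnt <- function(m) sum(m)
  rows <- lapply(REGIONS, function(r)
    data.frame(region = r, left = cnt(template$masks[[r]]$L),
               right = cnt(template$masks[[r]]$R)))
  out <- do.call(rbind, rows)
  out$total <- out$left + out$right
  put <- data.frame(region = "putamen",
                    left = sum(out$left[out$region != "caudate"]),
                    right = sum(out$right[out$region != "caudate"]),
                    total = sum(out$total[out$region != "caudate"]))
  str <- data.frame(region = "striatum", left = sum(out$left),
                    right = sum(out$right), total = sum(out$total))
  out <- rbind(out, put, str)
  parent <- sum(template_parent_mask(template))
  stopifnot(out$total[out$region == "striatum"] == parent,
            all(out$total == out$left + out$right))
  out
}

#' Sweep extraction cutoffs and tabulate striatal ROI sizes
#'
#' Runs [extract_striatum()] + [symmetrize()] at each cutoff and counts
#' mask voxels. Counts must be non-increasing in the cutoff; a violation
#' indicates an internal inconsistency and raises an error.
#'
#' @param template_img a `volume3d` of kind `"sbg_ratio"`.
#' @param cutoffs ascending numeric cutoffs, conventionally
#'   `c(3, 3.5, 4, 4.5, 5)`.
#' @param min_component_voxels passed to [extract_striatum()].
#' @return A data frame with columns `cutoff` and `voxels`.
#' @export
cutoff_sweep <- function(template_img, cutoffs = c(3, 3.5, 4, 4.5, 5),
                         min_component_voxels = 10) {
  if (is.unsorted(cutoffs, strictly = TRUE))
    stop("'cutoffs' must be sorted strictly ascending", call. = FALSE)
  voxels <- vapply(cutoffs, function(ct) {
    m <- symmetrize(extract_striatum(template_img, ct, min_component_voxels))
    sum(m$data)
  }, numeric(1))
  if (any(diff(voxels) > 0))
    stop("striatal ROI size increased with the cutoff; internal ",
         "consistency violated", call. = FALSE)
  data.frame(cutoff = cutoffs, voxels = voxels)
}

#' Extract, symmetrize and subdivide an uptake-based ROI template
#'
#' The full uptake-based workflow: threshold the averaged S/BG template
#' at `cutoff`, fuse with the mirror image, and subdivide into the three
#' bilateral regions.
#'
#' @param template_img averaged S/BG `volume3d`.
#' @param cutoff striatal-to-background cutoff (default 4.0, the level
#'   at which the extracted ROI best matches the averaged image).
#' @param min_component_voxels passed to [extract_striatum()].
#' @param spec a [subdivision_spec()].
#' @return An [roi_template()] with source `"fpcit_based"`.
#' @export
build_fpcit_template <- function(template_img, cutoff = 4,
                                 min_component_voxels = 10,
                                 spec = subdivision_spec()) {
  striatum <- symmetrize(extract_striatum(template_img, cutoff,
                                          min_component_voxels))
  subdivide(striatum, spec, source = "fpcit_based", cutoff = cutoff)
}
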