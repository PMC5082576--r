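# Binary-mask morphology on regular grids: 26-connected component
# labelling, and metric dilation/erosion by a Euclidean ball realized as
# an FFT convolution (exact for radii well below half the field of view,
# which holds for all intracranial structures on a whole-head grid).

# Label 26-connected components of a 3D logical mask.
# Returns an integer array, 0 outside the mask, components numbered from 1.
label_components_26 <- function(mask) {
  d <- dim(mask)
  n <- sum(mask)
  lab <- array(0L, d)
  if (n == 0L) return(lab)
  idx <- array(0L, d)
  idx[mask] <- seq_len(n)
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offsets <- offsets[offsets %*% c(1, 3, 9) > 0, , drop = FALSE]  # 13 forward
  edges <- vector("list", nrow(offsets))
  for (r in seq_len(nrow(offsets))) {
    o <- offsets[r, ]
    sel_a <- lapply(1:3, function(ax) {
      if (o[ax] >= 0) seq_len(d[ax] - o[ax]) else seq(1 - o[ax], d[ax])
    })
    sel_b <- lapply(1:3, function(ax) sel_a[[ax]] + o[ax])
    a <- idx[sel_a[[1]], sel_a[[2]], sel_a[[3]], drop = FALSE]
    b <- idx[sel_b[[1]], sel_b[[2]], sel_b[[3]], drop = FALSE]
    keep <- a > 0L & b > 0L
    if (any(keep)) edges[[r]] <- cbind(a[keep], b[keep])
  }
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (!is.null(edges) && nrow(edges))
    g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  lab[mask] <- as.integer(comp)
  lab
}

# Voxel offsets of a Euclidean ball of given radius, as a full-size FFT
# kernel centred (with wraparound) on the first voxel.
ball_kernel_fft <- function(dim3, voxel_mm, radius_mm) {
  r_vox <- pmin(floor(radius_mm / voxel_mm), (dim3 - 1L) %/% 2L)
  ox <- -r_vox[1]:r_vox[1]
  oy <- -r_vox[2]:r_vox[2]
  oz <- -r_vox[3]:r_vox[3]
  u <- outer(outer((ox * voxel_mm[1])^2, (oy * voxel_mm[2])^2, "+"),
             (oz * voxel_mm[3])^2, "+")
  ball <- u <= radius_mm^2 + 1e-9
  kern <- array(0, dim3)
  px <- (ox %% dim3[1]) + 1L
  py <- (oy %% dim3[2]) + 1L
  pz <- (oz %% dim3[3]) + 1L
  kern[px, py, pz] <- ball + 0
  kern
}

fft_convolve_binary <- function(mask, kern) {
  conv <- Re(stats::fft(stats::fft(mask + 0) * stats::fft(kern),
                        inverse = TRUE)) / length(mask)
  conv > 0.5
}

#' Dilate or erode a binary mask by a metric radius
#'
#' Morphological dilation (erosion) with a Euclidean ball structuring
#' element of the given radius in mm, evaluated on the voxel lattice.
#' Used to exclude a safety margin around the striatum when building
#' background ROIs, and to peel partial-volume-contaminated edge voxels
#' off a brain mask.
#'
#' @param mask a `volume3d` label volume or logical 3D array.
#' @param grid the [grid_spec()] (ignored if `mask` is a `volume3d`).
#' @param radius_mm ball radius in mm; 0 returns the mask unchanged.
#' @return A logical 3D array.
#' @export
dilate_mask <- function(mask, grid, radius_mm) {
  if (inherits(mask, "volume3d")) grid <- mask$grid
  m <- as_mask_array(mask, grid)
  if (radius_mm <= 0 || !any(m)) return(m)
  kern <- ball_kernel_fft(dim(m), grid$voxel_mm, radius_mm)
  fft_convolve_binary(m, kern)
}

#' @rdname dilate_mask
#' @export
erode_mask <- function(mask, grid, radius_mm) {
  if (inherits(mask, "volume3d")) grid <- mask$grid
  m <- as_mask_array(mask, grid)
  if (radius_mm <= 0 || !any(m)) return(m)
  !dilate_mask(!m, grid, radius_mm)
}

# Separable Gaussian blur in mm units with zero-padded boundaries.
# Kernel truncated at 4 sigma and renormalized to unit sum, so total
# counts are conserved exactly for interior sources.
gaussian_blur_array <- function(data, grid, fwhm_mm) {
  if (fwhm_mm < 0)
    stop("'fwhm_mm' must be non-negative", call. = FALSE)
  if (fwhm_mm == 0) return(data)
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  for (ax in 1:3) {
    sv <- sigma_mm / grid$voxel_mm[ax]
    r <- ceiling(4 * sv)
    k <- stats::dnorm(-r:r, sd = sv)
    k <- k / sum(k)
    perm <- c(ax, setdiff(1:3, ax))
    x <- aperm(data, perm)
    dx <- dim(x)
    n <- dx[1]
    K <- matrix(0, n, n)
    for (o in -r:r) {
      i <- max(1, 1 - o):min(n, n - o)
      K[cbind(i, i + o)] <- k[o + r + 1]
    }
    y <- K %*% matrix(x, n)
    dim(y) <- dx
    data <- aperm(y, order(perm))
  }
  data
}
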