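# Cutoff extraction, mirror fusion, subdivision geometry, size tables.

test_that("extraction thresholds inclusively and flags empty results", {
  g <- small_grid()
  flat <- volume3d(array(1, g$shape), g, "sbg_ratio")
  expect_warning(m <- extract_striatum(flat, 3), "empty mask")
  expect_equal(sum(m$data), 0)
  expect_error(extract_striatum(flat, 0.5), "cutoff")
  counts <- volume3d(array(1, g$shape), g, "counts")
  expect_error(extract_striatum(counts, 3), "ratio")
})

test_that("extraction on the noiseless unblurred phantom recovers the labels exactly", {
  cs <- control_subject()
  m <- extract_striatum(cs$sbg_unblurred, 4.0)
  expect_identical(m$data != 0, cs$striatum)
  # any cutoff strictly between background and striatal level works
  m2 <- extract_striatum(cs$sbg_unblurred, 2.0)
  expect_identical(m2$data != 0, cs$striatum)
})

test_that("component filtering removes speckle below the size threshold", {
  g <- default_grid()
  dat <- array(1, g$shape)
  dat[40:45, 40:45, 40:45] <- 6          # 216-voxel blob
  dat[10, 10, 10] <- 6                   # isolated speckle
  dat[80, 80, 80 ] <- 6
  vol <- volume3d(dat, g, "sbg_ratio")
  m <- extract_striatum(vol, 4, min_component_voxels = 10)
  expect_equal(sum(m$data), 216)
  m_all <- extract_striatum(vol, 4, min_component_voxels = 1)
  expect_equal(sum(m_all$data), 218)
})

test_that("threshold count equals the brute-force count before filtering", {
  cs <- control_subject()
  for (ct in c(3, 4, 5)) {
    m <- extract_striatum(cs$sbg, ct, min_component_voxels = 1)
    expect_equal(sum(m$data), sum(cs$sbg$data >= ct))
  }
})

test_that("symmetrize fuses a mask with its mirror and is a projection", {
  g <- grid_spec(c(13, 9, 7), c(2, 2, 2))
  set.seed(3)
  for (i in 1:20) {
    m <- random_mask(g, 0.15)
    out <- symmetrize(m, g)
    # brute-force oracle: union with the index-reversed copy
    expect_identical(out$data != 0, m | m[dim(m)[1]:1, , ])
    expect_identical(flip_lr(out)$data, out$data)
    expect_identical(symmetrize(out)$data, out$data)   # fixed point
  }
  # single off-midline voxel gains exactly its mirror twin
  one <- array(FALSE, g$shape)
  i <- which(abs(coords_mm(g, 1) - 12) < 1e-9)
  one[i, 4, 4] <- TRUE
  out <- symmetrize(one, g)
  hits <- which(out$data != 0, arr.ind = TRUE)
  expect_equal(nrow(hits), 2)
  expect_setequal(coords_mm(g, 1)[hits[, 1]], c(-12, 12))
})

test_that("mirror_from_right doubles a unilateral mask and rejects midline voxels", {
  g <- grid_spec(c(13, 9, 7), c(2, 2, 2))
  m <- array(FALSE, g$shape)
  right <- which(coords_mm(g, 1) > 0)
  m[right[1:3], 3:5, 3:5] <- TRUE
  out <- mirror_from_right(m, g)
  expect_equal(sum(out$data), 2 * sum(m))
  left_half <- out$data[coords_mm(g, 1) < 0, , ]
  expect_identical(left_half != 0, m[dim(m)[1]:1, , ][coords_mm(g, 1) < 0, , ])

  expect_equal(sum(mirror_from_right(array(FALSE, g$shape), g)$data), 0)

  mid <- array(FALSE, g$shape)
  mid[which(coords_mm(g, 1) == 0), 4, 4] <- TRUE
  expect_error(mirror_from_right(mid, g), "midline")
})

test_that("subdivision splits a rectangular toy putamen into equal halves", {
  g <- grid_spec(c(21, 21, 21), c(2, 2, 2))
  m <- array(FALSE, g$shape)
  xr <- which(coords_mm(g, 1) %in% c(4, 6, 8))
  yr <- which(coords_mm(g, 2) %in% seq(-8, 6, by = 2))   # 8 voxels deep
  zr <- which(coords_mm(g, 3) %in% seq(-8, 10, by = 2))  # 10 slices
  m[xr, yr, zr] <- TRUE
  m <- m | m[dim(m)[1]:1, , ]
  # plane far anterior-medial: everything is putamen
  sd0 <- subdivision_spec(plane_point = c(0, 100, 0),
                          plane_normal = c(-1, 1, 0), caudal_shift_mm = 0)
  w <- testthat::capture_warnings(tpl <- subdivide(m, sd0, g))
  expect_true(any(grepl("caudate part is empty", w)))
  sizes <- roi_sizes(tpl)
  expect_equal(sizes$total[sizes$region == "ant_putamen"],
               sizes$total[sizes$region == "post_putamen"])
  # per slice: even depth (8 voxels), midpoint between grid rows -> clean halves
  ant <- tpl$masks$ant_putamen$R; post <- tpl$masks$post_putamen$R
  for (k in zr)
    expect_equal(sum(ant[, , k]), sum(post[, , k]))
})

test_that("AP-midpoint ties go to the anterior putamen", {
  g <- grid_spec(c(13, 13, 5), c(2, 2, 2))
  m <- array(FALSE, g$shape)
  xr <- which(coords_mm(g, 1) %in% c(4, 6))
  yr <- which(coords_mm(g, 2) %in% c(-4, 0, 4))   # 3 voxels: midpoint on-grid
  m[xr, yr, 3] <- TRUE
  m <- m | m[dim(m)[1]:1, , ]
  sd0 <- subdivision_spec(plane_point = c(0, 100, 0),
                          plane_normal = c(-1, 1, 0), caudal_shift_mm = 0)
  suppressWarnings(tpl <- subdivide(m, sd0, g))
  expect_equal(sum(tpl$masks$ant_putamen$R), 4)   # y = 0 (tie) and y = 4
  expect_equal(sum(tpl$masks$post_putamen$R), 2)  # y = -4
})

test_that("a symmetric phantom putamen splits near-equally per slice", {
  # single ellipsoid centred at odd y: every slice has an even y-extent,
  # the midpoint falls between grid rows, halves are exact
  g <- default_grid()
  geom <- roikit:::ellipsoid_geom(c(26, -3, 2), c(5.5, 9, 7))
  m <- roikit:::ellipsoid_mask(g, geom)
  m <- m | m[dim(m)[1]:1, , ]
  sd0 <- subdivision_spec(plane_point = c(0, 100, 0),
                          plane_normal = c(-1, 1, 0), caudal_shift_mm = 0)
  suppressWarnings(tpl <- subdivide(m, sd0, g))
  ant <- tpl$masks$ant_putamen$R; post <- tpl$masks$post_putamen$R
  for (k in seq_len(g$shape[3])) {
    if (!any(ant[, , k]) && !any(post[, , k])) next
    expect_lte(abs(sum(ant[, , k]) - sum(post[, , k])), 1)
  }
})

test_that("subdivision with the true plane recovers the anatomy with Dice 1", {
  cs <- control_subject()
  striatum <- mask_volume(cs$striatum, cs$anatomy$grid)
  tpl <- subdivide(striatum, subdivision_spec(caudal_shift_mm = 0),
                   source = "mri_based")
  truth <- template_from_labels(cs$anatomy)
  for (r in c("caudate", "ant_putamen", "post_putamen")) {
    expect_identical(tpl$masks[[r]]$R, truth$masks[[r]]$R)
    expect_identical(tpl$masks[[r]]$L, truth$masks[[r]]$L)
  }
})

test_that("subdivide validates symmetry and emptiness", {
  g <- grid_spec(c(13, 9, 7), c(2, 2, 2))
  m <- array(FALSE, g$shape); m[9, 4, 4] <- TRUE   # asymmetric
  expect_error(subdivide(m, subdivision_spec(), g), "symmetric")
  expect_error(subdivide(array(FALSE, g$shape), subdivision_spec(), g),
               "empty")
})

test_that("roi_sizes adds up and the template is a partition", {
  cs <- control_subject()
  tpl <- build_fpcit_template(cs$sbg, cutoff = 4)
  sizes <- roi_sizes(tpl)
  tot <- function(r) sizes$total[sizes$region == r]
  expect_equal(tot("caudate") + tot("putamen"), tot("striatum"))
  expect_equal(tot("ant_putamen") + tot("post_putamen"), tot("putamen"))
  expect_equal(sizes$left + sizes$right, sizes$total)
  # partition of the parent striatal mask
  parent <- symmetrize(extract_striatum(cs$sbg, 4))
  all6 <- Reduce(`+`, unlist(lapply(tpl$masks, function(rs)
    list(rs$R, rs$L)), recursive = FALSE))
  expect_identical(all6 == 1, parent$data != 0)
  # left-right symmetry of the uptake-based template
  for (r in names(tpl$masks))
    expect_identical(flip_lr(mask_volume(tpl$masks[[r]]$R, tpl$grid))$data != 0,
                     tpl$masks[[r]]$L)
})

test_that("roi_template rejects overlaps and asymmetry", {
  g <- grid_spec(c(13, 9, 7), c(2, 2, 2))
  a <- array(FALSE, g$shape); a[9, 4, 4] <- TRUE
  aL <- a[dim(a)[1]:1, , ]
  empty <- array(FALSE, g$shape)
  masks_ok <- list(caudate = list(R = a, L = aL),
                   ant_putamen = list(R = empty, L = empty),
                   post_putamen = list(R = empty, L = empty))
  expect_s3_class(roi_template(masks_ok, g), "roi_template")
  masks_bad <- masks_ok
  masks_bad$ant_putamen <- list(R = a, L = aL)       # overlaps caudate
  expect_error(roi_template(masks_bad, g), "overlap")
  masks_asym <- masks_ok
  masks_asym$caudate$L <- empty
  expect_error(roi_template(masks_asym, g), "symmetric")
})

test_that("cutoff sweep is monotone and matches a step-function phantom", {
  cs <- control_subject()
  # constant-level striatum: counts constant across cutoffs below it, 0 above
  dat <- array(1, cs$sbg$grid$shape)
  dat[cs$striatum] <- 4.2
  vol <- volume3d(dat, cs$sbg$grid, "sbg_ratio")
  suppressWarnings(sw <- cutoff_sweep(vol, c(3, 4, 5)))
  N <- sum(cs$striatum)
  expect_equal(sw$voxels, c(N, N, 0))

  expect_error(cutoff_sweep(cs$sbg, c(4, 3)), "ascending")

  sw2 <- suppressWarnings(cutoff_sweep(cs$sbg, c(3, 3.5, 4, 4.5, 5)))
  expect_true(all(diff(sw2$voxels) < 0))   # strict on a blurred template
})

test_that("label round trip preserves an ROI template", {
  cs <- control_subject()
  tpl <- template_from_labels(cs$anatomy)
  lab <- template_to_labels(tpl)
  tpl2 <- template_from_labels(lab)
  for (r in names(tpl$masks)) {
    expect_identical(tpl$masks[[r]]$R, tpl2$masks[[r]]$R)
    expect_identical(tpl$masks[[r]]$L, tpl2$masks[[r]]$L)
  }
})
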