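# Shared fixtures, built in code. Heavyweight phantom objects are
# memoised per test file via this environment.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# Deterministic noiseless control subject on the default grid.
control_subject <- function() {
  fixture("control_subject", function() {
    spec <- phantom_spec()
    anat <- make_anatomy(spec)
    act <- assign_activity(anat, control_pattern(between_subject_cv = 0))
    scan <- simulate_scan(act, spec$fwhm_mm, "none")
    gt <- array(anat$data %in% 3:8, dim(anat$data))
    bg <- measure_background(scan, build_auto_background(scan, gt))
    list(spec = spec, anatomy = anat, activity = act, scan = scan,
         striatum = gt, background = bg,
         sbg = normalize_sbg(scan, bg),
         sbg_unblurred = normalize_sbg(act, 100))
  })
}

# Small grid for I/O and mask-geometry tests (x extent symmetric).
small_grid <- function() grid_spec(c(13L, 11L, 9L), c(2, 2, 2))

random_mask <- function(grid, p = 0.2) {
  array(stats::runif(prod(grid$shape)) < p, grid$shape)
}

expect_same_mask <- function(a, b) {
  a <- if (inherits(a, "volume3d")) a$data != 0 else a != 0
  b <- if (inherits(b, "volume3d")) b$data != 0 else b != 0
  expect_identical(a, b)
}
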