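---
title: "Striatal ROI templates for FP-CIT SPECT: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Striatal ROI templates for FP-CIT SPECT: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roikit)
```

## Overview

`roikit` quantifies striatal dopamine transporter binding on
anatomically normalized I-123 FP-CIT SPECT images through two families
of ROI templates — anatomy-based (drawn on MRI-like label volumes) and
uptake-based (extracted from an averaged normal-control image by a
striatal-to-background cutoff) — and validates both against a digital
striatal phantom with known ground truth. This vignette documents the
underlying models, every tunable parameter that matters, the numerical
choices, and the limits of what the phantom-based validation can show.

## Coordinate and data conventions

All volumes live on a shared axis-aligned RAS grid (x right, y
anterior, z superior; default 91 × 109 × 91 voxels at 2 mm, the common
normalized-space grid). The x extent is symmetric about the midline, so
mirroring about world x = 0 is an exact index flip and never
interpolates; any operation that needs mirroring checks this invariant
and refuses asymmetric grids. Grid mismatches between volumes are
always an error — nothing is silently resampled.

NIfTI-1 is the read/write format; the value kind (counts, S/BG ratio,
label) travels in the NIfTI `intent_name` field. Analyze 7.5 is
read-only and carries no orientation, so a fixed, documented assumption
is applied: Analyze files are treated as LAS and flipped to RAS on
read. A fixed dialect beats guessing per file; files whose true
orientation differs must be converted by the user.

## The S/BG model

Each subject's count image is divided by a scalar background — the mean
count in a cerebral-cortex ROI — giving a specific-to-background ratio
image with nonspecific tissue near 1. Two background definitions are
provided:

* `cortex_label`: the mean over a supplied cortex mask (in the phantom,
  the ground-truth nonspecific-tissue label).
* `auto_lowuptake`: an automatic recipe needing no anatomy. Brain
  voxels (above 10% of the volume maximum) are eroded by 8 mm to shed
  edge voxels contaminated by spill-out; the striatal mask dilated by a
  20 mm margin is excluded (guarding against spill-in of specific
  signal); voxels below 0.5 × the brain median (ventricle-dark) are
  dropped. All four parameters are arguments. The erosion step is
  essential at 9-mm resolution: without it, partial-volume edge voxels
  depress the measured background by 10–15%; with it the phantom's true
  level is recovered within 2%.

The background statistic is the mean, not the median, matching the
conventional S/BG definition. S/BG is the pure ratio S ÷ BG (cortex ≈
1, normal striatum ≈ 4–6 apparent), **not** (S − BG)/BG: extraction
cutoffs in the 3.0–5.0 range and all reported values are on the pure
ratio scale. Normalization is scale-invariant in the input counts and
idempotent on already-normalized images. Each subject is normalized by
its own individually measured background before cohort averaging.

## The phantom

The phantom is the package's test bed; its defaults are fixed study
conditions, not tuning knobs.

**Geometry.** Right-hemisphere structures are axis-aligned ellipsoids,
mirrored exactly to the left: caudate head (centre (12, 11, 8) mm,
semi-axes (5.5, 11, 9) mm, ≈ 2.3 cm³), anterior and posterior putamen
halves (centres (25, 6, 2) and (27, −10, 2), semi-axes (5.5, 8, 8),
together ≈ 3 cm³ per side), and the anterior horn of the lateral
ventricle (centre (6, 14, 10), semi-axes (3.5, 10, 9)) abutting the
caudate head anteromedially. The remaining brain — a sphere of radius
75 mm — is a single nonspecific compartment (the "cortex" label): a
striatum floating in zero-uptake tissue would be unphysiological, since
nonspecific FP-CIT uptake pervades the brain. Ellipsoids keep an
analytic volume oracle available and reproduce every geometric effect
the method depends on; the comma shape of the real caudate is not
modelled. A `ventricle_dilation` factor ≥ 1 scales the ventricle, which
is voxelized last and therefore carves into the adjacent caudate — the
atrophy configuration behind the caudal peak shift.

**Activity.** Cortex voxels carry `background_level` (default 100)
counts; each striatal region carries `background_level` × its S/BG
target × a per-subject, per-region-and-side multiplier drawn lognormal
with mean 1 and CV `between_subject_cv` (default 0.1; lognormal
guarantees positivity, and the generator draws per side so that
between-subject asymmetry exists whenever cv > 0). Ventricle and
extracerebral voxels are 0. Control targets are 8.0/8.0/8.0 — the
canonical striatum-to-background ratio of physical striatal phantom
studies; it is a *tissue-level* ratio, and 9-mm blur attenuates the
apparent template peak to ≈ 5.5–5.9, which is what lets a control
template support extraction at cutoffs up to 5.0, as real
normal-control templates do. Parkinsonian targets are 3.5/2.8/2.0,
declining rostrocaudally as required of the condition.

**Scanning.** The PSF is a stationary isotropic Gaussian with
σ = FWHM/(2√(2 ln 2)) per axis in mm (default FWHM 9.0 mm, a
high-resolution fan-beam system). The kernel is truncated at 4σ and
renormalized to unit sum, so total counts are conserved exactly for
interior sources; boundaries are zero-padded, and the brain is interior
to the field of view by construction. A real fan-beam PSF is spatially
variant, but the method's arguments depend only on finite resolution.
Optional Poisson resampling of the blurred counts models reconstructed
count statistics (noise is applied post-blur; projection-domain noise
and reconstruction are out of scope). Cohorts are reproducible under a
fixed seed.

**What the phantom does not emulate.** Anatomical normalization error
(no affine jitter), cortical folding, spatially variant resolution,
scatter and attenuation artefacts, and the caudate's comma shape.
Passing the phantom suite therefore demonstrates the correctness of the
*algorithms* under known conditions — not the clinical accuracy of any
particular cutoff or shift value on patient data.

## Uptake-based template construction

1. **Extraction**: voxels of the averaged S/BG template at or above the
   cutoff (inclusive comparison, which keeps constant-valued images
   well-defined). 26-connected components smaller than
   `min_component_voxels` (default 10) are removed as speckle; an empty
   result is returned with a warning rather than an error, so sweeps
   can pass through it.
2. **Symmetrization**: union of the mask with its mirror image; the
   output equals its own flip exactly. Striatal ROI size is
   non-increasing in the cutoff, and `cutoff_sweep()` enforces this as
   an internal consistency check.
3. **Subdivision**: per hemisphere, the caudate–putamen border is a
   plane through the internal-capsule gap (point (18.2, 6, 2), normal
   (−1, 0.25, 0)/‖·‖ for the right hemisphere; the left uses the exact
   mirror, implemented by classifying |x|, which makes symmetric inputs
   yield bitwise-symmetric templates). With zero caudal shift this
   plane separates the phantom's caudate and putamen ellipsoids exactly
   (margins ≈ 1.4 mm and 0.5 mm to the nearest surfaces), so
   subdividing the true striatal mask reproduces the ground-truth
   regions with Dice 1. `caudal_shift_mm` (default 4 mm) displaces the
   effective border posteriorly, enlarging the caudate ROI toward where
   blur and the dilated ventricle push the apparent caudate peak; the
   magnitude is a package choice — the caudal shift is qualitatively
   motivated but its size is not prescribed anywhere.
4. **Anterior/posterior putamen**: each axial slice of the putamen is
   split at the midpoint of its anteroposterior voxel extent in that
   slice; exact-midpoint ties go to the anterior putamen (a
   deterministic tie-break). On AP-symmetric shapes whose per-slice
   extents have even voxel counts the halves are exactly equal.

Anatomy-based templates enter as label volumes (codes 3–8) or as
unilateral right-hemisphere masks via `mirror_from_right()`, which
rejects masks touching the midline, and are subdivided by the same
machinery. Free-hand drawing itself is not automated.

## Quantification and statistics

Regional values are unweighted means over all mask voxels (no trimming
or thresholding inside the VOI), per side; the bilateral value is the
unweighted mean of the two side means, not a volume-weighted pooled
mean — sides are averaged after the per-side values exist. Empty
regions are reported as `NA` with a warning.

Region contrasts use the paired two-sided Wilcoxon signed-rank test.
With no zeros, no ties and n ≤ 25 the p-value comes from the exact null
distribution of the positive-rank sum; otherwise a normal approximation
with Pratt handling of zero differences (zeros ranked, then dropped
from the statistic and the null moments), tie correction, and a 0.5
continuity correction. An all-zero difference vector returns p = 1 with
a warning. No multiple-testing correction is applied — raw p-values are
reported, and users running many contrasts should adjust externally.
The test suite checks the exact path against full 2ⁿ sign enumeration
and against the reference implementation in `stats`, and calibrates the
test's size over 400 null cohorts.

`gradient_summary()` operationalizes the verbal notion of a
"rostrocaudal decline": decline if caudate > anterior putamen >
posterior putamen, each by more than a relative tolerance τ (default
0.05, a package choice), flat if all pairwise relative differences are
within τ, otherwise "other".

## Design choices in brief

* Mean background, pure-ratio S/BG, inclusive threshold, 26-connectivity,
  anterior tie-break: each fixed once and documented above.
* The distance (AP-midpoint) reading of the putamen split is
  implemented; a per-slice equal-area reading would differ on
  asymmetric shapes and was set aside.
* The automatic background recipe adds an edge-erosion step to the
  obvious threshold-minus-margin construction; without it the measured
  background is biased low at SPECT resolution (see above).
* Simulation sizes in the validation suite (16-subject control cohorts,
  14-subject Parkinsonian cohorts, 400-replicate null calibration)
  match the cohort sizes the method is designed around while keeping
  the full suite inexpensive.

## Known limitations

* The subdivision plane default is tuned to the phantom's geometry; for
  real templates the plane must be supplied by the user, mirroring the
  manual border-setting step of the original workflow.
* Analyze orientation is assumed, not detected.
* Oblique affines, resampling, 4D series and DICOM are out of scope.
* No partial-volume correction is applied anywhere: apparent S/BG
  values are resolution-dependent by design, and the uptake-based
  template mitigates — but does not remove — the tissue-mixture effect.
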