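# roikit

Striatal ROI templates and specific binding ratios for dopamine
transporter (I-123 FP-CIT, "DaTSCAN") SPECT.

## The problem

Quantifying striatal dopamine transporter binding from FP-CIT SPECT
requires regions of interest (ROIs) on anatomically normalized brain
images. The natural choice — ROIs drawn on MRI anatomy — turns out to
misread the caudate nucleus: at SPECT resolution (~9 mm FWHM) the
tissue-mixture (partial volume) effect of the adjacent anterior horn of
the lateral ventricle lowers the apparent caudate activity and shifts
its peak caudally, so an anatomically correct ROI samples the wrong
place. An alternative is to build the ROI template from the tracer
uptake itself: threshold an averaged normal-control image at a
striatal-to-background cutoff, force left-right symmetry by fusing the
mask with its mirror image, and subdivide the result into caudate,
anterior putamen and posterior putamen, deliberately shifting the
caudate ROI toward the caudal activity peak.

`roikit` implements both workflows end to end, plus a digital striatal
phantom that generates fully ground-truthed control and Parkinsonian
cohorts, so every stage can be validated without patient data.

## The quantity

All images are normalized to **S/BG ratio** (specific-to-background)
images:

    S/BG(v) = counts(v) / mean counts in the cerebral-cortex background ROI

so nonspecific tissue sits near 1 and normal striatum well above it.
Regional values are unweighted voxel means over each ROI, computed per
side and then averaged across hemispheres. Region differences are
tested with the paired two-sided Wilcoxon signed-rank test (exact null
distribution for small samples, Pratt zero handling otherwise).

## What is in the package

| module | functions |
| --- | --- |
| volumes & I/O | `volume3d`, `grid_spec`, `read_volume`, `write_volume` (NIfTI-1; Analyze 7.5 read-only), `flip_lr` |
| phantom | `phantom_spec`, `control_pattern`, `parkinsonian_pattern`, `make_anatomy`, `assign_activity`, `simulate_scan`, `make_cohort`, `peak_world_y` |
| normalization | `background_roi`, `cortex_background`, `build_auto_background`, `measure_background`, `normalize_sbg`, `normalize_subject`, `average_template` |
| ROI building | `extract_striatum`, `symmetrize`, `mirror_from_right`, `subdivision_spec`, `subdivide`, `build_fpcit_template`, `template_from_labels`, `roi_sizes`, `cutoff_sweep` |
| quantification | `apply_rois`, `quantify_cohort`, `cohort_table`, `region_contrast`, `signed_rank_test`, `gradient_summary` |

A thin command-line front end over these functions is installed at
`system.file("cli/roikit", package = "roikit")` with subcommands
`phantom`, `normalize`, `template`, `extract`, `subdivide`, `sweep`,
`quantify` and `contrast`.

## Worked example

Build a 16-subject normal-control phantom cohort, normalize each
subject by its automatically measured cortical background, average the
cohort into a template, and sweep the extraction cutoffs:

```r
library(roikit)

spec <- phantom_spec()                      # 2-mm grid, 9-mm PSF
cohort <- make_cohort(spec, control_pattern(), n = 16, seed = 1)

striatum_gt <- array(cohort$anatomy$data %in% 3:8, dim(cohort$anatomy$data))
subjects <- lapply(cohort$subjects, function(s)
  normalize_subject(s, striatum_gt, method = "auto"))

template <- average_template(subjects)
cutoff_sweep(template, c(3, 3.5, 4, 4.5, 5))
#>   cutoff voxels
#> 1    3.0   1592
#> 2    3.5   1092
#> 3    4.0    704
#> 4    4.5    394
#> 5    5.0    156
```

The striatal ROI shrinks monotonically as the cutoff rises. Extract at
cutoff 4.0, subdivide, and quantify the cohort through the uptake-based
template:

```r
tpl <- build_fpcit_template(template, cutoff = 4)
tpl
#> roi_template (fpcit_based, cutoff 4)
#>         region left right total
#> 1      caudate  152   152   304
#> 2  ant_putamen  111   111   222
#> 3 post_putamen   89    89   178
#> 4      putamen  200   200   400
#> 5     striatum  352   352   704

tab <- cohort_table(quantify_cohort(subjects, tpl))
summary(tab)
#>         region     mean        sd  n
#> 2      caudate 4.587131 0.3129493 16
#> 1  ant_putamen 4.558700 0.2404871 16
#> 3 post_putamen 4.466646 0.3115861 16

region_contrast(tab, "caudate", "ant_putamen")
#> Wilcoxon signed-rank (exact): caudate vs ant_putamen, n = 16, V = 69, p = 0.9799
```

Through uptake-based ROIs the three regional means of a control cohort
are statistically indistinguishable (the true regional ratios are equal
by construction; blur attenuates them from 8.0 to ~4.5). Repeating the
readout through anatomy-based ROIs on a cohort with dilated ventricles
drops the caudate mean by ~0.9 S/BG units while putamen values barely
move — the tissue-mixture effect the uptake-based template is designed
to escape. See the vignette (`vignettes/striatal-roi-templates.Rmd`)
for the model, parameter and design details.

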