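---
title: "Quantifying vocal fold abduction and adduction from axial cine-MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying vocal fold abduction and adduction from axial cine-MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

The vocal folds abduct (open) for breathing and adduct (close) for voicing.
In unilateral vocal fold paralysis (UVFP) one fold is immobile, typically
resting near the midline (paramedian), so the glottal aperture becomes
asymmetric and its change between tasks is reduced. Laryngoscopy shows this
qualitatively, but objective quantification from the endoscopic view is
hampered by projection distortion. Axial cine-MRI — rapid repeated
acquisition of a slice through the glottis at roughly 0.7–0.8 s per frame —
captures the slow abduction/adduction cycle (not phonatory vibration, which
is orders of magnitude faster) and supports area measurement in true
physical units.

`glottocine` implements the measurement chain for such series and the
metrics built on it:

* per frame, the glottal airway is split into **left and right hemi-glottal
  areas** (mm²) and **hemi-glottal angles** (degrees) about the line through
  the anterior commissure (AC) and posterior commissure (PC);
* per task period (10 s of sustained /hee/ phonation or quiet nasal
  respiration, 10 frames each), hemi-quantities are averaged;
* per subject, with $R = \mathrm{left}/\mathrm{right}$ on period means:
  * $\mathrm{VFPa} = |1 - R_{\mathrm{phonation}}|$ — phonation asymmetry,
  * $\mathrm{VFRa} = |1 - R_{\mathrm{respiration}}|$ — respiration asymmetry,
  * $\mathrm{VFAP} = 100\,(A_{\mathrm{resp}} - A_{\mathrm{phon}})/A_{\mathrm{resp}}$ —
    abduction potential, the percent drop in total glottal area from
    respiration to phonation;
  * starred variants (\*VFPa, \*VFRa, \*VFAP) substitute hemi-angles for
    hemi-areas.

Healthy folds move symmetrically, so asymmetries should be near 0 and VFAP
near 100 % (complete closure). An immobile fold leaves its hemi-area
unchanged across tasks: with symmetric respiration and full closure of the
healthy fold, VFAP is exactly 50 %. These two analytic ideals anchor the
end-to-end tests of the package.

## Frame geometry

Raster geometry uses 0-based pixel-center coordinates (x = column,
y = row), with physical spacing in mm/pixel (default 1.5 × 1.5 mm). The
bisecting line runs through AC and PC, oriented AC→PC, and provides a
signed distance in mm. **Laterality** must be made explicit because display
convention is not recoverable from an image array: by default positive
signed distance is subject-left, which maps image-right to subject-left
(radiological display); `left_positive = FALSE` flips it. Swapping sides
maps $R \to 1/R$, and $|1-R| \ne |1-1/R|$ in general, so the asymmetry
metrics are *not* invariant under relabeling — the convention is part of
the measurement definition.

**Hemi-areas** are pixel counts times pixel area, with each pixel assigned
by the sign of the signed distance of its center. Pixels whose centers fall
exactly on the line contribute half their area to each side; this makes
left + right equal the total mask area identically and preserves mirror
symmetry, both enforced by property tests over random masks.

**Hemi-angles** idealize each fold's medial edge as a line through AC. Per
axial position along the AC→PC axis, the laterally outermost airway pixel
is taken as an edge point; a least-squares line constrained through AC is
fitted and the acute angle to the bisecting line reported. Edge-pixel
centers sit up to one lateral pixel inside the true edge, so half the
lateral pixel quantum is added to each edge distance before fitting — this
removes a systematic underestimate of about 2.5° at 1.5 mm spacing and
brings recovery of constructed fold angles within 0.2° on clean rasters.

**Segmentation** stands in for the manual regions of interest of a human
reader: a global Otsu threshold (airway polarity configurable, dark by
default) followed by 4-connected region growth from a seed on the AC–PC
axis, restricted to a neighbourhood of the commissures. Binary input passes
through untouched. The procedure is deterministic; on noise-free rendered
frames it reproduces the rasterized polygon exactly, and at a
contrast-to-noise ratio of 20 its Dice overlap with ground truth exceeds
0.95.

**Degenerate inputs.** An *empty binary mask* is treated as a true
observation of a fully adducted glottis: hemi-areas are valid zeros while
hemi-angles are flagged invalid. A *failed segmentation* (seed not
airway-like) invalidates all four quantities for that frame. Period means
are taken per quantity over the frames where that quantity is valid; a
period with no valid area frames raises an error. This distinction matters:
complete closure during healthy phonation is physiology, not measurement
failure, and must flow through to VFAP = 100 %.

**Near-zero denominators.** $R$ and VFAP guard their denominators with an
epsilon (one pixel area, 2.25 mm², for areas; 0.5° for angles) and return
`NA` rather than raising: healthy phonation can close the glottis
completely, leaving VFPa genuinely undefined. `NA` metrics propagate into
the statistics via listwise deletion, with a message recording the count.
A negative VFAP (phonation larger than respiration) is reported as-is with
a warning rather than clipped.

## Statistics

Group comparison uses the unpaired t-test, in both a raw-data form and a
summary-statistics form (means, SDs, n), so the published group summaries
can be re-analysed directly. The pooled-variance variant is the default:
recomputing from the printed study-1 summaries reproduces the published
p-values under pooling (VFRa p ≈ 0.0013 against printed 0.001; VFAP
p ≈ 0.0085 against printed 0.008), whereas Welch does not. For the
phonation asymmetry comparison neither variant reproduces the printed
0.012 exactly (pooled ≈ 0.019, Welch ≈ 0.006, both significant at 0.05);
with only rounded summaries available this cannot be resolved further, and
the package documents rather than hides it.

Repeatability uses single-measure intraclass correlation coefficients
computed from the two-way ANOVA mean squares, with the form selectable:
ICC(2,1) (two-way random, absolute agreement — the default, standard for
test–retest and inter-reader designs), ICC(3,1) (consistency) and ICC(1,1)
(one-way). 95 % confidence intervals use the standard F-based formulas.
Estimates are verified in the test suite against an independent
`stats::aov` decomposition to 1e-10. Interpretation bands follow the
convention: almost perfect 0.81–1.00, substantial 0.61–0.80, moderate
0.40–0.60; the published bands leave 0.60–0.61 and 0.80–0.81 unassigned,
so estimates are rounded to two decimals first and the intervals treated
as contiguous, which reproduces the printed labels for all tabulated
values. Zero between-subject variance leaves the ICC undefined (`NA`).

## The synthetic cine generator

No raw MRI from the study is available, so the generator is the package's
test bed: it emulates the *mechanisms* of the study design with
closed-form ground truth, and every pipeline stage is validated against
that ground truth.

The glottis is idealized as a triangle with apex at AC: each fold's medial
edge makes a task-dependent half-angle $\theta$ with the AC→PC axis, giving
hemi-areas $\tfrac12 L^2 \tan\theta$ for anterior–posterior length $L$.
Frames are rasterized at pixel centers into a 240 × 180 mm field of view at
1.5 × 1.5 mm (160 × 120 pixels), with the axis placed midway between pixel
columns so that no pixel center lies exactly on an edge shared between
tasks — an immobile fold's rasterized hemi-area is then bit-identical
across tasks, keeping the 50 % ideal exact at raster level. Intensity mode
renders two levels (airway dark) plus seeded Gaussian noise.

Default study conditions (chosen once, as a plausible emulation of adult
laryngeal kinematics, and used by all cohort-level tests):

| parameter | default | rationale |
|---|---|---|
| AP glottal length | 20 mm | adult membranous + cartilaginous glottis |
| healthy respiration half-angle | N(25°, 4°) per subject, symmetric | comfortable quiet-breathing abduction |
| healthy phonation half-angle | 1° residual | keeps $R$ defined, mirroring finite healthy phonation asymmetry in vivo |
| UVFP paralysed fold | fixed N(14°, 3°), left side | paramedian posture, task-independent |
| UVFP healthy-side phonation | N(5°, 2°), ≥ 1° | incomplete compensation toward the midline |
| frame timing | 0.764 s per frame, 10 frames per 10-s task | protocol temporal resolution |
| within-task jitter | 1.5° SD per fold per frame | breath-to-breath and hold instability |
| session elevation shift | 1 mm SD per side per session | slice repositioning and larynx elevation |
| elevation gain | 1°/mm phonation, 0.15°/mm respiration | the larynx elevates during phonation, so phonation geometry is far more sensitive to slice position |
| reader-2 noise | 2 mm² / 1° SD per frame | independent ROI redrawing |

Studies 1 and 2 share one session's elevation offsets; study 3 draws fresh
ones. This is the designed mechanism by which inter-session repeatability
of the *phonation* metrics degrades while respiration metrics stay robust
— the pattern the study observed and attributed to axial slice
positioning. The test suite verifies the mechanism causally: median
inter-session ICC of VFPa falls monotonically (about 0.95 → 0.1) as the
elevation-shift SD grows from 0 to 4 mm, while inter-reader ICC tends to 1
as reader noise vanishes.

All randomness derives from one master seed through a documented
per-subject/per-study hash (`derive_seed()`), so any dataset is
bit-reproducible; regeneration with the same seed is `identical()`.

These defaults reproduce the *qualitative* published pattern — UVFP
cohorts show higher VFPa/VFRa, lower VFAP (≈53 % vs ≈95 %), the
angle-based \*VFPa comparison loses significance, and inter-session VFPa
is the fragile repeatability — but no attempt is made to match the printed
cohort means, whose generating distributions the text does not determine.

### What the generator does not emulate

No MRI physics (k-space, motion blur, coil sensitivity, intensity
inhomogeneity), no arytenoid or supraglottic anatomy, no curved glottal
axis, no vibration. Passing tests therefore demonstrate correctness of the
measurement chain and the *designed* statistical mechanisms, not
performance on clinical images; the manual-ROI stand-in segmentation, in
particular, is validated only on two-level synthetic frames.

## Numerical choices and limitations

* Raster accuracy: pixel-center counting carries an error bounded by
  roughly one pixel row along the fold (≈ 30 mm² at 1.5 mm for a 20 mm
  fold, usually much less); it vanishes as spacing shrinks, and the
  convergence (1.5 → 0.75 → 0.375 mm, monotone nonincreasing error against
  the closed form) is asserted in the tests.
* Sub-pixel apertures: a fold angle whose lateral extent is below one
  pixel (≈ 2° at 1.5 mm for L = 20 mm) may contain no pixel centers on its
  side; the angle is then flagged invalid rather than guessed. Angle
  recovery to ±1.5° is guaranteed only above this regime (or at finer
  spacing).
* Rigid motions that preserve the pixel grid (90° rotations,
  integer-pixel translations) leave measurements exactly invariant;
  arbitrary rotations perturb hemi-areas by a few pixel areas at coarse
  spacing (tested ≤ 2.5 mm², about 3 %, at 0.375 mm) and angles by < 1.5°.
* Mean-then-ratio: metrics are computed from period-*mean* hemi-areas. A
  per-frame ratio-then-mean alternative (`framewise_asymmetry()`) is
  provided for sensitivity analysis but is off by default; the two agree
  when frames are identical.
* The asymmetry convention is the magnitude $|1-R|$. The published
  patient means (up to 1.28) are only consistent with a non-negative
  convention, and with left-sided paralysis phonation gives $R > 1$;
  whether the original computation used $|1-R|$, $R-1$ or
  $\max(R, 1/R)-1$ is not recoverable from the text.
* Problem sizes in the shipped tests (cohorts of 14–20 subjects, 100
  seeded replicates for separation, 50 for repeatability medians, 1000
  random masks for conservation) were chosen to make the property checks
  statistically meaningful while keeping a full suite run to a few
  minutes.

## A worked example

```{r, eval = FALSE}
library(glottocine)

dataset <- simulate_cohort(cohort_config(), master_seed = 17)
metrics <- metrics_from_measurements(dataset$measurements)
metrics <- merge(metrics, dataset$subjects[, c("subject", "cohort")])

compare_groups(metrics, dataset$subjects)[, c("metric", "healthy", "uvfp", "p")]
repeatability_icc(metrics, form = "ICC2")
```

The `analysis/` scripts in the repository run this workflow end to end
(simulation, the file-based image path, metrics, group comparison,
repeatability) and write their tables under `results/`.
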