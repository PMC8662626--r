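---
title: "Box-counting fractal dimension of segmented brain regions"
author: "voxelFD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Box-counting fractal dimension of segmented brain regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxelFD)
```

## The estimator

A compact summary of a 3D structure's space-filling complexity is its
Minkowski--Bouligand (box-counting) dimension

$$D_{box}(S) = \lim_{\epsilon \to 0}\frac{\log N(\epsilon)}{\log (1/\epsilon)},$$

where the scaling factor $\epsilon = 1/s$ is the reciprocal of the box edge
length $s$ and $N(\epsilon)$ is the number of grid cells of edge $s$ that
intersect the structure. For a segmented brain region -- a binary voxel mask
cut out of an integer label volume -- the estimate is obtained by counting
occupied cells at a fixed series of edge lengths and fitting

$$\log_{10} N_k = b - D \,\log_{10} s_k$$

by ordinary least squares; the dimension estimate is $-\hat{\beta}$ (the log
base cancels in the slope, so base 10 is a presentation choice). A solid
region approaches 3, a sheet-like one 2; reported whole-brain values sit
near 2.95, and deep gray structures in the 2.3--2.6 range.

Alongside the slope, the fit's root-mean-square residual (in $\log_{10} N$
units) is kept as a *linearity diagnostic*. A single dimension only
summarises the structure if the log--log relation is close to a line; when
the RMSE exceeds a threshold (default 0.05, configurable), the result is
flagged `multifractal_suspect`. The flag is report-only -- the package never
aborts on it, and it performs no multifractal spectrum analysis.

## The scale schedule

The default schedule has twenty edge lengths spaced evenly in $\log_{10}$:
$s_k = 10^{0.01 + 0.0495k}$, $k = 0,\dots,19$, i.e. from about 1.02 to about
8.92 voxels with a constant ratio $10^{0.0495}$. Twenty points balance the
stability of the fit against counting cost; in our experience fewer points
noticeably perturb the estimate while more change little but cost time. Both
endpoints and the point count are arguments of `scaleSchedule()`, and an
explicit vector of edges is also accepted.

Edges are expressed in voxel units and all must exceed one voxel: at
$s \le 1$ every occupied voxel is its own box, $N$ pins to the voxel count,
and the fit degenerates -- such edges are rejected rather than clamped.
Physical voxel spacing never enters the fit (the dimension is
dimensionless); anisotropic spacing draws a warning because the voxel grid
then distorts physical shape.

## Counting rule and its numerical behaviour

`countBoxes()` uses the plain single-lattice rule: the grid is anchored at
the array index origin and voxel $(i,j,k)$ (zero-based) belongs to cell
$(\lfloor i/s\rfloor, \lfloor j/s\rfloor, \lfloor k/s\rfloor)$. Non-integer
edges are supported directly; there is no offset averaging and no
overlapping lattice. This rule is deliberately simple and exactly
reproducible, and every property below is tested against a brute-force
set-enumeration oracle.

Three behaviours of this rule are worth knowing, all of them quantified in
the test suite:

* **Monotonicity is typical, not guaranteed.** For well-filled masks
  $N(s)$ falls as $s$ grows, but a structure with internal holes can
  straddle *more* cell boundaries at a coarser, misaligned grid. The
  level-3 Menger sponge is a concrete counterexample under the default
  schedule; sparse random masks violate monotonicity regularly. The
  `BoxCountSeries` container therefore does not enforce it.
* **Translation sensitivity is bounded but real.** Shifting a mask by one
  voxel changes each $N(s)$ by at most one occupied cell layer per axis.
  On a filled 64-cube the fitted dimension moves from 2.939 to 2.862 under
  a one-voxel diagonal shift. Masks extracted from a volume keep that
  volume's coordinates, so estimates are comparable across sessions only
  when the segmentations live on a common grid -- which is exactly the
  conformed, cropped grid the upstream segmentation produces.
* **Misaligned scales overcount holey structures.** On a level-4 Menger
  sponge ($81^3$, $20^4$ solid voxels, similarity dimension
  $\log 20/\log 3 \approx 2.7268$) the counts are *exact* at the
  construction-aligned edges ($N(3) = 20^3$, $N(9) = 20^2$, and a
  $\{3, 9, 27\}$ schedule recovers 2.7268 to machine precision), but every
  other edge length catches boxes that straddle the sponge's base-3 holes.
  Under the default schedule the fit flattens to $\approx 2.55$ and the
  RMSE (0.073) itself flags the curvature. This is an inherent property of
  single-lattice box counting at scales incommensurate with a fractal's
  construction, not a defect of the implementation; the filled cube's mild
  low bias (2.94 rather than 3 at size 64) is the same finite-size
  staircase effect at the opposite extreme.

Degenerate inputs are errors with explicit messages: empty masks
(empty-ROI), edges $\le 1$, series with fewer than two distinct scales, and
non-positive counts. A zero-variance response (constant counts) fits slope
0 with $R^2$ defined as 0.

## Phantoms: what the synthetic data does and does not show

`makePhantom()` builds masks with analytically known dimension: filled cube
(3), one-voxel slab (2), one-voxel line (1), Menger sponge
($\log 20/\log 3$), and a seeded `random_blob` (thresholded smoothed noise,
no analytic dimension) used for oracle-equivalence checks. The level-4
sponge ($81^3$) is the largest default fixture -- large enough for a stable
fit, small enough that the whole suite runs in seconds; Euclidean phantoms
default to size 64. `embedPhantom()` places a phantom, centered, into a
background volume under a chosen label so that the full
write--read--extract--estimate pipeline can be exercised without any MRI
data.

Passing these tests shows that the counting engine, the fit, and the region
plumbing are correct on structures of known dimension. It does not show
that the pipeline reproduces published values on real cohorts: those depend
on the scanner data, the preprocessing, and the trained segmentation model,
none of which the phantoms emulate (no partial-volume effects, no noise, no
anatomy). Published per-region values serve here only as plausibility
bands.

## Session tables, repeat-scan variation

`measureSession()` reports, per region and for the whole segmented volume,
the voxel count, physical volume (count times voxel volume) and the FD fit.
`compareSessions()` pivots several sessions of one subject into a wide
table and summarises per-region stability as the relative variation
$(\max - \min)/\text{mean} \times 100\%$ -- the statistic is configurable
since published reports quote repeat-scan variation without defining the
formula.

## CDR labeling and the cross-sectional cohort

MRI sessions and Clinical Dementia Rating assessments happen on different
days, so sessions are labeled by windowing rules, in order: (1) a session
lying between two equal-score CDR visits takes that score regardless of
distance; (2) between two different scores, the nearer visit's score is
taken only if it is within the window (default 45 days), with equidistant
ties dropped; (3) with visits on one side only, the nearest is used within
the same window; otherwise the session is dropped with a recorded reason.
Labeling is monotone in the window: enlarging it never un-labels a session.

`buildCohort()` keeps one session per subject (earliest by default; the
choice of which single session to keep is genuinely open, and earliest
maximises follow-up consistency) and applies the class policy: control at
CDR 0, dementia at CDR $\ge$ 1 by default. CDR 0.5 (questionable dementia)
then belongs to neither class and is excluded with a message; the threshold
is an explicit argument because reasonable analyses differ on where to put
those subjects.

## Classification

`crossvalClassify()` trains a support vector machine on per-subject
(volume, FD) features under stratified k-fold cross-validation with a fixed
seed, pooling test-fold predictions for the report. Defaults: RBF kernel
with $C = 100$, $\gamma = 6$, five folds. A polynomial kernel is available
through the `kernel` argument -- sources describing this configuration
disagree between RBF and polynomial, so both are offered with RBF as the
default. Features are standardized *inside* each fold (fit on the training
split only): volumes in mm^3 and dimensionless FD differ by orders of
magnitude and an unscaled kernel would effectively see only volume.

Dementia is the positive class throughout, and the headline metric is
$F_\beta$ with $\beta = 8.25$,
$F_\beta = (1+\beta^2)PR/(\beta^2 P + R)$, which weights recall heavily: in
a screening setting a missed dementia case costs more than a false alarm,
and with a control class roughly 8 times the dementia class, plain accuracy
is dominated by controls. On synthetic features mimicking the reported
qualitative structure (FD shifted by one standard deviation between
classes, volume essentially unshifted) an FD-only classifier beats a
volume-only one in $F_\beta$ -- the form of the published claim that is
testable without the original cohort.

## Problem sizes and reproducibility

The test suite and the acceptance script are fully self-contained: all
inputs are generated in code (phantoms up to $81^3$, random masks up to
$24^3$, synthetic feature sets of $n = 200$, registries of tens of
subjects), with every random draw behind an explicit seed, and run in well
under a minute on one CPU. `scripts/acceptance.R` regenerates the default
schedule and writes its reference edge lengths as JSON.

## Known limitations

* Single-lattice counting at scales incommensurate with a structure's
  construction biases fractal estimates low (quantified above); results at
  matched schedules remain comparable across sessions and subjects, which
  is the intended use.
* `.mgz` volumes are not parsed natively; convert to NIfTI first.
* The `.npz` dialect is a single array (key `vol`), 1 mm isotropic by
  convention, since that dump format carries no spatial header.
* No multifractal analysis, no 2D slice-wise dimension, no lacunarity, no
  surface-based morphometry.
* Whole-brain masks are the union of all positive labels; whether
  background-adjacent structures should be excluded is left to the label
  selection.
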