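---
title: "Evaluating AI-assisted contouring: models, metrics and design choices"
author: "AutoContourQA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating AI-assisted contouring: models, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AutoContourQA)
```

## The problem

In a contemporary radiotherapy workflow, a deep-learning tool drafts the
organ-at-risk and target contours on the planning CT; a radiation
oncologist reviews and edits them; the edited structure set drives plan
optimization. Three structure sets therefore coexist for one patient:
the conventional manual set, the raw AI set, and the AI-adjusted set
(possibly one per reviewing physician). Whether the assisted workflow is
clinically equivalent to the manual one is settled by comparing these
sets geometrically, propagating the differences into dose statistics on
re-optimized plans, condensing plan quality into one normalized score,
and measuring what the assistance costs and saves: reviewer time and
interobserver spread. AutoContourQA implements that entire evaluation
chain on explicit voxel containers, with a synthetic cohort generator in
place of patient data.

## Geometry substrate

Masks and dose live on a shared `VoxelGrid`: origin and spacing in mm,
axial slices stacked along the third axis, voxel centers at
`origin + index * spacing` (0-based), and an explicit flag naming the
in-plane posterior direction so anatomical margins can be resolved to
grid axes. Volumes are voxel counts times the voxel volume.

*Rasterization.* RT-STRUCT-style planar polygons become masks by the
even-odd rule at voxel centers: a voxel is set iff its center falls
inside an odd number of the slice's polygons, so holes carried as
separate polygons are honoured. Contour planes are matched to grid
slices within half a slice thickness; anything further away is a
coordinate error, not something to silently snap. The even-odd test is
deliberately minimal and deterministic; the test suite cross-checks it
against an independent point-in-polygon implementation (`mgcv::in.out`)
on irregular polygons.

*Margins.* The planning target volume is the clinical target volume
grown by a safety margin — here 5 mm in every direction except 3 mm
posterior, the classic prostate recipe that spares the rectum. The
expansion kernel is an ellipsoidal Euclidean reach split per half-axis:
each anatomical direction contributes its own radius, so the posterior
half-axis can be shorter than the anterior one. This matches how
treatment planning systems implement anisotropic margins; since only the
margins themselves are ever specified clinically, the kernel shape is a
design choice and is recorded here.

*Surfaces.* A surface voxel is a set voxel with at least one 6-connected
unset or out-of-grid neighbour. Distances between surfaces are computed
with an exact anisotropic 3D Euclidean distance transform
(Felzenszwalb–Huttenlocher, compiled): seeded at one mask's surface
voxels, read off at the other's, which reproduces the brute-force
all-pairs computation exactly while staying linear in the grid size.

## Comparison metrics

For masks $A$ (reference) and $B$ (test) on one grid:

- $\mathrm{DSC} = 2|A \cap B|/(|A|+|B|) \in [0,1]$ — volumetric overlap;
- $\mathrm{HD} = \max\{h(A,B), h(B,A)\}$, with directed
  $h(A,B) = \max_{a\in\partial A}\min_{b\in\partial B}\lVert a-b\rVert$
  in mm between surface voxel centers. The 100th-percentile (classic)
  Hausdorff is the default; no percentile variant is applied;
- $\mathrm{RVD} = (V_B - V_A)/V_A$, computed signed. Cohort tables
  summarize $|\mathrm{RVD}|$ (published tables of this quantity are
  nonnegative), while raw per-patient output keeps the sign.

Degenerate cases are governed by explicit rules rather than NaNs:
structures missing from one set are flagged and not scored; both-empty
structures are undefined and excluded from summaries with a count; a
structure empty in exactly one set scores DSC 0 with HD undefined and
RVD $-1$ (test empty) or undefined (reference empty).

## Dose and DVH

Dose grids carry cGy values and a prescription. When dose and structure
grids differ, dose is trilinearly resampled onto the structure grid —
not the reverse, because rasterization fidelity of the structures
dominates metric sensitivity. The cumulative DVH is built over the
structure's voxels with a default bin width of 1 cGy. DVH inversions
($D_{x\%}$, $D_{v\,cc}$) return the largest bin edge whose cumulative
volume still covers the requested fraction or volume: at 1 cGy
resolution this is within one bin of a direct voxel sort for continuous
dose fields, and it is *exact* when the dose is concentrated at single
values — so a uniform field yields the same $D_{x\%}$ for every $x$,
$\mathrm{HI} = 0$, and $D_{\mathrm{mean}} = D_{\mathrm{min}}$, as it
should. Sub-bin linear interpolation was rejected because it smears
point masses across a bin and breaks those identities.

Derived indices:

- $\mathrm{HI} = (D_{2\%} - D_{98\%})/D_{50\%}$, zero for a perfectly
  uniform target dose and invariant under uniform dose scaling;
- $\mathrm{CI} = TV_{PV}^2/(V_{PTV}\cdot V_{TV})$ with $V_{TV}$ the
  volume receiving at least 95% of the prescription and $TV_{PV}$ its
  intersection with the PTV; in $(0,1]$, 1 iff the 95% isodose region
  coincides with the PTV;
- relative deltas $(X_{\mathrm{test}}-X_{\mathrm{ref}})/X_{\mathrm{ref}}$
  applied uniformly to dose statistics, HI, CI and nPQM. Deltas with a
  zero reference are undefined, logged and excluded from summaries.

The statistic keyword grammar (`Dmean`, `Dmedian`, `Dmax`, `Dmin`,
`D<x>%`, `D<v>cc`, `V<d>cGy`, `V<d>cGycc`) covers every published
constraint row the package ships. `Dmax` means the maximum voxel dose;
near-maximum reporting (`D0.03cc`, `D0.1cc`) is selected explicitly by
the scorecard, never substituted silently.

## Plan-quality scorecards

A scorecard is a YAML list of objectives, each scored independently:

- *threshold*: full points if the objective is met, zero otherwise;
- *linear*: two (threshold, score) pairs — the ideal threshold carrying
  the larger score — with linear interpolation of the score between
  them, the full score at or beyond the ideal threshold, and zero
  strictly beyond the minimally acceptable one.

The published prostate card prints a score at *both* linear thresholds
(5 at the ideal, 4 at the minimally acceptable), which conflicts with a
prose convention under which the minimally acceptable threshold is worth
nothing. The schema stores both pairs, so both readings are available:
the two-point reading (default, matching the printed card) interpolates
between 4 and 5; `convention = "prose"` forces the lower score to 0.
Every report states which convention was active. Fractional points are
allowed — nPQM is a ratio and integer rounding would distort it.

$\mathrm{PQM}$ is the sum of awarded points,
$\mathrm{nPQM} = 100\,\mathrm{PQM}/\mathrm{PQM_{max}} \in [0, 100]$,
with $\mathrm{PQM_{max}}$ the sum of per-objective maxima — each linear
objective contributes its larger score once (prostate card: 38;
head-and-neck card: 101). Objectives whose structure is missing or empty
score zero and are flagged; the evaluation continues, because a partial
score is more informative than an abort. Planning constraint sets
(strict inequalities, pass/fail, no points) ship alongside the
scorecards; protocol rows that name a structure without laterality are
expanded to both sides in the bundled files, and contralateral names
resolve to right-side structures by a fixed convention (recorded in the
alias table).

## Cohort pipeline and statistics

`runStudy()` chains the arms: geometry (AI vs adjusted, manual vs
adjusted), dosimetry (each arm's plan evaluated on its own contours,
deltas adjusted-vs-manual), plan quality, timing, Likert tallies and the
two-observer report (observer 2 is the delta denominator). Summaries
report mean (SD, $n-1$ denominator) and median (min–max); undefined
values are excluded and counted. Raw per-patient tables are always
written next to the summaries so every summary cell is recomputable.

Hypothesis testing follows the published analysis: a two-sided Wilcoxon
*rank-sum* test per structure × metric at $\alpha = 0.05$, with no
multiple-testing correction. The rank-sum test on paired per-patient
data is statistically unconventional — the paired signed-rank test is
available behind `paired = TRUE` and every report names the active test
— but the rank-sum form is the default for fidelity to the analysis it
reimplements. The implementation delegates to `stats::wilcox.test`; the
test suite verifies its exact small-sample p-values against a
from-scratch enumeration of the rank-sum null distribution.

Percent quantities are rounded only at presentation (integer percent for
time savings); raw CSVs keep full precision.

## Synthetic cohorts

The generator stands in for the clinical cohorts and fixes its defaults
once, as study conditions:

- *Grids*: prostate-like 2.5 × 2.5 × 5 mm on 64 × 64 × 28 voxels (5 mm
  slices being standard prostate practice), head-and-neck-like
  2 × 2 × 2 mm on 64 × 64 × 48. These sizes keep a five-patient
  end-to-end run in seconds while preserving realistic organ/voxel
  ratios.
- *Anatomy*: non-overlapping primitives — prostate-like: target
  ellipsoid with bladder antero-superior, rectum tube posterior, anal
  canal tube inferior, femoral heads lateral; head-and-neck-like: a
  reduced eight-structure roster spanning the large (oral cavity),
  mid-size (parotids, brainstem), elongated (spinal cord) and paired
  small (cochlea, ~0.2 cc) regimes. Coverage of metric regimes, not
  anatomical fidelity, is the goal. Sizes and positions are jittered
  per seed; overlaps are resolved by construction order.
- *Perturbation*: the AI set perturbs each manual structure to a target
  DSC of 0.85; each observer's adjusted set perturbs the AI set to DSC
  0.95. This builds in the ordering DSC(AI, adjusted) >
  DSC(manual, adjusted) — a light physician review of a coarser AI
  proposal — which is the qualitative signature the pipeline must
  detect. The perturbation moves the boundary by a smooth random field
  (6 cosine modes, 25–80 mm wavelengths) thresholded on the signed
  distance function, so disagreement looks like contour editing, not
  voxel speckle; amplitude calibration is by bisection with the field
  held fixed, deterministic per seed, and fails loudly when a target
  DSC is unreachable for a shape.
- *Dose*: prescription (6000 cGy prostate-like, 7095 cGy
  head-and-neck-like) inside the arm's own PTV with a 4% smooth
  heterogeneity, exponential falloff (10 mm length) outside. With the
  default heterogeneity every target voxel stays above the 95% isodose,
  so generated plans have CI = 1 and HI ≈ 0.05–0.1; larger noise
  amplitudes push CI below 1.
- *Timing and ratings*: manual and assisted times are drawn around 23
  and 6.4 min (prostate-like) / 150 and 23.6 min (head-and-neck-like),
  with the assisted time capped below 60% of manual so every patient
  saves time; Likert ratings are drawn from a fixed categorical mix
  (no correction 0.45, slight 0.35, medium 0.15, severe 0.05), chosen a
  priori as a plausible review profile.

All randomness flows from one master seed through arithmetic sub-seeds
per patient, structure and arm, so cohorts are bit-reproducible and the
full pipeline yields byte-identical CSV reports across runs.

What passing tests on these cohorts do *not* show: the phantoms have
smooth convex-ish organs, no image noise, no truly pathological AI
failures (a crop probability exists but defaults to 0), and dose fields
are analytic rather than optimizer output. Conclusions about a specific
commercial tool still require its own contours and plans; the pipeline
is what stays fixed.

## Numerical choices and limitations

- Voxel-center semantics everywhere: rasterization, surfaces, Hausdorff
  distances and volumes all refer to voxel centers; HD is reported in mm
  on the (possibly anisotropic) grid, and is granular at the voxel
  pitch, as HD values on coarse grids always are.
- DVH bin width is a recorded parameter (default 1 cGy); inversion is at
  bin-edge resolution (see above).
- Strict inequalities for protocol constraints, inclusive comparisons
  for scorecard thresholds (the score at exactly the printed threshold
  is the printed score).
- Bias/offset perturbations below the voxel pitch cannot change a mask;
  calibration targets DSC, which is well-defined regardless.
- The rank-sum default ignores pairing (see above); no correction for
  multiplicity is applied by default, matching the analysis convention
  it reproduces; a Benjamini–Hochberg adjustment can be applied to the
  returned p-value column by the user if desired.
- Structure-set I/O is plain text (run-length mask exchange format,
  contour CSV, dose text); binary clinical formats are expected to be
  converted upstream.

## Problem sizes used by the test suite

Oracle-equivalence checks run on random masks up to $10^3$ voxels (100
pairs, exact agreement with brute force); the discretization check uses
two 20 mm spheres at 1 mm spacing against the closed-form lens-overlap
DSC (within 2%); DVH checks use random fields up to $20^3$ voxels
against direct sorting (within one bin); calibration recovery runs 20
seeded shapes at targets {0.95, 0.8, 0.6} (±0.05 in ≥ 90%); the
determinism check runs the full pipeline twice on a seeded five-patient
cohort and compares report files byte-for-byte.
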