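---
title: "Methods: registering and scoring voltage against perfusion on the LV endocardium"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: registering and scoring voltage against perfusion on the LV endocardium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vtfuse)
```

This vignette documents the models, conventions and numerical choices behind
`vtfuse`. The package integrates two views of the same left-ventricular (LV)
substrate: a SPECT/CT-derived endocardial triangle mesh carrying
semiquantitative perfusion, and an electroanatomical mapping (EAM) point
cloud carrying bipolar voltage in a different coordinate frame.

## Geometry and the 17-segment model

An `LVMesh` stores vertices (mm), triangular faces, and an anatomical frame:
apex, base centroid, and the unit long axis pointing base→apex. Faces are
wound so normals point outward from the mesh solid; this convention fixes
signed quantities such as face orientation during decimation, and is
restored after any operation that could flip triangles.

Segment labels follow the standard AHA 17-segment convention, parameterised
in `segmentModel17()`:

* the axial extent below the base is split in equal thirds (boundaries at
  1/3 and 2/3) into basal, mid and apical bands — the clinical standard
  divides the long axis evenly and nothing in the source protocol suggests
  otherwise;
* the most apical 15% of the axial extent forms the apical cap (segment
  17). A purely sector-based apex is ill-defined on a continuous mesh, so
  the cap is given an explicit axial extent; 15% produces a cap whose
  vertex count is comparable to the other apical segments at both study
  resolutions;
* circumferential sectors (6 basal, 6 mid, 4 apical) are anchored to a
  declared anterior reference direction, with angle increasing towards the
  septum. Labelling depends only on position relative to the axis, so it is
  equivariant under rigid motion of mesh plus frame (a property tested
  directly).

`decimateMesh()` reduces resolution by quadric-error edge collapse: vertex
quadrics are accumulated from area-weighted face planes, and each round
collapses an independent (vertex-disjoint) set of lowest-cost edges, with
candidate positions restricted to the two endpoints and their midpoint.
Boundary (basal-rim) vertices only merge along the boundary so the open
base survives. Rounds stop exactly at the vertex budget, which is why the
358-vertex target is met within the ±2% the tests assert. Attributes are
then resampled by nearest original vertex — adequate for piecewise-constant
viability data, and deliberately simple to keep the transfer monotone.

## Synthetic subjects

The generator defines the conditions every test and the acceptance analysis
run under; its defaults are fixed once and mirror the study cohort:

| parameter | default | rationale |
|---|---|---|
| LV semi-axes | (25, 25, 65) mm | dilated ischaemic LV cavity dimensions |
| mesh resolutions | 3648 / 358 vertices | the two imaging resolutions used clinically |
| scar territory | inferior 0.75, anteroseptal 0.10, apical 0.15 | cohort had 15/2/3 of 20 |
| scar core uptake | 0.15 of subject max | severe fixed defect |
| border width | 8 mm | transition zone of the order of SPECT resolution |
| perfusion noise SD | 0.03 | keeps remote myocardium unambiguously normal |
| voltage model | log-normal, medians 0.15 / 0.8 / 3.0 mV, sdlog 0.45 | positive, right-skewed; medians sit inside the clinical <0.3 / 0.3–1.5 / >1.5 mV bands and sdlog keeps ≥90% of healthy points above 1.5 mV |
| points per subject | N(639, 197), N(776, 338), N(1804, 433) by group | per-group acquisition counts of the cohort |
| fiducials | 3 primary + 11 secondary, noise 2 mm | total 14 within the 12–15 used clinically; localisation noise is not quantified in the source, 2 mm is a realistic stand-in and is configurable |
| frame offset | rotation 5–25°, translation ≤30 mm/axis | plausible scanner-vs-mapping-system offset |
| deformation | 3 Gaussian bumps, amplitude U(2, 5) mm, σ = 20 mm | smooth, TPS-recoverable, magnitude comparable to cardiac-motion error |

Voltage points are sampled uniformly **by surface area** (not per vertex),
emulating a roving catheter, optionally jittered ≤2 mm off the surface
(default 1 mm). Each point's tissue class derives from the interpolated
local uptake through the perfusion score bins (<0.30 scar, <0.70 border,
else healthy), so enlarging a defect can only increase the fraction of
low-voltage points.

What the generator does **not** emulate: respiratory drift and field
scaling, electrogram fractionation, transmurality of perfusion defects,
clustered (region-of-interest) catheter sampling other than via an option,
and real inter-subject anatomical variability. Passing tests therefore
demonstrate correctness of the algorithms under controlled conditions, not
clinical-level agreement; in particular the synthetic cohort classifies
near-perfectly, whereas the clinical analogue reached ~70% concordance.

## Registration

The registration direction is EAM → SPECT (the voltage map is brought into
the imaging frame). The rigid stage solves orthogonal Procrustes over all
supplied primary pairs by SVD with the determinant +1 constraint, so a
configuration that would prefer a reflection still returns a proper
rotation. At least 3 non-collinear pairs are required; scale is fixed at 1
by default, with a similarity mode (`allowScale = TRUE`) available because
impedance fields can distort scale.

The nonrigid stage is a 3-D thin-plate spline with kernel U(r) = r fitted
on the rigidly aligned secondary pairs: the bending-energy-minimising
interpolant distributes each landmark's influence smoothly over space. With
`stiffness = 0` the warp reproduces every control point exactly (residuals
at machine precision — the kernel matrix is evaluated from exact coordinate
differences, since the expanded-square shortcut loses ~1e-7 mm near control
points); with `stiffness > 0` it smooths. Coplanar control points make the
interpolating system singular (one affine direction unidentifiable) and are
rejected with advice to add stiffness; with stiffness the minimal-norm
solution is taken instead. The TPS side conditions (weights orthogonal to
`[1 | X]`) are enforced by the linear system and checked by class validity.

Whether the clinical procedure interpolated or smoothed its secondary
fiducials is unknown; the default is exact interpolation (`stiffness = 0`)
with the regulariser exposed.

Fiducial registration error (`fre`) is the RMS residual at fitting
landmarks; target registration error (`tre`) is the same at held-out
points. On noise-free fiducials the full pipeline recovers ground-truth
surface positions to below 0.5 mm mean error for a typical subject (median
across subjects; individual subjects range roughly 0.3–0.6 mm depending on
where the deformation bumps fall relative to the secondary landmarks), and
the error grows monotonically with fiducial noise.

## Projection and point loss

Each registered point maps to its nearest mesh vertex within 10 mm (about
the SPECT spatial resolution); farther points are dropped and counted.
`maxDistanceMM = Inf` force-assigns every point, since it is unknown
whether the clinical pipeline dropped out-of-range points. Multiple points
on one vertex combine by minimum voltage by default — scar delineation errs
toward the lowest amplitude — with mean as the alternative. Nearest-vertex
(not nearest-face) assignment is used because segment scores are
vertex-indexed.

"Points used" is defined as the number of occupied vertices: a vertex
carries one effective value, so `loss = 1 − occupied/total`, bounded below
by `1 − V/N` (pigeonhole). This definition makes resolution dependence
assertable: loss is monotone as resolution falls, ≥48.9% for 700 points on
358 vertices, and zero for spread sub-sampled clouds on the 3648-vertex
mesh. Note that under this definition even the dense mesh shows loss for
dense random clouds (birthday collisions); the clinical "no loss at high
resolution" corresponds to the spread-sampling regime.

## Scoring

Scores ascend with viability (3 = fully viable). The clinical cutoffs fix
only the outer voltage bins (<0.3 mV deep scar, >1.5 mV healthy); the
border zone is split evenly at 0.9 mV. Perfusion bins are 30/50/70% of the
subject maximum — 50% is the conventional SPECT viability cut and <30% a
severe defect. Both tables are arguments, since the original scoring
software is unpublished. All bins are left-closed (an exact edge value
takes the higher score).

Per segment and modality the package reports n, mean and **sample** SD
(n−1; a single value gives SD 0 — fixed for determinism), and flags
heterogeneity when SD > mean. Voltage-empty segments are imputed to score 3
when their perfusion mean is at or above the viability threshold ("known
healthy"), and excluded from the denominator otherwise — which is how a
pooled denominator below 17 × subjects arises.

## Threshold selection and concordance

A single shared threshold binarises both modalities (mean ≥ t ⇒ viable; the
tie goes to viable by the category definitions). The sweep runs over all
observed score means; Youden's J selects the operating threshold, ties
resolved to the smaller value. The AUC is the trapezoidal area of the
continuous-voltage ROC against perfusion binarised at the chosen threshold.
This construction is intrinsically partly circular (one threshold defines
both truth and prediction) — it reproduces the clinical procedure's single
shared cutoff, and the exact original ROC procedure is not recoverable, so
the package treats it as the documented approximation. When a fixed
threshold is supplied (`rocSelect(table, threshold = )`), selection is
skipped; permutation nulls must use this form, because re-selecting the
Youden optimum per permutation biases the null AUC upward (~0.55 rather
than 0.5 in our checks).

Metrics come from the pooled 2×2 counts; any metric with a zero denominator
is NA (undefined), never 0. Per-subject concordances are also emitted.

In `runCohort()` the auto-threshold mode is made self-consistent in two
passes: impute at the scale midpoint (1.5), select the threshold, re-impute
at the selected value, classify. A numeric threshold skips selection
everywhere.

## Problem sizes and determinism

The default cohort (19 subjects, 3648-vertex meshes, up to ~2300 points per
subject) completes in well under a minute on one core; the test suite uses
a 600–900-vertex mesh for most unit properties and the full resolution
where the property concerns it (labelling partition, decimation to 358,
parameter recovery). All generators take explicit seeds and the whole run
is bit-reproducible per seed, which the tests assert byte-wise on the
written metrics JSON.

## Known limitations

* Nearest-vertex projection ignores face interiors; a point over a large
  triangle maps to its nearest corner.
* Decimation does not check for fold-overs; on the smooth LV shapes used
  here this has not been observed, but pathological inputs could produce
  self-intersections.
* The heterogeneity flag compares SD to mean on an ordinal scale, as in the
  source protocol; it is a coarse dispersion signal, not a variance test.
* The ROC construction shares a threshold between truth and predictor by
  design (see above); its AUC is not comparable to an externally validated
  classifier AUC.
* No electrogram waveform simulation, DICOM ingestion, or mapping-system
  export parsing.
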