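---
title: "Volumetric assessment of alveolar bone grafts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volumetric assessment of alveolar bone grafts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The clinical problem

In patients with a unilateral cleft of the alveolus, secondary alveolar
bone grafting (SABG) reconstructs the maxillary arch with autologous bone.
Outcome assessment asks three quantitative questions: how large was the
defect before surgery, how much material was grafted, and how much of it
is still mineralized bone at follow-up. `cleftvol` implements a
standardized answer from three cone-beam CT (CBCT) scans per patient —
pre-operative (V0), immediately post-operative (V1) and roughly six
months later (V2):

* **V_cleft** = mirror(V0) − V0 — the defect, measured against the
  patient's own unaffected side mirrored across the mid-sagittal
  (median palatine suture) plane;
* **V_graft** = V1 − V0 — the grafted material;
* **V_integrated** = V2 ∩ V_graft — mineralized tissue remaining inside
  the original graft envelope;
* **V_resorption** = V_graft − V_integrated (an exact bookkeeping
  identity, never measured independently);
* **V_missing** = mirror(V2) − V2 — the residual deficit relative to the
  mirrored healthy side.

From these, three clinical rates: filling rate = 100·V_graft/V_cleft
(>100% is overfilled, the usual surgical intent), alveolar cleft
restoration = 100·V_integrated/V_cleft, and bone graft resorption =
100·(V_graft − V_integrated)/V_graft. Rates are computed per case and
averaged across a cohort (mean of ratios); ratios of cohort mean volumes
are deliberately different numbers, and `compute_rates()` is tested on
both conventions.

## Pipeline and key design choices

### Segmentation

CBCT grey values are device-specific (not Hounsfield-calibrated), so the
bone and teeth windows of `threshold_spec()` are mandatory configuration
with both bounds inclusive. The dense bone-plus-teeth model is built by
`segment_case()` in three steps: dual thresholding, morphological closing
with a Euclidean ball of physical radius `closing_radius_mm` (default
0.5 mm, a few voxels at clinical 0.125–0.160 mm resolution — enough to
bridge thin cortical gaps), then deterministic cancellous filling:
every background component not 6-connected to the array border becomes
foreground. The interactive "semi-automatic" fill of commercial suites is
an operator convenience, not a definition; the border-connectivity rule
reproduces its intent deterministically.

All morphology uses exact anisotropic Euclidean distance transforms
(Felzenszwalb–Huttenlocher, compiled) thresholded at the physical radius,
i.e. a continuous Euclidean ball rather than a rounded per-axis discrete
ball; this respects anisotropic voxels and makes closing and opening
algebraically exact (extensive/anti-extensive and idempotent), which the
test suite asserts.

### Geometric normalization

Head orientation is standardized by re-slicing each grey volume parallel
to the occlusal plane (`reslice_to_plane()`): the minimal rotation maps
the current slice normal onto the occlusal normal, grey values are
interpolated trilinearly, and the output field of view is padded so
nothing is cropped. Masks are never interpolated with anything but
nearest neighbour, so Boolean algebra stays exact; all per-case algebra
happens on the V0 lattice after rigid registration of V1 and V2.

The mirror reference (`mirror_mask()`) reflects across a configured
plane; the plane is an input (placed on the median palatine suture), not
estimated. The reflection only sets the initial position — precise
alignment always comes from registration.

### Rigid registration by overlap maximization

`register_rigid()` finds the 6-DOF transform maximizing the Dice overlap
between binary models. Binary Dice is piecewise constant in the
parameters, so the optimizer maximizes a smooth surrogate: the
trilinearly interpolated moving model summed over sample points of the
fixed model (the denominator of soft Dice is constant for rigid maps that
keep the model in the field of view). The search is deterministic and
coarse-to-fine:

1. centre-of-mass initialization (composed with any supplied `init`);
2. an exhaustive translation scan (±10 mm, 2 mm steps) on a 4× box-filter
   pyramid level, followed by a rotation scan (±8°, 4° steps, intrinsic
   ZYX Euler angles) one level finer;
3. Nelder–Mead over all six parameters at the 2× level;
4. a rotation re-scan and re-centred Nelder–Mead polish rounds with a
   shrinking trust region on the full-resolution surface band of the
   fixed model.

Three numerical details matter and are worth recording. First,
downsampling must be a box filter: strided subsampling aliases the jagged
boundaries of rasterized masks and can displace the coarse optimum by
several degrees. Second, on coarse levels the sample weights are
(block occupancy − ½) over the fixed support plus a background halo;
without the negative background weights a constant-denominator overlap
sum rewards poses that push the moving model past the fixed boundary.
Third, the moving field is 7-point smoothed on coarse levels (otherwise
lattice-commensurate poses receive an interpolation bonus that can trap
the search at zero rotation), while the final polish deliberately uses
the raw field: its residual lattice preference snaps near-commensurate
optima — mirror alignments in particular — exactly onto the lattice,
which minimizes nearest-neighbour resampling damage. Rotation information
can also live entirely at fine spatial scales (coarse levels blur small
asymmetries away), hence the full-resolution rotation re-scan before the
polish.

Because some of these stages have no closed-form convergence guarantee,
the recovery of planted transforms is validated empirically: across 40
seeded trials with |t| ≤ 5 mm and |θ| ≤ 10°, the registration recovers
the pose within half a voxel and 1° in at least 95% of trials (in
practice with roughly threefold margin).

### Trimming and contour smoothing

Manual anatomical trimming and contour smoothing of the subtraction
models are replaced by deterministic surrogates: an axis-aligned world
trim box (`trim_to_box()`, voxel-centre inclusive) and a morphological
opening (`smooth_boundary()`, default radius 0.3 mm ≈ two voxels at
clinical resolution) applied to subtraction-derived masks only, where the
clinical protocol smooths manually. Opening removes protrusions thinner
than twice the radius — exactly the registration-jitter shells and mirror
asymmetry slivers the manual step targets.

## The phantom: what it emulates and what it does not

`generate_phantom()` builds a desk-scale stand-in for the clinical
triple-scan situation with exact, generator-side ground truth: a
horseshoe maxillary arch (outer radius 15 mm, thickness 6 mm, height
18 mm, 220° span) symmetric about the mid-sagittal plane; a unilateral
through-and-through cleft wedge (default 9 mm arc width, 6 mm depth at
30° from the midline); a graft that fills the wedge and overfills it
sideways and buccally (`overfill_factor`, default 1.36 — cohort filling
rates around 136% are the clinical norm); tooth spheres in symmetric
pairs; a soft-tissue cylinder; Gaussian noise (SD 25 grey units against
levels air 0 / soft tissue 80 / bone 400 / graft 450 / teeth 1000, so
default windows bone [200, 700] and teeth [700, 2000] segment cleanly);
and seeded rigid misalignments of V1 and V2 (up to 3 mm and 5°,
rasterized analytically through the inverse map — no interpolated grey
values, no pose hints in headers).

Resorption at V2 removes the requested volume fraction (default 0.57,
echoing typical six-month resorption rates around 56%) from the graft's
exposed buccal margin inward: graft voxels are ranked by exact Euclidean
distance from the outer free space (ties broken by |z|, then index) and
the deepest fraction is retained, which hits the requested retained
volume to within one voxel and leaves a geometrically coherent,
wall-adjacent integrated body — as graft remodelling does.

Two deliberate phantom-design choices keep the validation honest:

* **Rounded edges.** The cleft wedge and graft body are opened with the
  contour-smoothing radius at generation time. Real bone defects have no
  razor edges, and opening-invariant solids make the pipeline's contour
  smoothing idempotent on clean phantoms instead of a corner-shaving
  bias — so a measured-minus-truth discrepancy reflects the pipeline,
  not corner physics.
* **No partial-volume blur.** Boundaries are painted crisp, so the
  emitted case configs disable gap closing (there are no sub-voxel gaps
  to close, and closing would fillet concave junctions, i.e. alter the
  anatomy). With noise off, `segment_case()` recovers the clean masks
  voxel-for-voxel — asserted in the tests.

What the phantom does **not** emulate: partial-volume effects, beam
hardening, scatter and metal artifacts, anatomical asymmetry of the
healthy side, operator variability in plane placement, and facial growth
between timepoints. Passing the phantom suite therefore demonstrates the
correctness of the geometry, registration and Boolean volumetry under
controlled conditions; it does not certify clinical accuracy on real
CBCT data, where segmentation thresholds and landmark placement dominate
the error budget.

### Problem sizes used in the validation suite

The default phantom lattice is 160³ voxels at 0.25 mm — coarser than
clinical CBCT so that the complete validation (20 phantoms with noise and
misalignment, the same 20 seeds with both disabled, 40 registration
recovery trials, 1000 Boolean oracle pairs, 100 cohort replicates of
n = 23) runs in well under half an hour on one core. Module-level tests
use a 96³ lattice at 5/12 mm with identical anatomy. Observed recovery:
median absolute volume errors under default noise and misalignment are
below 2% for all five volumes (tolerance 5%), and below 1% with noise
and misalignment disabled.

## Synthetic cohorts and planted effects

`generate_cohort()` samples cleft width, overfill factor and resorption
fraction from uniform template ranges. Because the graft volume is
calibrated to `overfill_factor × cleft volume`, the filling rate equals
100 × overfill exactly, so a target Pearson correlation between filling
rate and cleft volume is planted directly on the overfill draw
(regression construction with standardized cleft volumes). By default
the manifest carries analytic (continuous-geometry) truth volumes — the
cohort-statistics check needs distributions, not images, and rasterizing
2300 phantoms would serve no purpose; `rasterize = TRUE` produces full
image volumes with exact voxel-count truth per case, and the manifest
records which basis applies (`truth_basis`). The analytic missing volume
uses the outer-margin resorption model: max(0, V_cleft − V_integrated).

`summarize_cohort()` reports per-metric means and sample SDs (n − 1
denominator) and Pearson correlations with two-sided p-values from the
t distribution with n − 2 degrees of freedom for the three clinically
interesting pairs (filling rate against cleft volume, resorption rate
and restoration rate). The correlation estimator is a documented choice:
cohort reports in this field rarely state the estimator, and Pearson on
rates is the convention. Degenerate inputs (zero variance) yield `NaN`
with a warning; degenerate denominators in `compute_rates()` raise
errors rather than silent `NaN`s — a clinical-report safety rule.

## Conventions and degenerate inputs

* World coordinates are LPS millimetres; voxel indices are 0-based; a
  voxel's value lives at its centre. NIfTI affines (RAS) are converted on
  read and write; only rigid affines are accepted (shear is an error).
* Masks serialize as int16 NIfTI for lossless round-trips; STL (binary,
  marching tetrahedra on the Kuhn 6-tetrahedra decomposition at the 0.5
  iso-level, watertight and outward-oriented) is export-only.
* DICOM series must be single-frame axial stacks with uniform slice gaps
  (tolerance 1e-3 mm — scanner jitter is tolerated, broken stacks are
  rejected); slice order is resolved from Image Position (Patient), so
  file listing order is irrelevant.
* Empty masks: registration refuses them; STL export refuses them;
  Boolean operations and volume measurement handle them exactly.
* All randomness (phantom noise, misalignment, cohort draws) is governed
  by explicit integer seeds; identical seeds give bit-identical volumes,
  manifests and registration results.

## Known limitations

* The registration objective follows the overlap-maximization principle
  on binary models; grey-level metrics (e.g. mutual information) are out
  of scope by design, and convergence is validated empirically rather
  than guaranteed.
* The mid-sagittal and occlusal planes are inputs; no automatic symmetry
  detection is attempted, so plane placement errors propagate into
  V_cleft and V_missing exactly as they do in the interactive protocol.
* Mirror-based defect measures are biased when the "healthy" side is
  itself abnormal; the phantom's healthy side is perfectly symmetric, so
  this bias is not exercised.
* Volumes are voxel counts; no sub-voxel (partial-volume) volume
  estimation is performed.
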