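---
title: "Reference-based nodal region delineation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-based nodal region delineation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hnatlas)
```

## The problem

Radiotherapy planning for head-and-neck cancer requires the clinical target
volume — dominated by the cervical lymph node levels — to be drawn on axial
CT slices, a slow manual task. `hnatlas` implements a reference-based
alternative: given a database of previously contoured subjects, the tool
(1) segments landmark structures (spine, mandible, hyoid, vessels) in both
reference and target volumes, (2) retrieves the reference whose anatomy is
geometrically most similar to the target, (3) registers the reference onto
the target with a landmark-initialized deformable transform, and
(4) projects the reference's expert-drawn region masks through the fitted
transform, producing candidate contours a physician can refine. Evaluation
is by Dice overlap, surface distances (in cm), the agreement between the
feature-space ranking `R_F` and the registration-outcome ranking `R_I`, and
the correlation between the feature distance `D_F` and the
post-registration Hausdorff distance `D_H`.

No clinical images ship with the package. A synthetic phantom cohort
generator stands in for them, with known ground truth at every stage; what
that does and does not demonstrate is discussed at the end.

## Transform model

The fitted transform is a rigid motion plus a cubic B-spline free-form
deformation:

$$g(x) = R\,(x - x_C) + x_C + T + D(x \mid \delta),$$

with Euler angles applied z–y–x about the volume centre $x_C$, translation
$T$, and $D$ the tensor-product cubic B-spline interpolation of
per-control-point coefficient vectors $\delta_j$ on a uniform grid. With
resolution $\rho$ (control points per axis) the knot spacing is image
extent divided by $\rho$; the maximum resolution used by the tool,
$[15, 15, 11]$, carries $2475$ control points. The literature this design
follows writes the grid index bounds as $0 \le l \le \rho_x$ (suggesting
$\rho + 1$ points) yet counts $15 \cdot 15 \cdot 11 = 2475$; we adopt
$\rho$ stored points per axis to match the printed count and replicate the
boundary coefficients outward (a ghost ring), so the cubic support covers
the whole image including corners.

**Direction convention.** `g(x)` maps a *target-frame* point to the
*reference* frame: that is the resampling direction, in which the
registered reference at target voxel $x$ is `reference(g(x))` and region
projection is a nearest-neighbour label lookup at `g(x)`. Papers in this
area typically describe the transform as "reference to target" while using
it in exactly this resampling sense; we state the convention explicitly
because inverting it silently is the classic registration bug. Landmark
pairs handed to the engine must live in the target frame
(`swap_landmarks()` flips a correspondence estimated the other way).

**Grid refinement.** Between multi-resolution levels the coarse field is
carried to the finer grid by least-squares fitting the fine coefficients to
the coarse field sampled at twice the fine control density. A plain
interpolation of the coarse field at the fine control points is the more
obvious construction, but for non-nested resolutions (e.g. $5^3 \to 9^3$)
it leaves 2–2.5% field discrepancy where the least-squares fit stays around
1.3%; non-nested spline spaces cannot represent each other exactly, so we
prefer the construction that minimizes the representation error.
`fit_coefficients_from_values()` retains exact interpolation semantics —
the landmark initialization requires the field to take prescribed values at
control points.

## Registration

The similarity metric is Parzen-window mutual information with 50 bins: a
zero-order kernel on the target intensities and a cubic B-spline kernel on
the interpolated reference intensities, over a seeded random 5% voxel
subset. MI is invariant to monotone intensity remapping, which is why it
tolerates contrast differences between subjects. The source literature
names neither estimator internals nor optimizer; ours are:

* **Rigid stage** — Nelder–Mead with generous parameter scaling on a 2×
  downsampled volume (the simplex search escapes the ridge where a
  translation partially compensates a rotation), then BFGS polish at full
  resolution.
* **Deformable stage** — per level (default schedule $[6,6,5] \to
  [10,10,8] \to [15,15,11]$): refine the grid, optionally re-initialize
  from landmarks, then gradient descent on negative MI over $\delta$ with
  backtracking line search. The gradient is analytic through the sparse
  B-spline basis matrix; the image gradient uses half-voxel central
  differences of the interpolated reference (a deliberately smoothed
  estimate). The rigid part stays frozen. Accepted steps are monotone in
  the metric by construction.

**Landmark initialization.** Every control point with a landmark within
`proximity_radius` (default: one grid spacing at the current level) adopts
the deformation of its *closest* landmark; all other control points keep
their current field value; coefficients are then refit by interpolation.
The initialized field need not be smooth — the subsequent MI optimisation
smooths it. Re-initialization happens at each level start and only at
in-radius control points, so optimizer progress elsewhere is preserved.

**Failure criterion.** The published account reports non-convergent runs
without defining failure; here a run is flagged failed on a non-finite
metric, and `converged` records whether the relative metric improvement
fell below tolerance within the iteration budget.

## Segmentation

Landmark structures are found by constraint-based dynamic thresholding
seeding a 3D active contour, progressing in order of detection
reliability. Per axial slice, 8 evenly spaced thresholds inside the rule's
intensity window are swept (highest first) and the first threshold whose
connected components pass the size window, the negative shape constraints
(elongation from second moments, solidity against the convex hull) and the
relative-location box around an earlier structure is accepted — a
sub-optimal threshold yielding partial structure is acceptable by design,
because the 3D growth completes it. The active contour is a morphological
evolution: per iteration the front dilates one voxel into the allowed
intensity window and a curvature constraint admits only voxels supported by
at least `curvature` neighbours; growth is monotone (the output always
contains the seed) and can be restricted to an axial slab of interest.
The concrete windows, sizes and boxes in `default_structure_rules()` are
configuration matched to the default phantom, not facts about anatomy; a
clinical deployment would retune them.

## Surface correspondence

Correspondence from mesh A to mesh B minimizes

$$E(C) = E_{sim} + \alpha E_{str} + \beta E_{pri},$$

with defaults $\alpha = 0.001$, $\beta = 0.0001$. The three roles
(similarity, structural distortion, prior plausibility) come from the
source method; their concrete forms there are delegated to an earlier
technique and are not printed, so the quadratic reading here —
$E_{sim}$ the mean squared distance of mapped points to surface B,
$E_{str}$ the mean squared graph-Laplacian of the displacement field,
$E_{pri}$ the mean squared displacement — is this package's
interpretation, and the module's largest inferred component.
Minimisation alternates closest-point assignment with an exact sparse
solve of the resulting quadratic; that is a majorize–minimize scheme, so
the true energy is non-increasing. Because closest-point assignment cannot
observe tangential motion on smooth surfaces, the descent is preceded by an
ICP rigid initialization by default (`init = "icp"`); structures are
corresponded independently and their sampled landmark pairs concatenated.

## Similarity retrieval

The feature vector per subject: body volume and extents; mandible and body
surface meshes; the 3D mandible–hyoid centroid offset; 2D hyoid–jugular and
hyoid–spine centroid offsets on the axial slice at the hyoid centroid;
vertical skull-base/mandible/hyoid distances (the skull base is proxied by
the superior body-extent plane — the weight list names it but the feature
list does not define it); and normalized hyoid/mandible centroid locations.
The distance is weighted Euclidean, $D_F = \sqrt{\sum_i w_i d_i^2}$:
absolute differences for scalars, Euclidean norms for vectors, and for mesh
features the ICP-aligned directional Hausdorff distance (reference → target;
a documented asymmetry). The published weights give only the range 10→0.1
and a priority order; `feature_weights()` interpolates that ordering
(hyoid-location features 10, mandible mesh 5, vertical distances 2, body
contour/volume 0.5, the rest 0.1) and expresses scalar terms in
decimetre-scale units (cm offsets, 100 cm³ volumes) so a single feature
cannot dominate purely through its unit. Mesh features are compared on
meshes decimated to ~600 vertices; the Hausdorff estimate uses area-uniform
surface sampling (seeded), which converges to the true directional value
from below as the sample count grows.

## Evaluation conventions

* Dice on voxel counts; both-empty is defined as 1 (agreement on absence —
  the ratio is otherwise 0/0).
* Surface distances between projected and ground-truth regions use **no**
  ICP prealignment — both already live in the target frame, and
  prealignment would hide exactly the registration error being measured.
  Retrieval-side mesh distances do prealign. Distances are reported in cm,
  by a single conversion at the reporting layer.
* The surface-distance direction is projected → truth, matching the
  directional Hausdorff definition; a symmetric option exists.
* `distance_correlation()` is Pearson by default (the published tables say
  "correlation coefficients" without qualification); Spearman is an option.
* Ranking ties are broken by stable input order.

## The synthetic cohort

`default_phantom_spec()` builds a 96³-voxel, 2 mm-spacing volume (192 mm
extent, matching head-and-neck fields of view): an ellipsoidal soft-tissue
body (40) in air (−1000) containing a posterior spine-like tube (800),
mandible-like (950) and hyoid-like (650) ellipsoids, paired jugular-like
(210) and carotid-like (230) contrast-vessel tubes, four nodal-region masks
placed between hyoid and vessels, and Gaussian intensity noise
(sd 10). Intensities follow the CT ordering bone > contrast vessel > soft
tissue > air. Cohort subjects are the base phantom with per-structure pose
jitter, warped by a random cubic B-spline field; the field's amplitude
parameter is its peak displacement magnitude (default 5 mm, knot spacing
48 mm — inter-subject-scale smooth variation), and the exact field is
returned so registration tests are parameter-recovery tests. Ground-truth
warps being B-spline fields on a coarse grid means perfect recovery is
representable by the registration model — a clean acceptance surface, and a
deliberate design choice.

What the phantoms do **not** emulate: streak/beam-hardening artifacts,
surgical resections, soft-tissue texture, oblique acquisitions, and true
anatomical shape variability. Passing the phantom suite therefore shows the
machinery is correct (transforms, metric, optimisation, projection,
ranking), not that the rules or weights are clinically adequate.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run at sizes chosen to exercise
every stage while staying desk-scale: warp-recovery registration at 96³/2 mm
(tests) and 64³/3 mm (script), the graded-amplitude retrieval cohort at
96³/2 mm with five subjects sharing one warp shape scaled to amplitudes
2–10 mm (a shared shape makes ranking monotone in amplitude by
construction), concentric-sphere Hausdorff checks on icospheres subdivided
four times (chordal error well under the 2% tolerance), and a 10,000-trial
permutation null for ranking agreement. Mutual information uses 50 bins and
a 5–8% voxel sample; interpolation is trilinear for intensities and strictly
nearest-neighbour for labels. Degenerate inputs fail loudly: constant images
(MI undefined), collinear ICP point sets, empty meshes, absent labels.

## Known limitations

* No folding prevention or diffeomorphic guarantee in the deformation
  (the method this follows has none either).
* The voxel-boundary isosurface is exact in enclosed volume but blocky;
  mesh distances on it carry half-voxel quantisation, which matters only
  below the voxel scale.
* Axis-aligned volumes only; no oblique direction cosines, no DICOM-RT.
* Segmentation rules are phantom-tuned configuration; real CT would need
  retuned windows and priors.
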