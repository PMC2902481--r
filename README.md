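# hnatlas

Reference-based delineation of head-and-neck lymph node regions in 3D
volumes.

Drawing the clinical target volume (CTV) for head-and-neck radiotherapy —
dominated by the cervical lymph node levels — is slow manual work on axial
CT slices. `hnatlas` implements the reference-based alternative: keep a
database of previously contoured subjects, find the one whose anatomy is
geometrically most similar to the new patient, deformably register it onto
the patient, and project its expert-drawn region masks through the fitted
transform as candidate contours.

The package provides the full pipeline:

* **Segmentation** — landmark structures (spine, mandible, hyoid, vessels)
  found by constraint-based dynamic thresholding seeding a 3D active
  contour, progressing in order of detection reliability
  (`progressive_segment()`).
* **Surface correspondence** — dense correspondence between homologous
  structure surfaces by minimising
  `E = E_sim + α·E_str + β·E_pri` (defaults α = 0.001, β = 0.0001),
  yielding landmark pairs (υ_k, ζ_k) (`correspond_surfaces()`,
  `sample_landmarks()`).
* **Registration** — rigid + cubic B-spline free-form deformation
  `g(x) = R(x − x_C) + x_C + T + D(x|δ)` fitted by multi-resolution
  Parzen-window mutual information, with the control grid optionally
  initialised from the landmark deformations at each level
  (`ffd_register()`, `deformable_register()`); masks are projected by
  nearest-neighbour lookup at `g(x)` (`project_region()`).
* **Retrieval** — weighted Euclidean feature distance
  `D_F = sqrt(Σ w_i d_i²)` over structure geometry (volumes, extents,
  centroid offsets, ICP-aligned directional Hausdorff mesh distances),
  ranking the reference database (`extract_features()`,
  `rank_references()`).
* **Evaluation** — Dice overlap, Hausdorff/mean surface distances in cm,
  agreement of the feature ranking R_F with the registration-outcome
  ranking R_I, and the D_F–D_H correlation (`dice()`,
  `region_surface_distances()`, `rank_agreement()`,
  `distance_correlation()`).
* **Synthetic cohort** — a head-and-neck-like phantom generator with
  labelled structures, nodal-region masks and *known* ground-truth
  B-spline warps, so every stage is testable without clinical data
  (`generate_phantom()`, `generate_cohort()`).

Volumes read/write MetaImage (`.mha`/`.mhd`) and NIfTI; meshes read/write
ASCII PLY/STL; expert contours import from per-slice polygon stacks
(JSON). A thin CLI (`inst/exec/hnatlas`) wraps the same functions
(`phantom`, `segment`, `register`, `project`, `rank`, `evaluate`).

## Worked example

Register a synthetic reference onto a warped, noisy target and project its
nodal regions (about two minutes at this size):

```r
library(hnatlas)

spec      <- default_phantom_spec(dims = c(64, 64, 64),
                                  spacing = c(3, 3, 3), noise_sd = 10)
reference <- generate_phantom(spec)
warp      <- random_warp_grid(spec$geometry, amplitude = 5,
                              control_spacing = 48, seed = 2)
target    <- warp_phantom(reference, warp)   # "new patient" + known truth

rules   <- default_structure_rules()[c("spine", "mandible", "hyoid",
                                       "jugular_left", "jugular_right")]
seg_t   <- progressive_segment(target$volume, rules)
seg_r   <- progressive_segment(reference$volume, rules)
lm      <- correspond_structure_sets(seg_t, seg_r,
                                     structures = c("mandible", "hyoid"),
                                     n_per_structure = 60, seed = 3)
cfg     <- registration_config(resolution_schedule = list(c(6, 6, 6),
                                                          c(10, 10, 10)),
                               use_landmarks = TRUE, seed = 4)
reg     <- deformable_register(reference$volume, target$volume,
                               init = NULL, config = cfg, landmarks = lm)
summary(reg)
#> Deformable B-spline registration (mutual information)
#> transform_parameters: angles (0.0000, 0.0000, 0.0000) rad, translation (0.00, 0.00, 0.00) mm
#>   control grid 10 x 10 x 10 (1000 points), coefficient RMS 1.022 mm
#>   level 1 (6x6x6): 25 accepted steps, metric -0.64697 -> -0.85337
#>   level 2 (10x10x10): 7 accepted steps, metric -0.84246 -> -0.86911
#>   converged: TRUE

proj   <- predict(reg, reference$nodal_regions)
report <- evaluate_projections(list(pair1 = proj),
                               list(pair1 = target$nodal_regions))
print(report, digits = 3)
#>    pair         region   dsc hausdorff_cm mean_cm
#> 1 pair1  level_1B_left 0.948        0.300 0.02977
#> 2 pair1 level_1B_right 0.898        0.300 0.05604
#> 3 pair1   level_2_left 0.981        0.297 0.01181
#> 4 pair1  level_2_right 0.990        0.282 0.00745
```

Reading: the landmark-initialised registration recovered the 5 mm synthetic
warp well enough that the projected nodal regions overlap the ground-truth
masks at Dice 0.90–0.99, with worst-case (Hausdorff) surface errors of
about 0.3 cm and mean surface errors well under a millimetre.

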