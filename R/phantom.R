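## Synthetic head-and-neck phantom cohort.
##
## A phantom is an ellipsoidal soft-tissue "body" in air containing analytic
## high-intensity bone primitives (spine-, mandible-, hyoid-like), tubular
## contrast-vessel primitives (jugular/carotid-like) and labelled nodal
## region masks.  Primitives are rasterized at voxel centres, so expected
## volumes are exact.  A cohort warps the base phantom with known smooth
## cubic B-spline displacement fields (the same transform family the
## registration engine fits, so registration tests are parameter-recovery
## tests) plus per-structure pose/scale jitter.
##
## Axes: x = left-right, y = anterior(-)/posterior(+), z = inferior-superior.

#' Phantom specification
#'
#' @param geometry a [volume_geometry()].
#' @param body list with `center` (mm), `semi_axes` (mm) and `intensity`.
#' @param structures named list; each element has `shape`
#'   (`"ellipsoid"`, `"tube"` or `"box"`), shape parameters (`center` +
#'   `semi_axes`, `p0` + `p1` + `radius`, or `center` + `half_size`) and an
#'   `intensity`.
#' @param nodal_regions named list of shape primitives (no intensity; these
#'   are the synthetic "expert contours").
#' @param noise_sd Gaussian intensity noise s.d. added to the volume only.
#' @param air background intensity (default -1000, CT-like).
#' @param seed integer seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(geometry, body, structures, nodal_regions = list(),
                         noise_sd = 0, air = -1000, seed = 1L) {
  stopifnot(inherits(geometry, "volume_geometry"))
  structure(list(geometry = geometry, body = body, structures = structures,
                 nodal_regions = nodal_regions, noise_sd = noise_sd,
                 air = air, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Default head-and-neck-like phantom
#'
#' 96^3 voxels at 2 mm spacing (192 mm extent): an ellipsoidal body of
#' soft-tissue intensity (40) in air (-1000), a spine-like posterior bone
#' tube (800), mandible-like (950) and hyoid-like (650) anterior bone
#' ellipsoids, paired jugular-like (210) and carotid-like (230)
#' contrast-vessel tubes, and four nodal-region masks (levels 1B/2, left and
#' right) placed between the hyoid and the vessels.
#'
#' @param dims,spacing volume geometry (defaults 96^3 at 2 mm).
#' @param noise_sd intensity noise s.d. (default 10).
#' @param seed integer seed.
#' @return A [phantom_spec()].
#' @export
default_phantom_spec <- function(dims = c(96, 96, 96), spacing = c(2, 2, 2),
                                 noise_sd = 10, seed = 1L) {
  geom <- volume_geometry(dims, spacing)
  ex <- geometry_extent(geom)
  c0 <- ex / 2
  ell <- function(dc, semi, int = NULL)
    c(list(shape = "ellipsoid", center = c0 + dc, semi_axes = semi),
      if (!is.null(int)) list(intensity = int))
  tube <- function(dxy, z0, z1, radius, int)
    list(shape = "tube", p0 = c(c0[1] + dxy[1], c0[2] + dxy[2], c0[3] + z0),
         p1 = c(c0[1] + dxy[1], c0[2] + dxy[2], c0[3] + z1),
         radius = radius, intensity = int)
  phantom_spec(
    geometry = geom,
    body = list(center = c0, semi_axes = c(75, 65, 92), intensity = 40),
    structures = list(
      spine = tube(c(0, 35), -58, 58, 11, 800),
      mandible = ell(c(0, -40, 40), c(26, 14, 9), 950),
      hyoid = ell(c(0, -38, 8), c(9, 5, 4), 650),
      jugular_left = tube(c(-28, -6), -55, 55, 5.5, 210),
      jugular_right = tube(c(28, -6), -55, 55, 5.5, 210),
      carotid_left = tube(c(-18, -10), -55, 55, 3.5, 230),
      carotid_right = tube(c(18, -10), -55, 55, 3.5, 230)),
    nodal_regions = list(
      level_1B_left = ell(c(-18, -32, 32), c(10, 10, 12)),
      level_1B_right = ell(c(18, -32, 32), c(10, 10, 12)),
      level_2_left = ell(c(-30, -15, 20), c(12, 14, 25)),
      level_2_right = ell(c(30, -15, 20), c(12, 14, 25))),
    noise_sd = noise_sd, seed = seed)
}

primitive_inside <- function(points, prim) {
  if (prim$shape == "ellipsoid") {
    rowSums(sweep(sweep(points, 2, prim$center), 2, prim$semi_axes, `/`)^2) <= 1
  } else if (prim$shape == "tube") {
    v <- prim$p1 - prim$p0
    len2 <- sum(v * v)
    t <- pmin(pmax(sweep(points, 2, prim$p0) %*% v / len2, 0), 1)
    closest <- sweep(outer(as.vector(t), v), 2, prim$p0, `+`)
    rowSums((points - closest)^2) <= prim$radius^2
  } else if (prim$shape == "box") {
    abs(sweep(points, 2, prim$center)) |>
      sweep(2, prim$half_size, `<=`) |> apply(1, all)
  } else stop("unknown primitive shape: ", prim$shape)
}

#' Rasterize a phantom
#'
#' Deterministic given the spec (including its seed).  Gaussian noise with
#' s.d. `noise_sd` is added to the intensity volume only, never to the
#' masks.
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` ([volume_image()]), `structures` and
#'   `nodal_regions` (both [region_mask()]), and `spec`.
#' @export
generate_phantom <- function(spec) {
  geom <- spec$geometry
  pts <- voxel_center_grid(geom)
  body_in <- primitive_inside(pts, c(spec$body, shape = "ellipsoid"))
  vals <- ifelse(body_in, spec$body$intensity, spec$air)
  labels <- integer(nrow(pts))
  for (i in seq_along(spec$structures)) {
    prim <- spec$structures[[i]]
    inside <- primitive_inside(pts, prim)
    if (any(inside & !body_in))
      stop("structure '", names(spec$structures)[i],
           "' extends outside the body ellipsoid")
    vals[inside] <- prim$intensity
    labels[inside] <- i
  }
  nodal <- integer(nrow(pts))
  for (i in seq_along(spec$nodal_regions)) {
    inside <- primitive_inside(pts, spec$nodal_regions[[i]])
    if (any(inside & !body_in))
      stop("nodal region '", names(spec$nodal_regions)[i],
           "' extends outside the body ellipsoid")
    nodal[inside] <- i
  }
  if (spec$noise_sd > 0) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(spec$seed)
    vals <- vals + stats::rnorm(length(vals), sd = spec$noise_sd)
  }
  d <- geom$dims
  list(volume = volume_image(array(vals, d), geom),
       structures = region_mask(array(labels, d), geom,
                                stats::setNames(seq_along(spec$structures),
                                                names(spec$structures))),
       nodal_regions = region_mask(array(nodal, d), geom,
                                   stats::setNames(seq_along(spec$nodal_regions),
                                                   names(spec$nodal_regions))),
       spec = spec)
}

#' Body mask of a phantom bundle
#'
#' Voxels inside the body ellipsoid, as a single-label [region_mask()].
#' @param bundle result of [generate_phantom()].
#' @export
phantom_body_mask <- function(bundle) {
  geom <- bundle$spec$geometry
  pts <- voxel_center_grid(geom)
  inside <- primitive_inside(pts, c(bundle$spec$body, shape = "ellipsoid"))
  region_mask(array(as.integer(inside), geom$dims), geom, c(body = 1L))
}

#' Cohort specification
#'
#' @param base a [phantom_spec()] for the base subject.
#' @param n_subjects number of warped subjects to generate (>= 1).
#' @param variation list with `translation_sd` (mm) and `scale_sd`
#'   (fractional) per-structure pose/size jitter.
#' @param deformation list with `amplitude` (mm; the peak displacement
#'   magnitude of each subject's ground-truth warp) and `control_spacing`
#'   (mm; knot spacing of the warp's B-spline grid).
#' @param seed integer root seed; per-subject streams are derived from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(base, n_subjects,
                        variation = list(translation_sd = 2, scale_sd = 0.05),
                        deformation = list(amplitude = 5, control_spacing = 48),
                        seed = 1L) {
  stopifnot(inherits(base, "phantom_spec"), n_subjects >= 1,
            deformation$amplitude >= 0)
  structure(list(base = base, n_subjects = as.integer(n_subjects),
                 variation = variation, deformation = deformation,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Random smooth B-spline displacement field
#'
#' Coefficients are drawn uniformly and the whole field rescaled so that its
#' peak displacement magnitude over the volume equals `amplitude`.
#'
#' @param geometry a [volume_geometry()].
#' @param amplitude peak |displacement| in mm.
#' @param control_spacing approximate knot spacing in mm (resolution >= 5).
#' @param seed integer seed.
#' @return a `control_grid` carrying the field.
#' @export
random_warp_grid <- function(geometry, amplitude, control_spacing = 48,
                             seed = 1L) {
  res <- pmax(5L, as.integer(round(geometry_extent(geometry) / control_spacing)))
  grid <- build_control_grid(res, geometry)
  if (amplitude <= 0) return(grid)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  grid$coefficients <- array(stats::runif(prod(res) * 3, -1, 1), c(res, 3L))
  # rescale so the peak |D| over a dense probe equals the amplitude
  probe <- voxel_center_grid(volume_geometry(
    pmin(geometry$dims, 32L), geometry_extent(geometry) / pmin(geometry$dims, 32L),
    geometry$origin))
  mags <- sqrt(rowSums(evaluate_deformation(probe, grid, clamp = TRUE)^2))
  grid$coefficients <- grid$coefficients * (amplitude / max(mags))
  grid
}

jitter_spec <- function(spec, translation_sd, scale_sd) {
  jit <- function(prim) {
    dt <- stats::rnorm(3, sd = translation_sd)
    sc <- 1 + stats::rnorm(1, sd = scale_sd)
    if (prim$shape == "ellipsoid") {
      prim$center <- prim$center + dt
      prim$semi_axes <- prim$semi_axes * sc
    } else if (prim$shape == "tube") {
      prim$p0 <- prim$p0 + dt; prim$p1 <- prim$p1 + dt
      prim$radius <- prim$radius * sc
    } else {
      prim$center <- prim$center + dt
      prim$half_size <- prim$half_size * sc
    }
    prim
  }
  spec$structures <- lapply(spec$structures, jit)
  spec$nodal_regions <- lapply(spec$nodal_regions, jit)
  spec
}

#' Warp a phantom bundle through a displacement field
#'
#' Resampling convention: the warped subject at point x takes the source
#' value at `x + D(x)` (trilinear for the volume, nearest-neighbour for the
#' label masks), so `D` is exactly the field a registration run from the
#' warped subject back to the source should recover.
#'
#' @param bundle result of [generate_phantom()].
#' @param warp a `control_grid` displacement field.
#' @return a bundle with warped `volume`, `structures`, `nodal_regions`.
#' @export
warp_phantom <- function(bundle, warp) {
  geom <- bundle$volume$geometry
  pts <- voxel_center_grid(geom)
  src <- pts + evaluate_deformation(pts, warp, clamp = TRUE)
  d <- geom$dims
  vol <- interp_volume(bundle$volume, src, outside = bundle$spec$air)
  out <- bundle
  out$volume <- volume_image(array(vol, d), geom)
  out$structures <- region_mask(array(lookup_labels(bundle$structures, src), d),
                                geom, bundle$structures$label_names)
  out$nodal_regions <- region_mask(array(lookup_labels(bundle$nodal_regions, src), d),
                                   geom, bundle$nodal_regions$label_names)
  out
}

#' Generate a synthetic cohort with known ground-truth warps
#'
#' Subject i is the base phantom with jittered structure poses, warped by a
#' known smooth B-spline displacement field, with intensity noise added
#' after warping.  The exact warp grids are returned for recovery tests; the
#' nodal masks are warped with the same fields (they play the role of the
#' expert contours).
#'
#' @param spec a [cohort_spec()].
#' @return list with `base` (unwarped bundle), `subjects` (list of bundles)
#'   and `warps` (list of `control_grid`s, one per subject).
#' @export
generate_cohort <- function(spec) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  sub_seeds <- sample.int(2^20, spec$n_subjects)
  base_spec <- spec$base
  base_spec$noise_sd <- 0
  base <- generate_phantom(base_spec)
  subjects <- vector("list", spec$n_subjects)
  warps <- vector("list", spec$n_subjects)
  for (i in seq_len(spec$n_subjects)) {
    set.seed(sub_seeds[i])
    spec_i <- base_spec
    ts <- spec$variation$translation_sd %||% 0
    ss <- spec$variation$scale_sd %||% 0
    if (ts > 0 || ss > 0) spec_i <- jitter_spec(spec_i, ts, ss)
    bundle_i <- generate_phantom(spec_i)
    warp <- random_warp_grid(spec$base$geometry, spec$deformation$amplitude,
                             spec$deformation$control_spacing %||% 48,
                             seed = sub_seeds[i])
    bundle_i <- warp_phantom(bundle_i, warp)
    if (spec$base$noise_sd > 0) {
      set.seed(sub_seeds[i] + 1L)
      bundle_i$volume$values <- bundle_i$volume$values +
        array(stats::rnorm(prod(spec$base$geometry$dims),
                           sd = spec$base$noise_sd),
              spec$base$geometry$dims)
    }
    subjects[[i]] <- bundle_i
    warps[[i]] <- warp
  }
  list(base = base, subjects = subjects, warps = warps)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Numerically invert a displacement field
#'
#' Finds `E` with `(x + D(x)) + E(x + D(x)) = x` by fixed-point iteration,
#' evaluated at the voxel centres of `geometry`.
#'
#' @param warp a `control_grid` displacement field `D`.
#' @param geometry where to evaluate the inverse.
#' @param iterations fixed-point iterations (default 20).
#' @return function mapping an n x 3 point matrix to inverse displacements.
#' @export
invert_displacement <- function(warp, geometry, iterations = 20L) {
  function(points) {
    y <- points
    for (k in seq_len(iterations))
      y <- points - evaluate_deformation(y, warp, clamp = TRUE)
    y - points
  }
}

#' Write a cohort to disk (volumes, masks, warp fields, manifest)
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_bundle <- function(bundle, prefix) {
    write_volume(bundle$volume, file.path(dir, paste0(prefix, "_volume.mha")),
                 element_type = "MET_FLOAT")
    write_mask(bundle$structures, file.path(dir, paste0(prefix, "_structures.mha")))
    write_mask(bundle$nodal_regions, file.path(dir, paste0(prefix, "_nodal.mha")))
    list(volume = paste0(prefix, "_volume.mha"),
         structures = paste0(prefix, "_structures.mha"),
         nodal_regions = paste0(prefix, "_nodal.mha"))
  }
  manifest <- list(base = write_bundle(cohort$base, "base"))
  manifest$subjects <- lapply(seq_along(cohort$subjects), function(i) {
    prefix <- sprintf("subject_%03d", i)
    entry <- write_bundle(cohort$subjects[[i]], prefix)
    geom <- cohort$base$volume$geometry
    pts <- voxel_center_grid(geom)
    D <- evaluate_deformation(pts, cohort$warps[[i]], clamp = TRUE)
    field <- lapply(1:3, function(a)
      volume_image(array(D[, a], geom$dims), geom))
    wf <- paste0(prefix, "_warp.mha")
    write_displacement_field(field, file.path(dir, wf))
    entry$warp <- wf
    entry
  })
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
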