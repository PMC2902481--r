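#' Volume geometry
#'
#' Describes the sampling grid of a 3D volume: voxel counts per axis,
#' anisotropic voxel spacing in millimetres and the world position of voxel
#' index (0,0,0).  Volumes are axis-aligned (axial acquisitions; no oblique
#' direction cosines), so the voxel-to-world map is the affine
#' `world = origin + index * spacing` applied componentwise.
#'
#' @param dims integer vector of length 3, voxels per axis (each >= 1).
#' @param spacing numeric vector of length 3, mm per voxel (each > 0).
#' @param origin numeric vector of length 3, world coordinates (mm) of voxel
#'   index `(0,0,0)`.  Defaults to the world origin.
#' @return An object of class `volume_geometry`.
#' @export
#' @examples
#' g <- volume_geometry(c(64, 64, 40), spacing = c(0.98, 0.98, 2.5))
#' voxel_to_world(c(2, 3, 4), g)
volume_geometry <- function(dims, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  dims <- as.integer(dims)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(dims) != 3L || any(is.na(dims)) || any(dims < 1L))
    stop("dims must be three integers >= 1")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive reals (mm/voxel)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be three finite reals (mm)")
  structure(list(dims = dims, spacing = spacing, origin = origin),
            class = "volume_geometry")
}

#' @export
print.volume_geometry <- function(x, ...) {
  cat(sprintf("volume_geometry: %d x %d x %d voxels, spacing (%g, %g, %g) mm, origin (%g, %g, %g) mm\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

geometry_equal <- function(a, b, tol = 1e-6) {
  identical(a$dims, b$dims) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' World-coordinate extent of a volume
#'
#' The image extent used by the control-grid construction: `dims * spacing`
#' per axis, in mm.
#' @param geometry a [volume_geometry()].
#' @return numeric length-3 vector (mm).
#' @export
geometry_extent <- function(geometry) {
  geometry$dims * geometry$spacing
}

#' 3D scalar volume
#'
#' A 3D scalar grid plus its [volume_geometry()].  Intensities are stored as
#' doubles; phantom volumes use a CT-like (Hounsfield-style) range.
#'
#' @param values 3D numeric array whose dimensions equal `geometry$dims`.
#' @param geometry a [volume_geometry()].
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(values, geometry) {
  stopifnot(inherits(geometry, "volume_geometry"))
  values <- as.array(values)
  if (length(dim(values)) != 3L || !all(dim(values) == geometry$dims))
    stop("values shape must equal geometry dims")
  storage.mode(values) <- "double"
  structure(list(values = values, geometry = geometry), class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  print(x$geometry)
  cat(sprintf("  intensity range [%g, %g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Labelled region mask
#'
#' A 3D non-negative integer label grid over a [volume_geometry()], with a
#' label -> region-name map (e.g. `c("level_1B_left" = 1)`).  Label 0 is
#' background and needs no name; every nonzero label present in the grid must
#' be named.
#'
#' @param labels 3D integer array (>= 0) with dimensions `geometry$dims`.
#' @param geometry a [volume_geometry()].
#' @param label_names named integer vector mapping region names to labels.
#' @return An object of class `region_mask`.
#' @export
region_mask <- function(labels, geometry, label_names = integer()) {
  stopifnot(inherits(geometry, "volume_geometry"))
  labels <- as.array(labels)
  if (length(dim(labels)) != 3L || !all(dim(labels) == geometry$dims))
    stop("labels shape must equal geometry dims")
  storage.mode(labels) <- "integer"
  if (any(labels < 0L)) stop("labels must be non-negative")
  present <- sort(unique(labels[labels > 0L]))
  label_names <- as.integer(label_names) |> stats::setNames(names(label_names))
  missing <- setdiff(present, label_names)
  if (length(missing))
    stop("unnamed labels present in mask: ", paste(missing, collapse = ", "))
  structure(list(labels = labels, geometry = geometry,
                 label_names = label_names),
            class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  print(x$geometry)
  counts <- vapply(x$label_names, function(l) sum(x$labels == l), numeric(1))
  for (i in seq_along(x$label_names))
    cat(sprintf("  label %d (%s): %d voxels\n", x$label_names[i],
                names(x$label_names)[i], counts[i]))
  invisible(x)
}

mask_label_of <- function(mask, label) {
  if (is.character(label)) {
    if (!label %in% names(mask$label_names))
      stop("region '", label, "' not present in mask")
    label <- mask$label_names[[label]]
  }
  as.integer(label)
}

#' Map voxel indices to world coordinates
#'
#' 0-based voxel indices; indices outside the volume are allowed (the map is
#' affine).  `world_to_voxel` is its exact inverse and returns fractional
#' indices.
#'
#' @param index numeric vector of length 3 (one index) or an n x 3 matrix.
#' @param geometry a [volume_geometry()].
#' @return Same shape as `index`: world coordinates in mm.
#' @export
voxel_to_world <- function(index, geometry) {
  if (is.matrix(index)) {
    sweep(sweep(index, 2, geometry$spacing, `*`), 2, geometry$origin, `+`)
  } else {
    geometry$origin + index * geometry$spacing
  }
}

#' @rdname voxel_to_world
#' @param world numeric vector of length 3 or an n x 3 matrix of mm points.
#' @export
world_to_voxel <- function(world, geometry) {
  if (is.matrix(world)) {
    sweep(sweep(world, 2, geometry$origin, `-`), 2, geometry$spacing, `/`)
  } else {
    (world - geometry$origin) / geometry$spacing
  }
}

#' World coordinates of every voxel centre
#'
#' @param geometry a [volume_geometry()].
#' @return `prod(dims)` x 3 matrix of mm points, x fastest (R array order).
#' @export
voxel_center_grid <- function(geometry) {
  d <- geometry$dims
  idx <- cbind(
    rep.int(seq_len(d[1]) - 1L, d[2] * d[3]),
    rep.int(rep(seq_len(d[2]) - 1L, each = d[1]), d[3]),
    rep(seq_len(d[3]) - 1L, each = d[1] * d[2]))
  voxel_to_world(idx, geometry)
}

#' Trilinear interpolation of a volume at world points
#'
#' Points outside the volume are assigned `outside` (default `NA`); callers
#' such as the registration metric treat those samples as missing.
#'
#' @param vol a [volume_image()].
#' @param points n x 3 matrix of world-mm points.
#' @param outside value for points outside the grid.
#' @return numeric vector of length n.
#' @export
interp_volume <- function(vol, points, outside = NA_real_) {
  v <- world_to_voxel(points, vol$geometry)
  d <- vol$geometry$dims
  i0 <- floor(v)
  f <- v - i0
  # clamp so voxel pairs (i0, i0+1) stay inside; record which were outside
  out <- v[, 1] < 0 | v[, 1] > d[1] - 1 |
         v[, 2] < 0 | v[, 2] > d[2] - 1 |
         v[, 3] < 0 | v[, 3] > d[3] - 1
  i0[, 1] <- pmin(pmax(i0[, 1], 0), d[1] - 2L)
  i0[, 2] <- pmin(pmax(i0[, 2], 0), d[2] - 2L)
  i0[, 3] <- pmin(pmax(i0[, 3], 0), d[3] - 2L)
  f <- v - i0
  f[, 1] <- pmin(pmax(f[, 1], 0), 1)
  f[, 2] <- pmin(pmax(f[, 2], 0), 1)
  f[, 3] <- pmin(pmax(f[, 3], 0), 1)
  a <- vol$values
  lin <- function(dx, dy, dz)
    a[cbind(i0[, 1] + dx + 1L, i0[, 2] + dy + 1L, i0[, 3] + dz + 1L)]
  w000 <- (1 - f[, 1]) * (1 - f[, 2]) * (1 - f[, 3])
  w100 <- f[, 1] * (1 - f[, 2]) * (1 - f[, 3])
  w010 <- (1 - f[, 1]) * f[, 2] * (1 - f[, 3])
  w110 <- f[, 1] * f[, 2] * (1 - f[, 3])
  w001 <- (1 - f[, 1]) * (1 - f[, 2]) * f[, 3]
  w101 <- f[, 1] * (1 - f[, 2]) * f[, 3]
  w011 <- (1 - f[, 1]) * f[, 2] * f[, 3]
  w111 <- f[, 1] * f[, 2] * f[, 3]
  res <- w000 * lin(0L, 0L, 0L) + w100 * lin(1L, 0L, 0L) +
         w010 * lin(0L, 1L, 0L) + w110 * lin(1L, 1L, 0L) +
         w001 * lin(0L, 0L, 1L) + w101 * lin(1L, 0L, 1L) +
         w011 * lin(0L, 1L, 1L) + w111 * lin(1L, 1L, 1L)
  res[out] <- outside
  res
}

#' Nearest-neighbour lookup of a label grid at world points
#'
#' Used for region projection: labels must never be intensity-interpolated.
#'
#' @param mask a [region_mask()].
#' @param points n x 3 matrix of world-mm points.
#' @return integer vector of labels; points outside the grid map to 0
#'   (background).
#' @export
lookup_labels <- function(mask, points) {
  v <- round(world_to_voxel(points, mask$geometry))
  d <- mask$geometry$dims
  out <- v[, 1] < 0 | v[, 1] >= d[1] |
         v[, 2] < 0 | v[, 2] >= d[2] |
         v[, 3] < 0 | v[, 3] >= d[3]
  v[out, ] <- 0
  lab <- mask$labels[cbind(v[, 1] + 1L, v[, 2] + 1L, v[, 3] + 1L)]
  lab[out] <- 0L
  lab
}
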