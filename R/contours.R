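## Importer for expert-drawn region contours supplied as per-slice closed
## polygons (a structured-text stand-in for planning-system exports, which
## draw regions as 2D contours on axial slices).  Polygons are rasterized
## into the label-volume representation used everywhere else.

point_in_polygon <- function(px, py, poly) {
  # even-odd crossing test, vectorised over query points
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi + 1e-300) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Rasterize a contour stack into a region mask
#'
#' Reads a JSON contour stack: a list of regions, each with per-slice closed
#' polygons (vertex lists in world mm).  Each polygon is rasterized on its
#' nearest axial slice with an even-odd fill; overlapping polygons of the
#' same region on the same slice therefore cut holes, matching the usual
#' planning-contour convention.
#'
#' Expected JSON shape:
#' \preformatted{
#' {"regions": [
#'   {"name": "level_2_left",
#'    "slices": [{"z": 40.0, "polygons": [[[x1,y1],[x2,y2],...]]}]}
#' ]}
#' }
#'
#' @param path JSON file.
#' @param geometry target [volume_geometry()].
#' @return a [region_mask()].
#' @export
read_contour_stack <- function(path, geometry) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$regions)) stop("contour stack has no 'regions' field: ", path)
  d <- geometry$dims
  labels <- array(0L, d)
  label_names <- integer(0)
  gx <- geometry$origin[1] + (seq_len(d[1]) - 1) * geometry$spacing[1]
  gy <- geometry$origin[2] + (seq_len(d[2]) - 1) * geometry$spacing[2]
  px <- rep(gx, times = d[2])
  py <- rep(gy, each = d[1])
  for (ri in seq_along(obj$regions)) {
    reg <- obj$regions[[ri]]
    lab <- length(label_names) + 1L
    label_names <- c(label_names, stats::setNames(lab, reg$name))
    for (sl in reg$slices) {
      k <- round((sl$z - geometry$origin[3]) / geometry$spacing[3]) + 1L
      if (k < 1L || k > d[3]) next
      filled <- rep(FALSE, d[1] * d[2])
      for (poly in sl$polygons) {
        P <- matrix(unlist(poly), ncol = 2, byrow = TRUE)
        if (nrow(P) < 3) next
        filled <- xor(filled, point_in_polygon(px, py, P))
      }
      sl_lab <- labels[, , k]
      sl_lab[filled] <- lab
      labels[, , k] <- sl_lab
    }
  }
  region_mask(labels, geometry, label_names)
}

#' Write a region mask as a contour stack (JSON)
#'
#' Traces each label's per-slice boundary as rectilinear polygons following
#' the voxel boundaries (exact for the label raster).
#'
#' @param mask a [region_mask()].
#' @param path output JSON file.
#' @export
write_contour_stack <- function(mask, path) {
  geom <- mask$geometry
  d <- geom$dims
  regions <- list()
  for (nm in names(mask$label_names)) {
    lab <- mask$label_names[[nm]]
    slices <- list()
    for (k in seq_len(d[3])) {
      sl <- mask$labels[, , k] == lab
      if (!any(sl)) next
      polys <- trace_boundary_polygons(sl, geom)
      slices[[length(slices) + 1L]] <-
        list(z = geom$origin[3] + (k - 1) * geom$spacing[3],
             polygons = polys)
    }
    regions[[length(regions) + 1L]] <- list(name = nm, slices = slices)
  }
  jsonlite::write_json(list(regions = regions), path, digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

# rectilinear polygons covering a 2D logical mask exactly: one rectangle per
# vertical pixel run (disjoint rectangles, so the even-odd fill reproduces
# the raster bit-exactly)
trace_boundary_polygons <- function(sl, geom) {
  d <- dim(sl)
  polys <- list()
  for (j in seq_len(d[2])) {
    col <- sl[, j]
    rr <- rle(col)
    ends <- cumsum(rr$lengths)
    starts <- ends - rr$lengths + 1
    for (q in seq_along(rr$values)) {
      if (!rr$values[q]) next
      x0 <- geom$origin[1] + (starts[q] - 1.5) * geom$spacing[1]
      x1 <- geom$origin[1] + (ends[q] - 0.5) * geom$spacing[1]
      y0 <- geom$origin[2] + (j - 1.5) * geom$spacing[2]
      y1 <- geom$origin[2] + (j - 0.5) * geom$spacing[2]
      polys[[length(polys) + 1L]] <- list(c(x0, y0), c(x1, y0),
                                          c(x1, y1), c(x0, y1))
    }
  }
  polys
}
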