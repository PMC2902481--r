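## Knowledge-based landmark-structure segmentation.
##
## Each structure carries a rule: an intensity window, a 2D size window,
## negative shape constraints (predicates that reject infeasible regions)
## and a location prior expressed relative to structures segmented earlier.
## Structures are processed in order of detection reliability; per axial
## slice a dynamic threshold sweep proposes candidate 2D regions, the
## accepted regions seed a 3D active-contour evolution, and the grown mask
## plus its surface mesh feed later rules, the correspondence stage and the
## similarity features.

#' Segmentation rule for one structure
#'
#' @param name structure name.
#' @param intensity_window `c(low, high)` intensity bounds for the threshold
#'   sweep and the active-contour growth region.
#' @param size_window `c(min, max)` acceptable 2D region area in mm^2.
#' @param shape_constraints list of negative predicates: `max_elongation`
#'   (sqrt of second-moment eigenvalue ratio) and `min_solidity`
#'   (area / convex-hull area).  A region violating any is rejected.
#' @param location_prior `NULL`, or a list with `ref` (name of an
#'   earlier-ranked structure), `offset` (mm, expected centroid of this
#'   structure relative to the reference centroid) and `box` (mm half-sizes
#'   of the acceptance box around that expected centroid).
#' @param reliability_rank lower ranks are segmented earlier and may be
#'   referenced by later rules.
#' @param contour_params list with `iterations` (3D active-contour sweeps)
#'   and `curvature` (minimum 6-neighbour support for a voxel to be added;
#'   higher is smoother).
#' @param slab optional `c(zmin, zmax)` mm window restricting the evolution
#'   to an axial slab of interest.
#' @return An object of class `structure_rule`.
#' @export
structure_rule <- function(name, intensity_window, size_window,
                           shape_constraints = list(max_elongation = 3,
                                                    min_solidity = 0.7),
                           location_prior = NULL,
                           reliability_rank = 1L,
                           contour_params = list(iterations = 40L,
                                                 curvature = 2L),
                           slab = NULL) {
  stopifnot(intensity_window[1] < intensity_window[2],
            size_window[1] < size_window[2])
  structure(list(name = name,
                 intensity_window = as.numeric(intensity_window),
                 size_window = as.numeric(size_window),
                 shape_constraints = shape_constraints,
                 location_prior = location_prior,
                 reliability_rank = as.integer(reliability_rank),
                 contour_params = contour_params,
                 slab = slab),
            class = "structure_rule")
}

#' Default rules matching the default phantom's structures
#'
#' The windows, sizes and relative-location boxes are configuration chosen
#' for [default_phantom_spec()]'s primitives (a clinical deployment would
#' tune them to real anatomy).
#' @return named list of [structure_rule()]s.
#' @export
default_structure_rules <- function() {
  list(
    spine = structure_rule("spine", c(700, 900), c(250, 500),
                           reliability_rank = 1L),
    mandible = structure_rule("mandible", c(850, 1050), c(100, 1400),
                              location_prior = list(ref = "spine",
                                                    offset = c(0, -75, 40),
                                                    box = c(20, 25, 25)),
                              reliability_rank = 2L),
    hyoid = structure_rule("hyoid", c(550, 750), c(40, 200),
                           location_prior = list(ref = "mandible",
                                                 offset = c(0, 2, -32),
                                                 box = c(15, 15, 14)),
                           reliability_rank = 3L),
    jugular_left = structure_rule("jugular_left", c(150, 270), c(60, 150),
                                  location_prior = list(ref = "hyoid",
                                                        offset = c(-28, 32, 0),
                                                        box = c(10, 10, 60)),
                                  reliability_rank = 4L),
    jugular_right = structure_rule("jugular_right", c(150, 270), c(60, 150),
                                   location_prior = list(ref = "hyoid",
                                                         offset = c(28, 32, 0),
                                                         box = c(10, 10, 60)),
                                   reliability_rank = 5L),
    carotid_left = structure_rule("carotid_left", c(150, 270), c(15, 55),
                                  location_prior = list(ref = "hyoid",
                                                        offset = c(-18, 28, 0),
                                                        box = c(8, 8, 60)),
                                  reliability_rank = 6L),
    carotid_right = structure_rule("carotid_right", c(150, 270), c(15, 55),
                                   location_prior = list(ref = "hyoid",
                                                         offset = c(18, 28, 0),
                                                         box = c(8, 8, 60)),
                                   reliability_rank = 7L))
}

# 4-connected components of a 2D logical matrix (igraph union-find)
label_components_2d <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(mask)
  if (!length(idx)) return(lab)
  nr <- nrow(mask)
  id <- seq_along(idx)
  lut <- integer(length(mask)); lut[idx] <- id
  edges <- NULL
  right <- idx[(idx + nr) <= length(mask) & mask[pmin(idx + nr, length(mask))]]
  down <- idx[(idx %% nr) != 0 & mask[pmin(idx + 1L, length(mask))]]
  e1 <- cbind(lut[right], lut[right + nr])
  e2 <- cbind(lut[down], lut[down + 1L])
  edges <- rbind(e1, e2)
  g <- igraph::graph_from_edgelist(
    rbind(edges, cbind(id, id)), directed = FALSE)
  comp <- igraph::components(g)$membership[seq_along(id)]
  lab[idx] <- as.integer(comp)
  lab
}

region_props_2d <- function(pix, spacing) {
  # pix: k x 2 matrix of 1-based (i,j); spacing: mm per pixel (x, y)
  xy <- cbind((pix[, 1] - 1) * spacing[1], (pix[, 2] - 1) * spacing[2])
  area <- nrow(pix) * spacing[1] * spacing[2]
  cen <- colMeans(xy)
  el <- 1
  if (nrow(pix) > 2) {
    cv <- stats::cov(xy) + diag(1e-9, 2)
    ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
    el <- sqrt(max(ev) / max(min(ev), 1e-12))
  }
  sol <- 1
  if (nrow(pix) > 3) {
    hull <- grDevices::chull(xy)
    hx <- xy[hull, 1]; hy <- xy[hull, 2]
    hull_area <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
    # pixel area underestimates the hull of pixel centres; pad by a pixel rim
    sol <- area / max(hull_area + 0.5 * sqrt(area) * mean(spacing), area)
  }
  list(area = area, centroid = cen, elongation = el, solidity = sol)
}

#' Dynamic threshold sweep on one axial slice
#'
#' Sweeps 8 evenly spaced thresholds through the rule's intensity window
#' (coarse to fine, i.e. highest threshold first) and returns the connected
#' components of the first threshold whose components pass the size, shape
#' and relative-location constraints.  An empty list is a valid outcome:
#' some slices segment and others do not.
#'
#' @param slice 2D numeric matrix (one axial slice).
#' @param rule a [structure_rule()].
#' @param context named list of previously found structures; each element
#'   has at least a `centroid` (mm, 3D).  Required if the rule has a
#'   location prior.
#' @param geometry the volume's [volume_geometry()] (pixel spacing).
#' @param z_mm world z of the slice.
#' @return list of candidate regions, each with `pixels` (k x 2 matrix of
#'   1-based indices), `centroid` (mm, 3D) and `area` (mm^2).
#' @export
dynamic_threshold_slice <- function(slice, rule, context = list(),
                                    geometry, z_mm) {
  win <- rule$intensity_window
  prior <- rule$location_prior
  if (!is.null(prior) && is.null(context[[prior$ref]]))
    return(list())
  thresholds <- rev(seq(win[1], win[2], length.out = 9L)[1:8])
  sp <- geometry$spacing[1:2]
  for (t in thresholds) {
    bin <- slice >= t & slice <= win[2]
    if (!any(bin)) next
    lab <- label_components_2d(bin)
    keep <- list()
    for (cid in seq_len(max(lab))) {
      pix <- which(lab == cid, arr.ind = TRUE)
      pr <- region_props_2d(pix, sp)
      if (pr$area < rule$size_window[1] || pr$area > rule$size_window[2]) next
      sc <- rule$shape_constraints
      if (!is.null(sc$max_elongation) && pr$elongation > sc$max_elongation) next
      if (!is.null(sc$min_solidity) && pr$solidity < sc$min_solidity) next
      cen3 <- c(geometry$origin[1:2] + pr$centroid, z_mm)
      if (!is.null(prior)) {
        expected <- context[[prior$ref]]$centroid + prior$offset
        if (any(abs(cen3 - expected) > prior$box)) next
      }
      keep[[length(keep) + 1L]] <- list(pixels = pix, centroid = cen3,
                                        area = pr$area)
    }
    if (length(keep)) return(keep)
  }
  list()
}

shift_logical <- function(x, s) {
  d <- dim(x)
  out <- array(FALSE, d)
  src <- lapply(1:3, function(a) {
    i <- seq_len(d[a]) - s[a]
    i[i < 1 | i > d[a]] <- NA
    i
  })
  ok <- lapply(src, function(i) !is.na(i))
  out[ok[[1]], ok[[2]], ok[[3]]] <-
    x[src[[1]][ok[[1]]], src[[2]][ok[[2]]], src[[3]][ok[[3]]]]
  out
}

neighbor_count <- function(x) {
  n <- array(0L, dim(x))
  for (s in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                 c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)))
    n <- n + shift_logical(x, s)
  n
}

#' 3D active-contour growth from partial 2D seeds
#'
#' Morphological level-set-style evolution: per iteration the front dilates
#' by one voxel (6-connectivity) into the allowed intensity window, and a
#' curvature constraint admits only new voxels supported by at least
#' `curvature` foreground neighbours.  The seed is always contained in the
#' output (monotone growth); zero iterations returns the seed unchanged.
#'
#' @param volume a [volume_image()].
#' @param seeds 3D logical array of seed voxels (non-empty).
#' @param params list with `iterations`, `curvature` and optionally
#'   `intensity_window` (defaults to the range of the seed intensities,
#'   expanded by 10%).
#' @param slab optional `c(zmin, zmax)` mm axial slab restriction.
#' @return 3D logical array.
#' @export
active_contour_3d <- function(volume, seeds, params = list(), slab = NULL) {
  if (!any(seeds)) stop("active contour needs a non-empty seed")
  iterations <- params$iterations %||% 40L
  curvature <- params$curvature %||% 2L
  win <- params$intensity_window
  if (is.null(win)) {
    sv <- range(volume$values[seeds])
    pad <- 0.1 * max(diff(sv), 1)
    win <- c(sv[1] - pad, sv[2] + pad)
  }
  allowed <- volume$values >= win[1] & volume$values <= win[2]
  if (!is.null(slab)) {
    z <- volume$geometry$origin[3] +
      (seq_len(volume$geometry$dims[3]) - 1) * volume$geometry$spacing[3]
    outside <- z < slab[1] | z > slab[2]
    allowed[, , outside] <- FALSE
  }
  cur <- seeds
  for (k in seq_len(iterations)) {
    cand <- (!cur) & allowed & (neighbor_count(cur) >= 1L)
    if (!any(cand)) break
    u <- cur | cand
    grow <- cand & (neighbor_count(u) >= curvature)
    if (!any(grow)) break
    cur <- cur | grow
  }
  cur | seeds
}

#' Progressive knowledge-based segmentation
#'
#' Processes rules in `reliability_rank` order.  For each structure, the
#' dynamic threshold sweep runs on every axial slice, accepted regions seed
#' the 3D active contour, and the result is recorded as a mask label plus a
#' surface mesh.  A rule whose prior references a structure that was not
#' found is skipped with a warning (partial success is a valid outcome);
#' voxels claimed by earlier structures are not re-claimed.
#'
#' @param volume a [volume_image()].
#' @param rules list of [structure_rule()]s.
#' @return An object of class `structure_set`: list with `masks`
#'   ([region_mask()]), `meshes` (named list of [surface_mesh()]) and
#'   `centroids` (named list, mm).
#' @export
progressive_segment <- function(volume, rules) {
  geom <- volume$geometry
  d <- geom$dims
  if (length(rules)) {
    ranks <- vapply(rules, function(r) r$reliability_rank, numeric(1))
    rules <- rules[order(ranks)]
    nm <- vapply(rules, function(r) r$name, character(1))
    for (i in seq_along(rules)) {
      pr <- rules[[i]]$location_prior
      if (!is.null(pr)) {
        j <- match(pr$ref, nm)
        if (!is.na(j) && rules[[j]]$reliability_rank >= rules[[i]]$reliability_rank)
          stop("cyclic/forward location-prior dependency: ",
               rules[[i]]$name, " -> ", pr$ref)
      }
    }
  }
  labels <- array(0L, d)
  label_names <- integer(0)
  meshes <- list()
  context <- list()
  zs <- geom$origin[3] + (seq_len(d[3]) - 1) * geom$spacing[3]
  for (rule in rules) {
    if (!is.null(rule$location_prior) &&
        is.null(context[[rule$location_prior$ref]])) {
      warning("skipping '", rule$name, "': prior structure '",
              rule$location_prior$ref, "' was not found")
      next
    }
    seeds <- array(FALSE, d)
    for (k in seq_len(d[3])) {
      regions <- dynamic_threshold_slice(volume$values[, , k], rule,
                                         context, geom, zs[k])
      for (reg in regions)
        seeds[cbind(reg$pixels, k)] <- TRUE
    }
    if (!any(seeds)) {
      warning("structure '", rule$name, "' not detected on any slice")
      next
    }
    params <- rule$contour_params
    params$intensity_window <- params$intensity_window %||% rule$intensity_window
    grown <- active_contour_3d(volume, seeds, params, rule$slab)
    grown <- grown & labels == 0L
    if (!any(grown)) {
      warning("structure '", rule$name,
              "' vanished after removing already-claimed voxels")
      next
    }
    lab <- length(label_names) + 1L
    labels[grown] <- lab
    label_names <- c(label_names, stats::setNames(lab, rule$name))
    vox <- which(grown, arr.ind = TRUE) - 1L
    context[[rule$name]] <- list(centroid = colMeans(voxel_to_world(vox, geom)))
  }
  masks <- region_mask(labels, geom, label_names)
  for (nm in names(label_names))
    meshes[[nm]] <- extract_isosurface(masks, nm)
  structure(list(masks = masks, meshes = meshes,
                 centroids = lapply(context, `[[`, "centroid")),
            class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  cat("structure_set with", length(x$meshes), "structures:\n")
  for (nm in names(x$meshes))
    cat(sprintf("  %s: %d voxels, %d mesh faces\n", nm,
                sum(x$masks$labels == x$masks$label_names[[nm]]),
                nrow(x$meshes[[nm]]$faces)))
  invisible(x)
}

#' Read segmentation rules from a YAML config
#'
#' One block per structure; fields mirror [structure_rule()] arguments.
#' @param path YAML file.
#' @return named list of [structure_rule()]s.
#' @export
read_structure_rules <- function(path) {
  cfg <- yaml::read_yaml(path)
  rules <- lapply(names(cfg), function(nm) {
    b <- cfg[[nm]]
    structure_rule(nm,
                   intensity_window = as.numeric(b$intensity_window),
                   size_window = as.numeric(b$size_window),
                   shape_constraints = b$shape_constraints %||%
                     list(max_elongation = 3, min_solidity = 0.7),
                   location_prior = if (!is.null(b$location_prior))
                     list(ref = b$location_prior$ref,
                          offset = as.numeric(b$location_prior$offset),
                          box = as.numeric(b$location_prior$box)),
                   reliability_rank = b$reliability_rank %||% 1L,
                   contour_params = b$contour_params %||%
                     list(iterations = 40L, curvature = 2L),
                   slab = if (!is.null(b$slab)) as.numeric(b$slab))
  })
  stats::setNames(rules, names(cfg))
}
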