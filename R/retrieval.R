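## Geometric similarity between subjects and reference ranking.
##
## Subjects are compared by a weighted Euclidean distance over a feature
## vector of structure geometry: body volume/extents, mandible and body
## surface meshes (compared by ICP-aligned directional Hausdorff distance),
## the mandible-hyoid centroid offset, 2D hyoid-jugular and hyoid-spine
## offsets on the axial slice at the hyoid centroid, vertical
## skull-base/mandible/hyoid distances, and normalized centroid locations.
## The most similar reference subjects (ranking R_F) are the candidates
## expected to register best onto the query.

#' Minimum distance from a point to a triangle mesh
#'
#' Exact point-to-triangle distance (not vertex-only), minimised over all
#' faces.
#'
#' @param p length-3 point or n x 3 matrix (mm).
#' @param mesh a non-empty [surface_mesh()].
#' @return distance(s) in mm.
#' @export
point_to_mesh_distance <- function(p, mesh) {
  if (nrow(mesh$faces) == 0L) stop("mesh has no faces")
  one <- !is.matrix(p)
  if (one) p <- matrix(p, nrow = 1)
  d <- closest_point_on_mesh(p, mesh)$distance
  if (one) d[1] else d
}

#' ICP rigid alignment of points onto a mesh
#'
#' Iteratively matches each source point to its closest point on the target
#' mesh and solves the least-squares rigid motion (SVD/Kabsch), until the
#' RMS residual stops improving.  The residual trace is non-increasing.
#'
#' @param source_points n x 3 matrix (n >= 3, non-collinear), e.g. the
#'   vertices of a reference mesh.
#' @param target_mesh a [surface_mesh()].
#' @param iterations maximum ICP iterations.
#' @param tol relative residual-improvement stopping tolerance.
#' @return list with `rotation` (3 x 3), `translation` (length 3; the
#'   transform is `p %*% t(rotation) + translation`), `residual_trace` (RMS
#'   mm per iteration) and `transformed` (aligned source points).
#' @export
icp_align <- function(source_points, target_mesh, iterations = 200L,
                      tol = 1e-10) {
  P <- matrix(as.numeric(source_points), ncol = 3)
  if (nrow(P) < 3) stop("ICP needs at least 3 source points")
  sv <- svd(sweep(P, 2, colMeans(P)))$d
  if (sv[2] < 1e-9 * max(sv[1], 1))
    stop("degenerate (collinear) source point set")
  R <- diag(3); tvec <- c(0, 0, 0)
  cur <- P
  cp <- closest_point_on_mesh(cur, target_mesh)
  res <- sqrt(mean(cp$distance^2))
  trace <- res
  for (k in seq_len(iterations)) {
    # Kabsch: best rigid motion taking the ORIGINAL points onto the matches
    mu_p <- colMeans(P); mu_q <- colMeans(cp$point)
    H <- crossprod(sweep(P, 2, mu_p), sweep(cp$point, 2, mu_q))
    s <- svd(H)
    d <- sign(det(s$v %*% t(s$u)))
    R_new <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
    t_new <- mu_q - as.numeric(R_new %*% mu_p)
    new_pts <- P %*% t(R_new) + matrix(t_new, nrow(P), 3, byrow = TRUE)
    cp_new <- closest_point_on_mesh(new_pts, target_mesh)
    new_res <- sqrt(mean(cp_new$distance^2))
    if (new_res > res * (1 + 1e-12)) break
    R <- R_new; tvec <- t_new; cur <- new_pts
    improved <- res - new_res
    cp <- cp_new; res <- new_res
    trace <- c(trace, res)
    if (improved < tol * max(res, 1e-9)) break
  }
  list(rotation = R, translation = tvec, residual_trace = trace,
       transformed = cur)
}

#' Directional Hausdorff and mean surface distance between meshes
#'
#' Samples `n_samples` area-uniform points on the (optionally ICP-aligned)
#' reference mesh and measures exact point-to-mesh distances to the target
#' mesh; returns their maximum (directional Hausdorff, reference to target)
#' and mean, in mm.  Retrieval uses `prealign = TRUE` (shape comparison
#' independent of pose); evaluation of projected regions uses
#' `prealign = FALSE` (both meshes already share the target frame).
#'
#' @param S_R,S_T non-empty [surface_mesh()]es (reference, target).
#' @param prealign run [icp_align()] on `S_R`'s vertices first.
#' @param n_samples surface samples (default 2000).
#' @param seed integer seed for the area-uniform sampling.
#' @param symmetric also sample T against R and take the larger direction
#'   (off by default; the published measure is directional).
#' @return named numeric vector `c(hausdorff = , mean = )` in mm.
#' @export
hausdorff_mesh_distance <- function(S_R, S_T, prealign = FALSE,
                                    n_samples = 2000L, seed = 1L,
                                    symmetric = FALSE) {
  if (nrow(S_R$faces) == 0L || nrow(S_T$faces) == 0L)
    stop("hausdorff distance needs two non-empty meshes")
  R_use <- S_R
  if (prealign) {
    icp <- icp_align(S_R$vertices, S_T)
    R_use <- surface_mesh(icp$transformed, S_R$faces)
  }
  pts <- sample_mesh_points(R_use, n_samples, seed = seed)
  d <- point_to_mesh_distance(pts, S_T)
  out <- c(hausdorff = max(d), mean = mean(d))
  if (symmetric) {
    pts2 <- sample_mesh_points(S_T, n_samples, seed = seed + 1L)
    d2 <- point_to_mesh_distance(pts2, R_use)
    out <- pmax(out, c(hausdorff = max(d2), mean = mean(d2)))
  }
  out
}

mask_centroid <- function(mask, label) {
  label <- mask_label_of(mask, label)
  vox <- which(mask$labels == label, arr.ind = TRUE) - 1L
  if (!nrow(vox)) stop("empty region: label ", label)
  unname(colMeans(voxel_to_world(vox, mask$geometry)))
}

slice_centroid_2d <- function(mask, label, k) {
  label <- mask_label_of(mask, label)
  sl <- mask$labels[, , k] == label
  if (!any(sl)) {
    # fall back to the closest slice containing the label
    ks <- which(apply(mask$labels == label, 3, any))
    k <- ks[which.min(abs(ks - k))]
    sl <- mask$labels[, , k] == label
  }
  pix <- which(sl, arr.ind = TRUE) - 1L
  unname(mask$geometry$origin[1:2] +
           colMeans(pix) * mask$geometry$spacing[1:2])
}

#' Geometric feature vector of one subject
#'
#' @param structures a `structure_set` (or list with `masks` and `meshes`)
#'   containing at least mandible, hyoid, spine and one jugular structure.
#' @param body a [region_mask()] of the head-and-neck outer region (label 1
#'   or named `body`).
#' @param mesh_decimate target vertex count for the stored mandible/body
#'   meshes (subsampled surface meshes keep the mesh-distance features
#'   affordable; 0 keeps full meshes).
#' @return An object of class `subject_features`.
#' @export
extract_features <- function(structures, body, mesh_decimate = 600L) {
  masks <- structures$masks
  need <- c("mandible", "hyoid", "spine")
  missing <- setdiff(need, names(masks$label_names))
  if (length(missing))
    stop("missing required structure: ", paste(missing, collapse = ", "))
  jug <- intersect(c("jugular_left", "jugular_right", "jugular"),
                   names(masks$label_names))
  if (!length(jug)) stop("missing required structure: jugular")
  body_lab <- if ("body" %in% names(body$label_names)) "body" else
    body$label_names[[1]]
  vox_vol <- prod(body$geometry$spacing)
  body_vox <- which(body$labels == mask_label_of(body, body_lab),
                    arr.ind = TRUE) - 1L
  body_pts_min <- voxel_to_world(unname(apply(body_vox, 2, min)),
                                 body$geometry) - body$geometry$spacing / 2
  body_pts_max <- voxel_to_world(unname(apply(body_vox, 2, max)),
                                 body$geometry) + body$geometry$spacing / 2
  extents <- body_pts_max - body_pts_min
  cen <- list(mandible = mask_centroid(masks, "mandible"),
              hyoid = mask_centroid(masks, "hyoid"),
              spine = mask_centroid(masks, "spine"),
              jugular = mask_centroid(masks, jug[1]))
  hy_k <- round((cen$hyoid[3] - masks$geometry$origin[3]) /
                  masks$geometry$spacing[3]) + 1L
  hy_k <- min(max(hy_k, 1L), masks$geometry$dims[3])
  hy2 <- slice_centroid_2d(masks, "hyoid", hy_k)
  ju2 <- slice_centroid_2d(masks, jug[1], hy_k)
  sp2 <- slice_centroid_2d(masks, "spine", hy_k)
  norm_c <- function(c3) pmin(pmax((c3 - body_pts_min) / extents, 0), 1)
  body_mesh <- extract_isosurface(body, body_lab)
  dec <- function(mesh) {
    if (mesh_decimate <= 0 || nrow(mesh$vertices) <= mesh_decimate) return(mesh)
    decimate_mesh(mesh, mesh_decimate)
  }
  # skull-base proxy: the superior body-extent plane
  skull_z <- body_pts_max[3]
  structure(list(
    body_volume = nrow(body_vox) * vox_vol,
    body_extents = extents,
    mandible_mesh = dec(structures$meshes$mandible),
    body_mesh = dec(body_mesh),
    mandible_hyoid_offset = cen$mandible - cen$hyoid,
    hyoid_jugular_offset_2d = ju2 - hy2,
    hyoid_spine_offset_2d = sp2 - hy2,
    vertical_offsets = c(skull_mandible = skull_z - cen$mandible[3],
                         mandible_hyoid = cen$mandible[3] - cen$hyoid[3]),
    hyoid_norm = norm_c(cen$hyoid),
    mandible_norm = norm_c(cen$mandible)),
    class = "subject_features")
}

# crude area-preserving decimation: cluster vertices on a coarse grid
decimate_mesh <- function(mesh, target_vertices) {
  bb <- mesh_bbox(mesh)
  span <- pmax(bb[2, ] - bb[1, ], 1e-6)
  k <- max(2, ceiling((target_vertices)^(1 / 3)))
  repeat {
    cell <- span / k
    key <- floor(sweep(sweep(mesh$vertices, 2, bb[1, ]), 2, cell, `/`))
    id <- paste(key[, 1], key[, 2], key[, 3])
    uid <- !duplicated(id)
    if (sum(uid) >= target_vertices || k > 64) break
    k <- k + max(1, k %/% 4)
  }
  map <- match(id, id[uid])
  # representative vertex: centroid of each cluster
  V <- rowsum(mesh$vertices, map) / as.numeric(table(map))
  Fm <- matrix(map[mesh$faces], ncol = 3)
  keep <- Fm[, 1] != Fm[, 2] & Fm[, 2] != Fm[, 3] & Fm[, 1] != Fm[, 3]
  Fm <- Fm[keep, , drop = FALSE]
  # drop vertices whose faces all collapsed; they would sit off the surface
  used <- sort(unique(as.vector(Fm)))
  remap <- integer(nrow(V)); remap[used] <- seq_along(used)
  surface_mesh(V[used, , drop = FALSE], matrix(remap[Fm], ncol = 3))
}

#' Feature weights
#'
#' Weights range from 10 down to 0.1, heaviest first: hyoid-location
#' features, then the mandible mesh distance, then vertical skull-base /
#' mandible / hyoid distances, then outer-contour volume/extents, then the
#' rest.  The published account gives the range and this priority order;
#' the concrete values are this package's interpolation of it.
#'
#' @param ... named overrides of individual weights.
#' @return named numeric vector of per-feature weights.
#' @export
feature_weights <- function(...) {
  w <- c(hyoid_norm = 10, hyoid_jugular_offset_2d = 10,
         hyoid_spine_offset_2d = 10, mandible_hyoid_offset = 10,
         mandible_mesh = 5,
         vertical_offsets = 2,
         body_volume = 0.5, body_extents = 0.5, body_mesh = 0.5,
         mandible_norm = 0.1)
  ov <- c(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(w))
    if (length(bad)) stop("unknown feature weight: ", paste(bad, collapse = ", "))
    w[names(ov)] <- ov
  }
  if (any(w <= 0)) stop("feature weights must be positive")
  w
}

# per-feature scalar distances d_i between two feature vectors
feature_term_distances <- function(F_d, F_Q, n_mesh_samples = 800L,
                                   seed = 1L) {
  stopifnot(inherits(F_d, "subject_features"),
            inherits(F_Q, "subject_features"))
  mesh_d <- function(a, b)
    hausdorff_mesh_distance(a, b, prealign = TRUE,
                            n_samples = n_mesh_samples, seed = seed)[["hausdorff"]]
  # scalar features in cm / litre-like magnitudes so no single unit dominates
  c(body_volume = abs(F_d$body_volume - F_Q$body_volume) / 1e5,
    body_extents = sqrt(sum((F_d$body_extents - F_Q$body_extents)^2)) / 10,
    mandible_mesh = mesh_d(F_d$mandible_mesh, F_Q$mandible_mesh) / 10,
    body_mesh = mesh_d(F_d$body_mesh, F_Q$body_mesh) / 10,
    mandible_hyoid_offset =
      sqrt(sum((F_d$mandible_hyoid_offset - F_Q$mandible_hyoid_offset)^2)) / 10,
    hyoid_jugular_offset_2d =
      sqrt(sum((F_d$hyoid_jugular_offset_2d - F_Q$hyoid_jugular_offset_2d)^2)) / 10,
    hyoid_spine_offset_2d =
      sqrt(sum((F_d$hyoid_spine_offset_2d - F_Q$hyoid_spine_offset_2d)^2)) / 10,
    vertical_offsets =
      sqrt(sum((F_d$vertical_offsets - F_Q$vertical_offsets)^2)) / 10,
    hyoid_norm = sqrt(sum((F_d$hyoid_norm - F_Q$hyoid_norm)^2)),
    mandible_norm = sqrt(sum((F_d$mandible_norm - F_Q$mandible_norm)^2)))
}

#' Weighted Euclidean feature-space distance D_F
#'
#' `D_F = sqrt(sum_i w_i d_i^2)`: scalar features contribute absolute
#' differences, vector features Euclidean norms of differences, and mesh
#' features the ICP-aligned directional Hausdorff distance.  Non-negative
#' and zero when the scalar/vector features agree; the mesh term is
#' directional (model to query), a documented asymmetry.
#'
#' @param F_d,F_Q [extract_features()] results (model and query).
#' @param weights a [feature_weights()] vector.
#' @param n_mesh_samples surface samples for the mesh terms.
#' @param seed sampling seed.
#' @return `D_F` (scalar).
#' @export
feature_distance <- function(F_d, F_Q, weights = feature_weights(),
                             n_mesh_samples = 800L, seed = 1L) {
  d <- feature_term_distances(F_d, F_Q, n_mesh_samples, seed)
  if (!setequal(names(d), names(weights)))
    stop("feature schema mismatch between vectors and weights")
  sqrt(sum(weights[names(d)] * d^2))
}

#' Reference database record
#'
#' @param id reference subject identifier.
#' @param features a [extract_features()] result.
#' @param nodal_regions optional [region_mask()] of expert-drawn regions.
#' @param volume optional [volume_image()].
#' @export
reference_record <- function(id, features, nodal_regions = NULL,
                             volume = NULL) {
  structure(list(id = id, features = features,
                 nodal_regions = nodal_regions, volume = volume),
            class = "reference_record")
}

#' Rank reference subjects by feature-space distance (R_F)
#'
#' Sorted ascending by `D_F`; ties keep the database order (stable).
#'
#' @param query a [extract_features()] result for the query subject.
#' @param db non-empty list of [reference_record()]s.
#' @param weights a [feature_weights()] vector.
#' @param query_id optional identifier recorded in the result.
#' @inheritParams feature_distance
#' @return An object of class `ranked_references`: data.frame with columns
#'   `id`, `D_F`, `rank`.
#' @export
rank_references <- function(query, db, weights = feature_weights(),
                            query_id = NULL, n_mesh_samples = 800L,
                            seed = 1L) {
  if (!length(db)) stop("reference database is empty")
  DF <- vapply(db, function(rec)
    feature_distance(rec$features, query, weights,
                     n_mesh_samples = n_mesh_samples, seed = seed),
    numeric(1))
  ids <- vapply(db, `[[`, character(1), "id")
  ord <- order(DF)  # stable: ties keep input order
  out <- data.frame(id = ids[ord], D_F = DF[ord],
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  structure(out, class = c("ranked_references", "data.frame"),
            query_id = query_id)
}

#' @export
print.ranked_references <- function(x, ...) {
  qid <- attr(x, "query_id")
  cat("Reference ranking R_F", if (!is.null(qid)) paste0(" (query ", qid, ")"),
      ":\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
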