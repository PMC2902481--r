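#' Triangle surface mesh
#'
#' Vertices in world millimetres, faces as 1-based vertex-index triples.
#' Degenerate (zero-area) faces are dropped at construction.
#'
#' @param vertices n x 3 numeric matrix (mm).
#' @param faces m x 3 integer matrix of vertex indices.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  if (ncol(vertices) != 3L) stop("vertices must be n x 3")
  if (nrow(faces) > 0 &&
      (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  if (nrow(faces) > 0) {
    a <- vertices[faces[, 1], , drop = FALSE]
    e1 <- vertices[faces[, 2], , drop = FALSE] - a
    e2 <- vertices[faces[, 3], , drop = FALSE] - a
    cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    area2 <- sqrt(rowSums(cr^2))
    faces <- faces[area2 > 1e-12, , drop = FALSE]
  }
  structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  bb <- mesh_bbox(x)
  cat(sprintf("surface_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  cat(sprintf("  bbox [%.2f, %.2f] x [%.2f, %.2f] x [%.2f, %.2f] mm\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

#' Mesh summaries
#'
#' `mesh_bbox` returns the 2 x 3 min/max corner matrix, `mesh_area` the total
#' surface area (mm^2), and `mesh_volume` the enclosed volume (mm^3) by the
#' signed-tetrahedron sum (meaningful for closed, consistently wound meshes).
#'
#' @param mesh a [surface_mesh()].
#' @export
mesh_bbox <- function(mesh) {
  rbind(min = apply(mesh$vertices, 2, min), max = apply(mesh$vertices, 2, max))
}

face_cross <- function(mesh) {
  a <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  e1 <- mesh$vertices[mesh$faces[, 2], , drop = FALSE] - a
  e2 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE] - a
  cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
        e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
        e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
}

#' @rdname mesh_bbox
#' @export
mesh_area <- function(mesh) {
  sum(sqrt(rowSums(face_cross(mesh)^2))) / 2
}

#' @rdname mesh_bbox
#' @export
mesh_volume <- function(mesh) {
  a <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  ce <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  abs(sum(a[, 1] * (b[, 2] * ce[, 3] - b[, 3] * ce[, 2]) -
          a[, 2] * (b[, 1] * ce[, 3] - b[, 3] * ce[, 1]) +
          a[, 3] * (b[, 1] * ce[, 2] - b[, 2] * ce[, 1]))) / 6
}

#' Apply a rigid transform to mesh vertices
#'
#' @param mesh a [surface_mesh()].
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 mm vector.
#' @param center rotation centre (mm), default the origin.
#' @export
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0),
                           center = c(0, 0, 0)) {
  v <- sweep(mesh$vertices, 2, center)
  v <- v %*% t(rotation)
  v <- sweep(sweep(v, 2, center, `+`), 2, translation, `+`)
  surface_mesh(v, mesh$faces)
}

#' Area-uniform random points on a mesh surface
#'
#' Faces are drawn with probability proportional to area, then a uniform
#' point inside each drawn triangle.  Deterministic given `seed`.
#'
#' @param mesh a [surface_mesh()].
#' @param n number of samples.
#' @param seed integer seed.
#' @return n x 3 matrix of mm points.
#' @export
sample_mesh_points <- function(mesh, n, seed = 1L) {
  if (nrow(mesh$faces) == 0L) stop("cannot sample an empty mesh")
  areas <- sqrt(rowSums(face_cross(mesh)^2)) / 2
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  fi <- sample.int(nrow(mesh$faces), n, replace = TRUE, prob = areas)
  u <- stats::runif(n); v <- stats::runif(n)
  flip <- u + v > 1
  u[flip] <- 1 - u[flip]; v[flip] <- 1 - v[flip]
  a <- mesh$vertices[mesh$faces[fi, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$faces[fi, 2], , drop = FALSE]
  ce <- mesh$vertices[mesh$faces[fi, 3], , drop = FALSE]
  a + u * (b - a) + v * (ce - a)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Closest points on a mesh
#'
#' Exact point-to-triangle distances (projection onto the face plane with
#' clamping to edges), minimised over all faces.  Returns both the distances
#' and the closest surface points, which the surface-correspondence solver
#' and ICP both need.
#'
#' @param points n x 3 matrix of query points (mm).
#' @param mesh a [surface_mesh()].
#' @return list with `distance` (length n) and `point` (n x 3).
#' @export
closest_point_on_mesh <- function(points, mesh) {
  if (nrow(mesh$faces) == 0L) stop("mesh has no faces")
  points <- matrix(as.numeric(points), ncol = 3)
  n <- nrow(points)
  best_d2 <- rep(Inf, n)
  best_pt <- matrix(0, n, 3)
  V <- mesh$vertices
  F_ <- mesh$faces
  nf <- nrow(F_)
  cent <- (V[F_[, 1], , drop = FALSE] + V[F_[, 2], , drop = FALSE] +
           V[F_[, 3], , drop = FALSE]) / 3
  rad <- sqrt(pmax(
    rowSums((V[F_[, 1], , drop = FALSE] - cent)^2),
    pmax(rowSums((V[F_[, 2], , drop = FALSE] - cent)^2),
         rowSums((V[F_[, 3], , drop = FALSE] - cent)^2))))
  cc2 <- rowSums(cent^2)
  chunk <- max(1L, floor(4e6 / nf))
  for (s in seq(1L, n, by = chunk)) {
    ii <- s:min(n, s + chunk - 1L)
    P <- points[ii, , drop = FALSE]
    # distances to face centroids: candidate faces per point are those whose
    # lower bound (centroid distance - circumradius) beats the per-point
    # upper bound (min over faces of centroid distance + circumradius)
    D <- sqrt(pmax(outer(rowSums(P^2), cc2, `+`) - 2 * P %*% t(cent), 0))
    ub <- apply(sweep(D, 2, rad, `+`), 1, min)
    cand <- which(sweep(D, 2, rad) <= ub + 1e-9, arr.ind = TRUE)
    o <- order(cand[, 2])
    cand <- cand[o, , drop = FALSE]
    runs <- rle(cand[, 2])
    pos <- 1L
    loc_d2 <- rep(Inf, length(ii))
    loc_pt <- matrix(0, length(ii), 3)
    for (r in seq_along(runs$values)) {
      f <- runs$values[r]
      rows <- cand[pos:(pos + runs$lengths[r] - 1L), 1]
      pos <- pos + runs$lengths[r]
      res <- point_triangle_closest(P[rows, , drop = FALSE],
                                    V[F_[f, 1], ], V[F_[f, 2], ], V[F_[f, 3], ])
      upd <- res$d2 < loc_d2[rows]
      loc_d2[rows[upd]] <- res$d2[upd]
      loc_pt[rows[upd], ] <- res$pt[upd, , drop = FALSE]
    }
    best_d2[ii] <- loc_d2
    best_pt[ii, ] <- loc_pt
  }
  list(distance = sqrt(pmax(best_d2, 0)), point = best_pt)
}

# closest point on one triangle (a,b,c) for many query points p (vectorised)
point_triangle_closest <- function(p, a, b, cc) {
  e1 <- b - a; e2 <- cc - a
  n <- nrow(p)
  d <- sweep(p, 2, a)
  d11 <- sum(e1 * e1); d12 <- sum(e1 * e2); d22 <- sum(e2 * e2)
  q1 <- d %*% e1; q2 <- d %*% e2
  det <- d11 * d22 - d12 * d12
  if (det < 1e-300) {  # degenerate triangle: fall back to segment a-b
    t <- pmin(pmax(q1 / max(d11, 1e-300), 0), 1)
    pt <- sweep(outer(as.vector(t), e1), 2, a, `+`)
    return(list(d2 = rowSums((p - pt)^2), pt = pt))
  }
  u <- (d22 * q1 - d12 * q2) / det
  v <- (d11 * q2 - d12 * q1) / det
  inside <- u >= 0 & v >= 0 & u + v <= 1
  pt <- matrix(0, n, 3)
  if (any(inside)) {
    pt[inside, ] <- sweep(outer(as.vector(u[inside]), e1) +
                          outer(as.vector(v[inside]), e2), 2, a, `+`)
  }
  out <- which(!inside)
  if (length(out)) {
    po <- p[out, , drop = FALSE]
    seg <- function(s0, sv) {
      len2 <- sum(sv * sv)
      t <- if (len2 > 0) pmin(pmax(sweep(po, 2, s0) %*% sv / len2, 0), 1)
           else matrix(0, nrow(po), 1)
      sweep(outer(as.vector(t), sv), 2, s0, `+`)
    }
    p1 <- seg(a, e1); p2 <- seg(a, e2); p3 <- seg(b, cc - b)
    d1 <- rowSums((po - p1)^2); d2_ <- rowSums((po - p2)^2)
    d3 <- rowSums((po - p3)^2)
    pick <- cbind(d1, d2_, d3)
    w <- max.col(-pick, ties.method = "first")
    sel <- rbind(p1, p2, p3)[(w - 1L) * length(out) + seq_along(out), , drop = FALSE]
    pt[out, ] <- sel
  }
  list(d2 = rowSums((p - pt)^2), pt = pt)
}

#' Extract the boundary surface of a labelled region
#'
#' Emits the closed voxel-boundary surface of one label: every face between a
#' voxel carrying the label and a background/other-label voxel becomes two
#' consistently wound triangles, with vertices at voxel corners in world mm.
#' The enclosed volume of the resulting mesh equals the voxel count times the
#' voxel volume exactly.
#'
#' @param mask a [region_mask()].
#' @param label integer label or region name present in the mask.
#' @return A [surface_mesh()].
#' @export
extract_isosurface <- function(mask, label) {
  label <- mask_label_of(mask, label)
  B <- mask$labels == label
  if (!any(B)) stop("empty region: label ", label, " absent from mask")
  d <- dim(B)
  geom <- mask$geometry
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- B
  quads <- list(); qi <- 0L
  # for each axis and direction collect exposed faces
  shifts <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                 c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (s in shifts) {
    nb <- pad[(2:(d[1] + 1)) + s[1], (2:(d[2] + 1)) + s[2],
              (3:(d[3] + 2)) - 1 + s[3], drop = FALSE]
    dim(nb) <- d
    idx <- which(B & !nb, arr.ind = TRUE) - 1L  # 0-based voxel indices
    if (!nrow(idx)) next
    qi <- qi + 1L
    quads[[qi]] <- list(idx = idx, s = s)
  }
  verts <- list(); faces <- list()
  nv <- 0L
  h <- geom$spacing
  for (q in quads) {
    idx <- q$idx; s <- q$s
    ctr <- voxel_to_world(idx, geom)
    ax <- which(s != 0)
    o1 <- c(2, 1, 1)[ax]; o2 <- c(3, 3, 2)[ax]  # the two in-plane axes
    face_c <- ctr
    face_c[, ax] <- face_c[, ax] + s[ax] * h[ax] / 2
    mk <- function(d1, d2) {
      v <- face_c
      v[, o1] <- v[, o1] + d1 * h[o1] / 2
      v[, o2] <- v[, o2] + d2 * h[o2] / 2
      v
    }
    v1 <- mk(-1, -1); v2 <- mk(1, -1); v3 <- mk(1, 1); v4 <- mk(-1, 1)
    k <- nrow(idx)
    base <- nv + (seq_len(k) - 1L) * 4L
    # winding: (o1 x o2) = +ax for the cyclic cases; flip when needed
    pos_norm <- (ax == 1 && o1 == 2 && o2 == 3) ||
                (ax == 2 && o1 == 1 && o2 == 3) ||  # x cross z = -y
                (ax == 3 && o1 == 1 && o2 == 2)
    cross_sign <- c(1, -1, 1)[ax]  # sign of (e_o1 x e_o2) . e_ax
    outward <- s[ax]
    if (cross_sign * outward > 0) {
      f1 <- cbind(base + 1L, base + 2L, base + 3L)
      f2 <- cbind(base + 1L, base + 3L, base + 4L)
    } else {
      f1 <- cbind(base + 1L, base + 3L, base + 2L)
      f2 <- cbind(base + 1L, base + 4L, base + 3L)
    }
    verts[[length(verts) + 1L]] <-
      matrix(rbind(t(v1), t(v2), t(v3), t(v4)), ncol = 3, byrow = TRUE)
    faces[[length(faces) + 1L]] <- rbind(f1, f2)
    nv <- nv + 4L * k
  }
  V <- do.call(rbind, verts)
  F_ <- do.call(rbind, faces)
  # merge duplicate corner vertices
  key <- paste(round(V[, 1] * 1e6), round(V[, 2] * 1e6), round(V[, 3] * 1e6))
  uk <- !duplicated(key)
  map <- match(key, key[uk])
  V2 <- V[uk, , drop = FALSE]
  F2 <- matrix(map[F_], ncol = 3)
  surface_mesh(V2, F2)
}

#' Read and write triangle meshes (ASCII PLY / STL)
#'
#' @param mesh a [surface_mesh()].
#' @param path file path ending in `.ply` or `.stl`.
#' @export
write_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "ply") {
    con <- file(path, "w")
    on.exit(close(con), add = TRUE)
    writeLines(c("ply", "format ascii 1.0",
                 paste("element vertex", nrow(mesh$vertices)),
                 "property float x", "property float y", "property float z",
                 paste("element face", nrow(mesh$faces)),
                 "property list uchar int vertex_indices",
                 "end_header"), con)
    writeLines(apply(format(mesh$vertices, digits = 9, trim = TRUE,
                            scientific = FALSE), 1, paste, collapse = " "), con)
    writeLines(paste(3, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                     mesh$faces[, 3] - 1L), con)
  } else if (ext == "stl") {
    con <- file(path, "w")
    on.exit(close(con), add = TRUE)
    nrm <- face_cross(mesh)
    len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
    nrm <- nrm / len
    writeLines("solid mesh", con)
    for (f in seq_len(nrow(mesh$faces))) {
      writeLines(c(sprintf("facet normal %g %g %g",
                           nrm[f, 1], nrm[f, 2], nrm[f, 3]),
                   "  outer loop",
                   sprintf("    vertex %g %g %g",
                           mesh$vertices[mesh$faces[f, ], 1],
                           mesh$vertices[mesh$faces[f, ], 2],
                           mesh$vertices[mesh$faces[f, ], 3]),
                   "  endloop", "endfacet"), con)
    }
    writeLines("endsolid mesh", con)
  } else stop("unsupported mesh format: ", path)
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("no such mesh file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "ply") {
    lines <- readLines(path)
    if (lines[1] != "ply" || !grepl("ascii", lines[2]))
      stop("only ASCII PLY supported: ", path)
    nv <- as.integer(sub("element vertex ", "",
                         grep("^element vertex", lines, value = TRUE)[1]))
    nf <- as.integer(sub("element face ", "",
                         grep("^element face", lines, value = TRUE)[1]))
    hend <- which(lines == "end_header")[1]
    vl <- lines[(hend + 1):(hend + nv)]
    V <- matrix(as.numeric(unlist(strsplit(trimws(vl), "\\s+"))),
                ncol = 3, byrow = TRUE)
    fl <- lines[(hend + nv + 1):(hend + nv + nf)]
    Fm <- matrix(as.integer(unlist(strsplit(trimws(fl), "\\s+"))),
                 ncol = 4, byrow = TRUE)
    if (any(Fm[, 1] != 3L)) stop("non-triangular PLY faces in ", path)
    surface_mesh(V, Fm[, 2:4] + 1L)
  } else if (ext == "stl") {
    lines <- readLines(path)
    vl <- grep("^\\s*vertex", lines, value = TRUE)
    V <- matrix(as.numeric(unlist(lapply(strsplit(trimws(vl), "\\s+"),
                                         function(x) x[2:4]))),
                ncol = 3, byrow = TRUE)
    nf <- nrow(V) / 3
    # merge identical vertices
    key <- paste(V[, 1], V[, 2], V[, 3])
    uk <- !duplicated(key)
    map <- match(key, key[uk])
    surface_mesh(V[uk, , drop = FALSE],
                 matrix(map, ncol = 3, byrow = TRUE))
  } else stop("unsupported mesh format: ", path)
}
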