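# Shared fixtures and independent oracles, all built in code.

# icosphere: subdivided icosahedron projected onto a sphere
make_sphere_mesh <- function(radius = 10, center = c(0, 0, 0), subdiv = 3) {
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  F_ <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    nv <- nrow(V)
    edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    mids <- new.env()
    newV <- V
    getmid <- function(a, b) {
      k <- edge_key(a, b)
      if (!is.null(mids[[k]])) return(mids[[k]])
      m <- (V[a, ] + V[b, ]) / 2
      newV <<- rbind(newV, m)
      mids[[k]] <- nrow(newV)
      nrow(newV)
    }
    newF <- matrix(0L, 0, 3)
    for (f in seq_len(nrow(F_))) {
      a <- F_[f, 1]; b <- F_[f, 2]; cc <- F_[f, 3]
      ab <- getmid(a, b); bc <- getmid(b, cc); ca <- getmid(cc, a)
      newF <- rbind(newF, c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc),
                    c(ab, bc, ca))
    }
    V <- newV; F_ <- newF
  }
  V <- V / sqrt(rowSums(V^2)) * radius
  V <- sweep(V, 2, center, `+`)
  surface_mesh(V, F_)
}

# axis-aligned box mask inside a given geometry (0-based voxel index bounds,
# inclusive)
make_box_mask <- function(dims, lo, hi, spacing = c(1, 1, 1),
                          name = "box") {
  g <- volume_geometry(dims, spacing)
  lab <- array(0L, dims)
  lab[(lo[1]:hi[1]) + 1, (lo[2]:hi[2]) + 1, (lo[3]:hi[3]) + 1] <- 1L
  region_mask(lab, g, stats::setNames(1L, name))
}

# independent exact point-triangle distance: minimize the quadratic
# |a + u e1 + v e2 - p|^2 over the simplex by enumerating the unconstrained
# stationary point, the three edge minimizers and the three vertices
oracle_point_triangle <- function(p, a, b, cc) {
  e1 <- b - a; e2 <- cc - a
  cand <- list(a, b, cc)
  G <- rbind(c(sum(e1 * e1), sum(e1 * e2)), c(sum(e1 * e2), sum(e2 * e2)))
  rhs <- c(sum(e1 * (p - a)), sum(e2 * (p - a)))
  uv <- tryCatch(solve(G, rhs), error = function(e) c(-1, -1))
  if (uv[1] >= 0 && uv[2] >= 0 && sum(uv) <= 1)
    cand <- c(cand, list(a + uv[1] * e1 + uv[2] * e2))
  seg_min <- function(s0, sv) {
    t <- sum(sv * (p - s0)) / max(sum(sv * sv), 1e-300)
    s0 + min(max(t, 0), 1) * sv
  }
  cand <- c(cand, list(seg_min(a, e1), seg_min(a, e2), seg_min(b, cc - b)))
  min(vapply(cand, function(q) sqrt(sum((p - q)^2)), numeric(1)))
}

oracle_point_mesh <- function(p, mesh) {
  min(vapply(seq_len(nrow(mesh$faces)), function(f)
    oracle_point_triangle(p, mesh$vertices[mesh$faces[f, 1], ],
                          mesh$vertices[mesh$faces[f, 2], ],
                          mesh$vertices[mesh$faces[f, 3], ]),
    numeric(1)))
}

# brute-force tensor-product B-spline field evaluation over ALL stored
# control points (ghost weights folded onto the clamped boundary indices)
oracle_bspline_field <- function(x, grid) {
  bs <- function(t) c((1 - t)^3 / 6, (3 * t^3 - 6 * t^2 + 4) / 6,
                      (-3 * t^3 + 3 * t^2 + 3 * t + 1) / 6, t^3 / 6)
  r <- grid$resolution
  u <- (x - grid$origin) / grid$spacing
  out <- c(0, 0, 0)
  wts <- lapply(1:3, function(a) {
    ia <- min(floor(u[a]), r[a] - 1)
    w <- numeric(r[a])
    ww <- bs(u[a] - ia)
    for (dd in 0:3) {
      tgt <- min(max(ia + dd - 1, 0), r[a] - 1) + 1
      w[tgt] <- w[tgt] + ww[dd + 1]
    }
    w
  })
  for (i in seq_len(r[1])) for (j in seq_len(r[2])) for (k in seq_len(r[3])) {
    w <- wts[[1]][i] * wts[[2]][j] * wts[[3]][k]
    if (w != 0) out <- out + w * grid$coefficients[i, j, k, ]
  }
  out
}

# small fast phantom used across tests
small_phantom_spec <- function(noise_sd = 0, seed = 1L)
  default_phantom_spec(dims = c(48, 48, 48), spacing = c(4, 4, 4),
                       noise_sd = noise_sd, seed = seed)
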