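## Rigid + cubic B-spline free-form deformation transform model.
##
## The deformation lives on a sparse uniform control grid over the image
## extent.  With resolution rho (control points per axis) the grid spacing is
## h_d = (q_d * voxel_spacing_d) / rho_d, control point (l,m,n) sits at
## origin + (l*h_x, m*h_y, n*h_z), and the dense field is the tensor-product
## cubic B-spline interpolation of the per-control-point coefficient
## vectors.  Outside indices are handled by replicating the boundary
## coefficients (the "ghost ring"), so the spline support covers the whole
## image extent including the corners.

# uniform cubic B-spline basis, t in [0,1], four weights for indices
# i0-1, i0, i0+1, i0+2
bspline_weights <- function(t) {
  t2 <- t * t; t3 <- t2 * t
  cbind((1 - t)^3 / 6,
        (3 * t3 - 6 * t2 + 4) / 6,
        (-3 * t3 + 3 * t2 + 3 * t + 1) / 6,
        t3 / 6)
}

#' Rigid transform parameters
#'
#' Euler angles applied z-y-x (the first angle is the in-plane/axial
#' rotation), a translation in mm, and the rotation centre (by convention the
#' centre of the reference volume).
#'
#' @param angles numeric length-3, radians.
#' @param translation numeric length-3, mm.
#' @param center rotation centre, mm.
#' @return An object of class `rigid_parameters`.
#' @export
rigid_parameters <- function(angles = c(0, 0, 0), translation = c(0, 0, 0),
                             center = c(0, 0, 0)) {
  stopifnot(length(angles) == 3, length(translation) == 3, length(center) == 3)
  structure(list(angles = as.numeric(angles),
                 translation = as.numeric(translation),
                 center = as.numeric(center)),
            class = "rigid_parameters")
}

#' Rotation matrix from Euler angles (z-y-x order)
#'
#' @param angles numeric length-3 (radians); the first rotates about z, the
#'   second about y, the third about x; right-handed.
#' @return 3 x 3 orthonormal matrix with determinant +1.
#' @export
euler_rotation <- function(angles) {
  cz <- cos(angles[1]); sz <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cx <- cos(angles[3]); sx <- sin(angles[3])
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Rz %*% Ry %*% Rx
}

apply_rigid <- function(points, rigid) {
  R <- euler_rotation(rigid$angles)
  p <- sweep(points, 2, rigid$center)
  p <- p %*% t(R)
  sweep(sweep(p, 2, rigid$center, `+`), 2, rigid$translation, `+`)
}

#' Build a zero-coefficient B-spline control grid
#'
#' Grid spacing per axis is image extent divided by the resolution; the grid
#' covers the whole extent (boundary coefficients are replicated outward so
#' the cubic support is defined everywhere in the image).
#'
#' @param resolution integer length-3, control points per axis (>= 4 each;
#'   cubic support needs four points).
#' @param geometry the [volume_geometry()] the grid spans.
#' @return An object of class `control_grid` with zero coefficients.
#' @export
#' @examples
#' g <- volume_geometry(c(150, 150, 110))
#' cg <- build_control_grid(c(15, 15, 11), g)
#' n_control_points(cg)  # 2475
build_control_grid <- function(resolution, geometry) {
  resolution <- as.integer(resolution)
  if (length(resolution) != 3L || any(resolution < 4L))
    stop("control-grid resolution must be >= 4 per axis (cubic support)")
  extent <- geometry_extent(geometry)
  spacing <- extent / resolution
  # anchor at the voxel bounding-box corner (half a voxel before the first
  # voxel centre) so every voxel centre and voxel corner is inside support
  structure(list(resolution = resolution,
                 spacing = spacing,
                 origin = geometry$origin - geometry$spacing / 2,
                 geometry = geometry,
                 coefficients = array(0, c(resolution, 3L))),
            class = "control_grid")
}

#' @rdname build_control_grid
#' @param grid a `control_grid`.
#' @export
n_control_points <- function(grid) prod(grid$resolution)

#' World positions of the control points
#'
#' @param grid a `control_grid`.
#' @return (prod(resolution)) x 3 matrix in array order (first axis fastest).
#' @export
control_point_positions <- function(grid) {
  r <- grid$resolution
  idx <- cbind(
    rep.int(seq_len(r[1]) - 1L, r[2] * r[3]),
    rep.int(rep(seq_len(r[2]) - 1L, each = r[1]), r[3]),
    rep(seq_len(r[3]) - 1L, each = r[1] * r[2]))
  sweep(sweep(idx, 2, grid$spacing, `*`), 2, grid$origin, `+`)
}

#' Sparse B-spline basis matrix at arbitrary points
#'
#' Row i holds the (up to 64) tensor-product cubic B-spline weights of point
#' i over the control points; out-of-range support indices are folded onto
#' the replicated boundary coefficients.  The dense deformation at the points
#' is then `W %*% matrix(grid$coefficients, ncol = 3)`.
#'
#' @param points n x 3 matrix of world-mm points inside the grid support.
#' @param grid a `control_grid`.
#' @param clamp if `TRUE`, points outside the support are clamped onto it
#'   (constant extension) instead of raising an error.
#' @return a `dgCMatrix` of dimension n x prod(resolution).
#' @export
deformation_basis_matrix <- function(points, grid, clamp = FALSE) {
  points <- matrix(as.numeric(points), ncol = 3)
  r <- grid$resolution
  u <- sweep(sweep(points, 2, grid$origin), 2, grid$spacing, `/`)
  if (!clamp &&
      (any(u < -1e-9) || any(sweep(u, 2, as.numeric(r), `-`) > 1e-9)))
    stop("point outside control-grid support")
  n <- nrow(points)
  i0 <- w <- vector("list", 3)
  for (a in 1:3) {
    ua <- pmin(pmax(u[, a], 0), r[a])
    ia <- pmin(floor(ua), r[a] - 1)
    i0[[a]] <- ia
    w[[a]] <- bspline_weights(ua - ia)
  }
  rows <- rep.int(seq_len(n), 64L)
  jj <- numeric(n * 64L); xx <- numeric(n * 64L)
  pos <- 1L
  for (dz in 0:3) {
    iz <- pmin(pmax(i0[[3]] + dz - 1, 0), r[3] - 1)
    for (dy in 0:3) {
      iy <- pmin(pmax(i0[[2]] + dy - 1, 0), r[2] - 1)
      wyz <- w[[2]][, dy + 1] * w[[3]][, dz + 1]
      for (dx in 0:3) {
        ix <- pmin(pmax(i0[[1]] + dx - 1, 0), r[1] - 1)
        idx <- ix + r[1] * (iy + r[2] * iz) + 1
        jj[pos:(pos + n - 1L)] <- idx
        xx[pos:(pos + n - 1L)] <- w[[1]][, dx + 1] * wyz
        pos <- pos + n
      }
    }
  }
  Matrix::sparseMatrix(i = rows, j = jj, x = xx,
                       dims = c(n, prod(r)))
}

#' Evaluate the B-spline deformation field
#'
#' Tensor-product cubic B-spline interpolation of the coefficient field at
#' arbitrary points inside the grid support.
#'
#' @param points length-3 vector or n x 3 matrix of world-mm points.
#' @param grid a `control_grid`.
#' @param clamp passed to [deformation_basis_matrix()].
#' @return deformation offsets in mm, same shape as `points`.
#' @export
evaluate_deformation <- function(points, grid, clamp = FALSE) {
  one <- !is.matrix(points)
  if (one) points <- matrix(points, nrow = 1)
  W <- deformation_basis_matrix(points, grid, clamp = clamp)
  D <- as.matrix(W %*% matrix(grid$coefficients, ncol = 3))
  if (one) as.numeric(D) else D
}

#' Interpolating spline coefficients from prescribed control-point values
#'
#' Solves the separable tridiagonal interpolation system so that
#' `evaluate_deformation` reproduces the prescribed values exactly at every
#' control-point location (boundary handled by replicated coefficients).
#'
#' @param values prod(resolution) x 3 matrix (or array resolution x 3) of
#'   deformation values at the control points, array order.
#' @param grid a `control_grid` (its coefficients are ignored).
#' @return a new `control_grid` with interpolating coefficients.
#' @export
fit_coefficients_from_values <- function(values, grid) {
  r <- grid$resolution
  v <- array(as.numeric(values), c(r, 3L))
  solve1d <- function(m) {
    # interpolation matrix: v_j = (c_{j-1} + 4 c_j + c_{j+1}) / 6 with
    # replicated end coefficients
    A <- diag(4 / 6, m)
    for (j in seq_len(m - 1)) { A[j, j + 1] <- 1 / 6; A[j + 1, j] <- 1 / 6 }
    A[1, 1] <- 5 / 6; A[m, m] <- 5 / 6
    solve(A)
  }
  inv <- lapply(1:3, function(a) solve1d(r[a]))
  out <- array(0, c(r, 3L))
  for (comp in 1:3) {
    x <- v[, , , comp]
    # axis 1
    x <- array(inv[[1]] %*% matrix(x, nrow = r[1]), c(r[1], r[2], r[3]))
    # axis 2
    xp <- aperm(x, c(2, 1, 3))
    xp <- array(inv[[2]] %*% matrix(xp, nrow = r[2]), c(r[2], r[1], r[3]))
    x <- aperm(xp, c(2, 1, 3))
    # axis 3
    xp <- aperm(x, c(3, 1, 2))
    xp <- array(inv[[3]] %*% matrix(xp, nrow = r[3]), c(r[3], r[1], r[2]))
    out[, , , comp] <- aperm(xp, c(2, 3, 1))
  }
  grid$coefficients <- out
  grid
}

#' Refine a control grid to a finer resolution
#'
#' Chooses fine-grid coefficients so the fine deformation field reproduces
#' the coarse field: the coarse field is sampled on a grid twice as dense as
#' the fine control points and the fine coefficients are the least-squares
#' fit to those samples.  (A plain interpolation of the coarse field at the
#' fine control points is slightly less faithful between control points for
#' non-nested resolutions; the dense fit keeps the field discrepancy around
#' a percent of the coefficient RMS.)
#'
#' @param coarse a `control_grid`.
#' @param fine_resolution integer length-3, >= the coarse resolution per axis.
#' @return a `control_grid` at the finer resolution.
#' @export
refine_grid <- function(coarse, fine_resolution) {
  fine_resolution <- as.integer(fine_resolution)
  if (any(fine_resolution < coarse$resolution))
    stop("fine resolution must be >= coarse resolution per axis")
  fine <- build_control_grid(fine_resolution, coarse$geometry)
  ns <- fine_resolution * 2L
  sg <- volume_geometry(ns, geometry_extent(coarse$geometry) / ns,
                        coarse$geometry$origin)
  pts <- voxel_center_grid(sg)
  W <- deformation_basis_matrix(pts, fine, clamp = TRUE)
  d <- evaluate_deformation(pts, coarse, clamp = TRUE)
  coef <- as.matrix(Matrix::solve(Matrix::crossprod(W),
                                  Matrix::crossprod(W, d)))
  fine$coefficients <- array(coef, c(fine_resolution, 3L))
  fine
}

#' Combined rigid + FFD transform parameters
#'
#' The full parameter vector is the 6 rigid parameters followed by the
#' 3 * prod(resolution) deformation coefficients.
#'
#' @param rigid a [rigid_parameters()].
#' @param grid a `control_grid`.
#' @return An object of class `transform_parameters`.
#' @export
transform_parameters <- function(rigid, grid) {
  stopifnot(inherits(rigid, "rigid_parameters"), inherits(grid, "control_grid"))
  structure(list(rigid = rigid, grid = grid), class = "transform_parameters")
}

#' @export
print.transform_parameters <- function(x, ...) {
  cat(sprintf("transform_parameters: angles (%.4f, %.4f, %.4f) rad, translation (%.2f, %.2f, %.2f) mm\n",
              x$rigid$angles[1], x$rigid$angles[2], x$rigid$angles[3],
              x$rigid$translation[1], x$rigid$translation[2],
              x$rigid$translation[3]))
  cat(sprintf("  control grid %d x %d x %d (%d points), coefficient RMS %.3f mm\n",
              x$grid$resolution[1], x$grid$resolution[2], x$grid$resolution[3],
              n_control_points(x$grid), sqrt(mean(x$grid$coefficients^2))))
  invisible(x)
}

#' Apply the full transform to points
#'
#' `g(x) = R (x - x_C) + x_C + T + D(x)`: rigid motion about the centre,
#' translation, then the additive B-spline deformation evaluated at x.
#'
#' @param points length-3 vector or n x 3 matrix (mm).
#' @param params a [transform_parameters()].
#' @return transformed points, same shape.
#' @export
transform_point <- function(points, params) {
  one <- !is.matrix(points)
  p <- matrix(as.numeric(points), ncol = 3)
  out <- apply_rigid(p, params$rigid) + evaluate_deformation(p, params$grid)
  if (one) as.numeric(out) else out
}

#' Serialize / restore transform parameters (structured text)
#'
#' @param params a [transform_parameters()].
#' @param path JSON file path.
#' @export
write_transform <- function(params, path) {
  obj <- list(
    rigid = list(angles = params$rigid$angles,
                 translation = params$rigid$translation,
                 center = params$rigid$center),
    grid = list(resolution = params$grid$resolution,
                spacing = params$grid$spacing,
                origin = params$grid$origin,
                dims = params$grid$geometry$dims,
                voxel_spacing = params$grid$geometry$spacing,
                geometry_origin = params$grid$geometry$origin,
                coefficients = as.numeric(params$grid$coefficients)))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  geom <- volume_geometry(obj$grid$dims, obj$grid$voxel_spacing,
                          obj$grid$geometry_origin)
  grid <- build_control_grid(obj$grid$resolution, geom)
  grid$coefficients <- array(obj$grid$coefficients,
                             c(grid$resolution, 3L))
  transform_parameters(
    rigid_parameters(obj$rigid$angles, obj$rigid$translation,
                     obj$rigid$center),
    grid)
}
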