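# Rigid + cubic B-spline free-form deformation transform model.

test_that("control grid resolution gives the printed point count and spacing", {
  g <- volume_geometry(c(150, 150, 110))
  cg <- build_control_grid(c(15, 15, 11), g)
  expect_identical(n_control_points(cg), 2475)
  expect_equal(cg$spacing, c(10, 10, 10))
  expect_error(build_control_grid(c(3, 4, 4), g), "resolution")
})

test_that("zero coefficients give a zero field and constant coefficients a constant field (partition of unity)", {
  g <- volume_geometry(c(40, 40, 30), c(1.5, 1.5, 2))
  cg <- build_control_grid(c(6, 6, 5), g)
  set.seed(1)
  pts <- cbind(runif(50, 0, 58), runif(50, 0, 58), runif(50, 0, 58))
  expect_equal(evaluate_deformation(pts, cg), matrix(0, 50, 3))
  cg$coefficients[] <- -3.25
  expect_equal(evaluate_deformation(pts, cg),
               matrix(-3.25, 50, 3), tolerance = 1e-12)
})

test_that("spline evaluation matches the full-summation oracle over all control points", {
  g <- volume_geometry(c(60, 60, 60))
  cg <- build_control_grid(c(6, 6, 6), g)
  set.seed(2)
  cg$coefficients <- array(rnorm(6^3 * 3), c(6, 6, 6, 3))
  pts <- cbind(runif(25, 0, 59), runif(25, 0, 59), runif(25, 0, 59))
  D <- evaluate_deformation(pts, cg)
  for (i in seq_len(nrow(pts)))
    expect_equal(D[i, ], oracle_bspline_field(pts[i, ], cg),
                 tolerance = 1e-10)
})

test_that("points outside the grid support are rejected unless clamped", {
  g <- volume_geometry(c(20, 20, 20))
  cg <- build_control_grid(c(4, 4, 4), g)
  expect_error(evaluate_deformation(c(25, 5, 5), cg), "outside")
  expect_silent(evaluate_deformation(c(25, 5, 5), cg, clamp = TRUE))
})

test_that("the full transform composes rigid motion and additive deformation", {
  g <- volume_geometry(c(60, 60, 60))
  cg <- build_control_grid(c(6, 6, 6), g)
  idp <- transform_parameters(rigid_parameters(), cg)
  set.seed(3)
  pts <- matrix(runif(30, 5, 55), ncol = 3)
  expect_equal(transform_point(pts, idp), pts)

  tp <- transform_parameters(rigid_parameters(translation = c(5, 0, 0)), cg)
  expect_equal(transform_point(pts, tp), sweep(pts, 2, c(5, 0, 0), `+`))

  xc <- c(30, 30, 30)
  rot <- transform_parameters(rigid_parameters(c(pi / 2, 0, 0), center = xc), cg)
  expect_equal(transform_point(xc + c(1, 0, 0), rot), xc + c(0, 1, 0),
               tolerance = 1e-12)
  # with zero deformation the transform equals the closed-form rigid map
  R <- euler_rotation(c(0.3, -0.2, 0.1))
  rp <- rigid_parameters(c(0.3, -0.2, 0.1), c(1, 2, -3), xc)
  tp2 <- transform_parameters(rp, cg)
  closed <- sweep(sweep(pts, 2, xc) %*% t(R), 2, xc + c(1, 2, -3), `+`)
  expect_equal(transform_point(pts, tp2), closed, tolerance = 1e-12)
})

test_that("euler rotation matrices are orthonormal with determinant +1", {
  set.seed(4)
  for (k in 1:5) {
    R <- euler_rotation(runif(3, -pi, pi))
    expect_equal(crossprod(R), diag(3), tolerance = 1e-12)
    expect_equal(det(R), 1, tolerance = 1e-12)
  }
})

test_that("coefficient fitting interpolates prescribed control-point values", {
  g <- volume_geometry(c(60, 60, 60))
  cg0 <- build_control_grid(c(6, 6, 6), g)
  z <- fit_coefficients_from_values(matrix(0, 216, 3), cg0)
  expect_equal(z$coefficients, cg0$coefficients)
  co <- fit_coefficients_from_values(matrix(1.5, 216, 3), cg0)
  expect_equal(evaluate_deformation(control_point_positions(co), co),
               matrix(1.5, 216, 3), tolerance = 1e-8)
  set.seed(5)
  vals <- matrix(rnorm(216 * 3), ncol = 3)
  cf <- fit_coefficients_from_values(vals, cg0)
  expect_equal(evaluate_deformation(control_point_positions(cf), cf), vals,
               tolerance = 1e-8)
})

test_that("grid refinement preserves zero, constant and random coarse fields", {
  g <- volume_geometry(c(60, 60, 60))
  cg <- build_control_grid(c(5, 5, 5), g)
  rz <- refine_grid(cg, c(9, 9, 9))
  expect_equal(max(abs(rz$coefficients)), 0, tolerance = 1e-10)

  cg$coefficients[] <- 2
  rc <- refine_grid(cg, c(9, 9, 9))
  set.seed(6)
  pts <- matrix(runif(300, 5, 55), ncol = 3)
  expect_equal(evaluate_deformation(pts, rc), matrix(2, 100, 3),
               tolerance = 1e-8)

  set.seed(7)
  cg$coefficients <- array(rnorm(5^3 * 3), c(5, 5, 5, 3))
  rr <- refine_grid(cg, c(9, 9, 9))
  pts <- matrix(runif(600, 0, 59), ncol = 3)
  disc <- max(abs(evaluate_deformation(pts, rr) - evaluate_deformation(pts, cg)))
  expect_lt(disc, 0.02 * sqrt(mean(cg$coefficients^2)))
  expect_error(refine_grid(rr, c(5, 5, 5)), "fine resolution")
})

test_that("perturbing one control point only changes the field within its local support", {
  g <- volume_geometry(c(80, 80, 80))
  cg <- build_control_grid(c(8, 8, 8), g)      # spacing 10 mm
  cg2 <- cg
  cg2$coefficients[4, 4, 4, 1] <- 5
  cp <- control_point_positions(cg)[4 + 8 * 3 + 64 * 3, ]
  set.seed(8)
  pts <- matrix(runif(900, 0, 79), ncol = 3)
  delta <- abs(evaluate_deformation(pts, cg2)[, 1] -
                 evaluate_deformation(pts, cg)[, 1])
  far <- apply(abs(sweep(pts, 2, cp)), 1, max) > 2 * 10  # outside 4-spacing box
  expect_true(all(delta[far] < 1e-12))
  expect_gt(max(delta[!far]), 0.1)
})

test_that("the field is C2: second differences are continuous across knot planes", {
  g <- volume_geometry(c(60, 60, 60))
  cg <- build_control_grid(c(6, 6, 6), g)
  set.seed(9)
  cg$coefficients <- array(rnorm(6^3 * 3), c(6, 6, 6, 3))
  knot_x <- cg$origin[1] + 3 * cg$spacing[1]
  h <- 1e-3
  d2 <- function(x0, eps) {
    xs <- rbind(c(x0 - h + eps, 30, 30), c(x0 + eps, 30, 30),
                c(x0 + h + eps, 30, 30))
    D <- evaluate_deformation(xs, cg)
    (D[1, ] - 2 * D[2, ] + D[3, ]) / h^2
  }
  expect_equal(d2(knot_x, -5 * h), d2(knot_x, 5 * h), tolerance = 0.05)
})

test_that("transform parameters serialize and restore exactly", {
  g <- volume_geometry(c(40, 40, 40), c(2, 2, 2), c(-1, 0, 1))
  cg <- build_control_grid(c(5, 5, 5), g)
  set.seed(10)
  cg$coefficients <- array(rnorm(5^3 * 3), c(5, 5, 5, 3))
  tp <- transform_parameters(rigid_parameters(c(0.1, 0.2, -0.3),
                                              c(4, -5, 6), c(40, 40, 40)), cg)
  p <- withr::local_tempfile(fileext = ".json")
  write_transform(tp, p)
  tp2 <- read_transform(p)
  expect_equal(tp2$rigid$angles, tp$rigid$angles)
  expect_equal(tp2$rigid$translation, tp$rigid$translation)
  expect_equal(tp2$grid$coefficients, tp$grid$coefficients)
  set.seed(11)
  pts <- matrix(runif(30, 5, 75), ncol = 3)
  expect_equal(transform_point(pts, tp2), transform_point(pts, tp))
})
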