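# Point-to-mesh distances, ICP, Hausdorff mesh distance, features and the
# feature-space ranking R_F.

test_that("point-to-mesh distance matches the exact all-triangle oracle", {
  m <- make_box_mask(c(8, 8, 8), c(2, 2, 2), c(5, 5, 5))
  mesh <- extract_isosurface(m, 1L)
  # a vertex of the mesh is at distance zero
  expect_equal(point_to_mesh_distance(mesh$vertices[7, ], mesh), 0)
  set.seed(1)
  pts <- matrix(runif(60, -2, 10), ncol = 3)
  d <- point_to_mesh_distance(pts, mesh)
  for (i in seq_len(nrow(pts)))
    expect_equal(d[i], oracle_point_mesh(pts[i, ], mesh), tolerance = 1e-10)
  expect_error(point_to_mesh_distance(c(0, 0, 0),
                                      surface_mesh(matrix(0, 0, 3),
                                                   matrix(0L, 0, 3))),
               "faces")
})

test_that("the centre of a unit cube is half a unit from its surface", {
  m <- make_box_mask(c(3, 3, 3), c(1, 1, 1), c(1, 1, 1))
  mesh <- extract_isosurface(m, 1L)      # unit cube centred at (1,1,1)
  expect_equal(point_to_mesh_distance(c(1, 1, 1), mesh), 0.5)
})

test_that("ICP is the identity on matching meshes and recovers known rigid motion", {
  # a voxelized blob: corners pin the alignment, unlike a smooth ellipsoid
  m <- make_box_mask(c(14, 12, 10), c(2, 2, 2), c(10, 8, 6),
                     spacing = c(2, 2, 2))
  A <- extract_isosurface(m, 1L)
  icp0 <- icp_align(A$vertices, A)
  expect_equal(icp0$rotation, diag(3), tolerance = 1e-6)
  expect_lt(sqrt(sum(icp0$translation^2)), 1e-6)

  ang <- 10 * pi / 180
  R_true <- euler_rotation(c(ang, 0, 0))
  t_true <- c(3, -4, 0)
  B <- surface_mesh(A$vertices %*% t(R_true) +
                      matrix(t_true, nrow(A$vertices), 3, byrow = TRUE),
                    A$faces)
  icp <- icp_align(A$vertices, B)
  rot_err <- acos(pmin(1, (sum(diag(crossprod(icp$rotation, R_true))) - 1) / 2))
  expect_lt(rot_err * 180 / pi, 0.5)
  expect_lt(sqrt(sum((icp$translation - t_true)^2)), 0.2)
  expect_true(all(diff(icp$residual_trace) <= 1e-9))
  expect_error(icp_align(matrix(rep(1:3, 3), 3, 3, byrow = FALSE), A),
               "collinear|degenerate")
})

test_that("hausdorff distance is zero on identity, ICP cancels a translation, and spheres give the analytic gap", {
  A <- make_sphere_mesh(radius = 10, subdiv = 3)
  self <- hausdorff_mesh_distance(A, A, prealign = FALSE, n_samples = 500,
                                  seed = 2)
  expect_lt(self[["hausdorff"]], 1e-9)
  expect_lt(self[["mean"]], 1e-9)

  B <- surface_mesh(sweep(A$vertices, 2, c(3, 0, 0), `+`), A$faces)
  aligned <- hausdorff_mesh_distance(A, B, prealign = TRUE, n_samples = 500,
                                     seed = 3)
  expect_lt(aligned[["hausdorff"]], 0.05)

  big <- make_sphere_mesh(radius = 12, subdiv = 4)
  small <- make_sphere_mesh(radius = 10, subdiv = 4)
  d <- hausdorff_mesh_distance(small, big, prealign = FALSE,
                               n_samples = 1500, seed = 4)
  expect_lt(abs(d[["hausdorff"]] - 2) / 2, 0.02)
  expect_lt(abs(d[["mean"]] - 2) / 2, 0.02)
  # hausdorff >= mean always; both scale linearly with the mesh
  expect_gte(d[["hausdorff"]], d[["mean"]])
  small2 <- surface_mesh(small$vertices * 2, small$faces)
  big2 <- surface_mesh(big$vertices * 2, big$faces)
  d2 <- hausdorff_mesh_distance(small2, big2, prealign = FALSE,
                                n_samples = 1500, seed = 4)
  expect_equal(d2[["mean"]], 2 * d[["mean"]], tolerance = 1e-8)
})

test_that("feature extraction reproduces the analytic phantom poses", {
  spec <- default_phantom_spec(noise_sd = 0)
  ph <- generate_phantom(spec)
  meshes <- lapply(names(ph$structures$label_names),
                   function(nm) extract_isosurface(ph$structures, nm))
  names(meshes) <- names(ph$structures$label_names)
  ss <- list(masks = ph$structures, meshes = meshes)
  fv <- extract_features(ss, phantom_body_mask(ph))
  vox <- max(spec$geometry$spacing)
  man <- spec$structures$mandible$center
  hyo <- spec$structures$hyoid$center
  expect_lt(max(abs(fv$mandible_hyoid_offset - (man - hyo))), vox)
  # jugular runs parallel to the hyoid axially: 2D offset is the (x, y) gap
  jug <- spec$structures$jugular_left$p0[1:2]
  expect_lt(max(abs(fv$hyoid_jugular_offset_2d - (jug - hyo[1:2]))), vox)
  # body centred in its bounding box, structures on the midline
  expect_equal(fv$hyoid_norm[1], 0.5, tolerance = 0.05)
  expect_equal(fv$mandible_norm[1], 0.5, tolerance = 0.05)
  expect_equal(fv$body_volume,
               sum(phantom_body_mask(ph)$labels) * prod(spec$geometry$spacing))

  ss_missing <- list(masks = region_mask(
    array(0L, spec$geometry$dims), spec$geometry, integer()), meshes = list())
  expect_error(extract_features(ss_missing, phantom_body_mask(ph)),
               "mandible")
})

test_that("feature distance is a weighted Euclidean semi-metric", {
  spec <- default_phantom_spec(noise_sd = 0)
  ph <- generate_phantom(spec)
  meshes <- lapply(names(ph$structures$label_names),
                   function(nm) extract_isosurface(ph$structures, nm))
  names(meshes) <- names(ph$structures$label_names)
  fv <- extract_features(list(masks = ph$structures, meshes = meshes),
                         phantom_body_mask(ph))
  expect_equal(feature_distance(fv, fv), 0, tolerance = 1e-8)

  # single differing scalar reduces to sqrt(w) * d
  fv2 <- fv
  fv2$body_volume <- fv$body_volume + 2e5    # d_i = 2 in the 100 cm^3 unit
  w <- feature_weights(body_volume = 1)
  expect_equal(feature_distance(fv2, fv, w), 2, tolerance = 1e-8)

  # hand-expanded weighted sum over several differing features
  fv3 <- fv
  fv3$hyoid_norm <- fv$hyoid_norm + c(0.1, 0, 0)
  fv3$mandible_hyoid_offset <- fv$mandible_hyoid_offset + c(3, -4, 0)
  fv3$body_volume <- fv$body_volume + 1e5
  w <- feature_weights()
  expected <- sqrt(w[["hyoid_norm"]] * 0.1^2 +
                   w[["mandible_hyoid_offset"]] * 0.5^2 +
                   w[["body_volume"]] * 1^2)
  expect_equal(feature_distance(fv3, fv, w), expected, tolerance = 1e-8)
  expect_error(feature_weights(not_a_feature = 2), "unknown")
})

test_that("reference ranking is stable, ascending, and puts an exact match first", {
  spec <- default_phantom_spec(noise_sd = 0)
  ph <- generate_phantom(spec)
  meshes <- lapply(names(ph$structures$label_names),
                   function(nm) extract_isosurface(ph$structures, nm))
  names(meshes) <- names(ph$structures$label_names)
  fv <- extract_features(list(masks = ph$structures, meshes = meshes),
                         phantom_body_mask(ph))
  fv_far <- fv
  fv_far$hyoid_norm <- pmin(fv$hyoid_norm + 0.2, 1)
  db1 <- list(reference_record("only", fv_far))
  r1 <- rank_references(fv, db1)
  expect_identical(r1$id, "only")

  db <- list(reference_record("far", fv_far),
             reference_record("self", fv))
  r <- rank_references(fv, db)
  expect_identical(r$id[1], "self")
  expect_equal(r$D_F[1], 0, tolerance = 1e-8)
  expect_true(all(diff(r$D_F) >= 0))
  expect_error(rank_references(fv, list()), "empty")
})
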