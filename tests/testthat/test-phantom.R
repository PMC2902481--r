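# Synthetic phantom cohort generator.

test_that("phantom generation is a pure function of its spec", {
  spec <- small_phantom_spec(noise_sd = 8, seed = 42)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$volume$values, b$volume$values)
  expect_identical(a$structures$labels, b$structures$labels)
  expect_identical(a$nodal_regions$labels, b$nodal_regions$labels)
})

test_that("without noise the volume is piecewise constant at the spec intensities", {
  ph <- generate_phantom(small_phantom_spec(noise_sd = 0))
  sp <- ph$spec
  for (nm in names(sp$structures)) {
    lab <- ph$structures$label_names[[nm]]
    vals <- ph$volume$values[ph$structures$labels == lab]
    expect_identical(unique(vals), sp$structures[[nm]]$intensity)
  }
  outside_all <- ph$structures$labels == 0L
  expect_setequal(unique(ph$volume$values[outside_all]),
                  c(sp$body$intensity, sp$air))
})

test_that("bone/soft-tissue contrast matches the spec within sampling error", {
  sd_n <- 15
  ph <- generate_phantom(small_phantom_spec(noise_sd = sd_n, seed = 9))
  sp <- ph$spec
  bone <- ph$volume$values[ph$structures$labels ==
                             ph$structures$label_names[["spine"]]]
  soft <- ph$volume$values[ph$structures$labels == 0L &
                             ph$volume$values > -200]
  expected <- sp$structures$spine$intensity - sp$body$intensity
  tol <- 3 * sd_n / sqrt(min(length(bone), length(soft)))
  expect_lt(abs((mean(bone) - mean(soft)) - expected), tol)
})

test_that("structures outside the body ellipsoid are rejected", {
  spec <- small_phantom_spec()
  spec$structures$spine$p1[3] <- 500
  expect_error(generate_phantom(spec), "outside the body")
})

test_that("a zero-variation cohort reproduces the base subject exactly", {
  base <- small_phantom_spec(noise_sd = 0)
  cs <- cohort_spec(base, n_subjects = 2,
                    variation = list(translation_sd = 0, scale_sd = 0),
                    deformation = list(amplitude = 0, control_spacing = 48),
                    seed = 5)
  co <- generate_cohort(cs)
  for (s in co$subjects) {
    expect_identical(s$volume$values, co$base$volume$values)
    expect_identical(s$nodal_regions$labels, co$base$nodal_regions$labels)
  }
  expect_equal(max(abs(co$warps[[1]]$coefficients)), 0)
})

test_that("cohorts are reproducible and warp amplitude controls mean displacement", {
  base <- small_phantom_spec(noise_sd = 0)
  cs <- cohort_spec(base, n_subjects = 3,
                    variation = list(translation_sd = 0, scale_sd = 0),
                    deformation = list(amplitude = 5, control_spacing = 48),
                    seed = 7)
  co <- generate_cohort(cs)
  co2 <- generate_cohort(cs)
  expect_identical(co$subjects[[2]]$volume$values,
                   co2$subjects[[2]]$volume$values)
  g <- base$geometry
  pts <- voxel_center_grid(g)
  for (w in co$warps) {
    mag <- sqrt(rowSums(evaluate_deformation(pts, w, clamp = TRUE)^2))
    expect_gt(mean(mag), 0.2 * 5)
    expect_lt(mean(mag), 5 + 1e-6)
    expect_lt(max(mag), 5 * 1.05)   # amplitude is the (probed) peak
  }
})

test_that("warped nodal masks keep volume within 20% at 5 mm amplitude", {
  base <- small_phantom_spec(noise_sd = 0)
  cs <- cohort_spec(base, n_subjects = 2,
                    variation = list(translation_sd = 0, scale_sd = 0),
                    deformation = list(amplitude = 5, control_spacing = 48),
                    seed = 13)
  co <- generate_cohort(cs)
  for (s in co$subjects) {
    for (nm in names(base$nodal_regions)) {
      lab <- co$base$nodal_regions$label_names[[nm]]
      v0 <- sum(co$base$nodal_regions$labels == lab)
      v1 <- sum(s$nodal_regions$labels == lab)
      expect_lt(abs(v1 - v0) / v0, 0.2)
    }
  }
})

test_that("ground-truth warps are numerically invertible to sub-voxel residual", {
  g <- volume_geometry(c(32, 32, 32), c(4, 4, 4))
  w <- random_warp_grid(g, amplitude = 5, control_spacing = 48, seed = 3)
  inv <- invert_displacement(w, g)
  pts <- voxel_center_grid(g)
  fwd <- pts + evaluate_deformation(pts, w, clamp = TRUE)
  resid <- fwd + inv(fwd) - pts
  expect_lt(mean(sqrt(rowSums(resid^2))), 0.1 * 4)
})

test_that("structures stay singly connected after default-amplitude warping", {
  base <- small_phantom_spec(noise_sd = 0)
  cs <- cohort_spec(base, n_subjects = 1,
                    variation = list(translation_sd = 0, scale_sd = 0),
                    deformation = list(amplitude = 5, control_spacing = 48),
                    seed = 21)
  co <- generate_cohort(cs)
  labs <- co$subjects[[1]]$structures$labels
  n_components_3d <- function(mask) {
    idx <- which(mask)
    if (!length(idx)) return(0L)
    d <- dim(mask)
    id <- seq_along(idx)
    lut <- integer(length(mask)); lut[idx] <- id
    edges <- NULL
    for (step in c(1L, d[1], d[1] * d[2])) {
      ok <- (idx + step) <= length(mask)
      if (step == 1L) ok <- ok & (idx %% d[1] != 0)
      if (step == d[1]) ok <- ok & ((idx - 1L) %/% d[1] %% d[2] != d[2] - 1L)
      nb <- idx[ok] + step
      has <- lut[nb] > 0
      edges <- rbind(edges, cbind(lut[idx[ok][has]], lut[nb[has]]))
    }
    g <- igraph::graph_from_edgelist(rbind(edges, cbind(id, id)),
                                     directed = FALSE)
    igraph::components(g)$no
  }
  for (nm in c("spine", "mandible", "hyoid")) {
    lab <- co$subjects[[1]]$structures$label_names[[nm]]
    expect_equal(n_components_3d(labs == lab), 1)
  }
})

test_that("cohorts write volumes, masks, warps and a manifest to disk", {
  base <- phantom_spec(volume_geometry(c(24, 24, 24), c(6, 6, 6)),
                       body = list(center = c(72, 72, 72),
                                   semi_axes = c(55, 50, 65), intensity = 40),
                       structures = list(
                         blob = list(shape = "ellipsoid", center = c(72, 60, 72),
                                     semi_axes = c(14, 10, 12), intensity = 700)),
                       nodal_regions = list(
                         node = list(shape = "ellipsoid", center = c(84, 72, 72),
                                     semi_axes = c(10, 10, 10))),
                       noise_sd = 0, seed = 2)
  co <- generate_cohort(cohort_spec(base, 1,
                                    variation = list(translation_sd = 0,
                                                     scale_sd = 0),
                                    deformation = list(amplitude = 3,
                                                       control_spacing = 60),
                                    seed = 3))
  dir <- withr::local_tempdir()
  manifest <- write_cohort(co, dir)
  man <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  expect_true(file.exists(file.path(dir, man$base$volume)))
  expect_true(file.exists(file.path(dir, man$subjects$warp[1])))
  fld <- read_displacement_field(file.path(dir, man$subjects$warp[1]))
  pts <- voxel_center_grid(base$geometry)
  D <- evaluate_deformation(pts, co$warps[[1]], clamp = TRUE)
  expect_equal(as.numeric(fld[[1]]$values), D[, 1], tolerance = 1e-5)
})
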