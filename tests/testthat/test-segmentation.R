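# Constraint-based dynamic thresholding, 3D active contour and the
# progressive segmentation pipeline.

make_disk_slice <- function(dims = c(64, 64), center = c(32, 32), r = 6,
                            value = 800, bg = 40) {
  sl <- matrix(bg, dims[1], dims[2])
  ix <- outer(seq_len(dims[1]) - center[1], rep(1, dims[2]))
  iy <- outer(rep(1, dims[1]), seq_len(dims[2]) - center[2])
  sl[ix^2 + iy^2 <= r^2] <- value
  sl
}

test_that("a uniform slice yields no candidate regions", {
  g <- volume_geometry(c(64, 64, 8))
  rule <- structure_rule("s", c(500, 900), c(10, 400))
  expect_length(dynamic_threshold_slice(matrix(40, 64, 64), rule,
                                        geometry = g, z_mm = 0), 0)
})

test_that("a bright disk of in-window size is found and covers the disk", {
  g <- volume_geometry(c(64, 64, 8))
  sl <- make_disk_slice(r = 6)
  rule <- structure_rule("s", c(500, 900), c(60, 200))
  regions <- dynamic_threshold_slice(sl, rule, geometry = g, z_mm = 0)
  expect_length(regions, 1)
  disk_px <- sum(sl > 500)
  expect_gte(nrow(regions[[1]]$pixels) / disk_px, 0.9)
  expect_equal(regions[[1]]$centroid[1:2], c(31, 31), tolerance = 0.1)
})

test_that("negative shape constraints reject an elongated bar", {
  g <- volume_geometry(c(64, 64, 8))
  sl <- matrix(40, 64, 64)
  sl[10:50, 30:32] <- 800   # elongation far above the cap
  rule <- structure_rule("s", c(500, 900), c(60, 200),
                         shape_constraints = list(max_elongation = 3))
  expect_length(dynamic_threshold_slice(sl, rule, geometry = g, z_mm = 0), 0)
})

test_that("location priors gate candidates on earlier structures", {
  g <- volume_geometry(c(64, 64, 8))
  sl <- make_disk_slice(center = c(40, 40))
  rule <- structure_rule("s", c(500, 900), c(60, 200),
                         location_prior = list(ref = "anchor",
                                               offset = c(0, 0, 0),
                                               box = c(5, 5, 50)),
                         reliability_rank = 2L)
  near <- list(anchor = list(centroid = c(39, 39, 0)))
  far <- list(anchor = list(centroid = c(10, 10, 0)))
  expect_length(dynamic_threshold_slice(sl, rule, near, g, 0), 1)
  expect_length(dynamic_threshold_slice(sl, rule, far, g, 0), 0)
  # missing prior structure: no candidates rather than an error
  expect_length(dynamic_threshold_slice(sl, rule, list(), g, 0), 0)
})

test_that("active contour growth contains its seed and stops at intensity boundaries", {
  g <- volume_geometry(c(40, 40, 40))
  pts <- voxel_center_grid(g)
  sphere <- rowSums(sweep(pts, 2, c(20, 20, 20))^2) <= 10^2
  vol <- volume_image(array(ifelse(sphere, 800, 40), g$dims), g)
  sph_arr <- array(sphere, g$dims)

  # already-converged seed: the full sphere stays the sphere
  out <- active_contour_3d(vol, sph_arr,
                           list(iterations = 10, curvature = 2,
                                intensity_window = c(500, 900)))
  expect_identical(out, sph_arr)

  # zero iterations: output equals the seed exactly
  seed <- array(FALSE, g$dims)
  seed[, , 21] <- sph_arr[, , 21]
  expect_identical(active_contour_3d(vol, seed, list(iterations = 0)), seed)

  # one equatorial slice grows to most of the sphere with minimal leakage
  grown <- active_contour_3d(vol, seed,
                             list(iterations = 40, curvature = 2,
                                  intensity_window = c(500, 900)))
  expect_true(all(grown[seed]))                 # monotone seeding
  expect_gte(sum(grown & sph_arr) / sum(sph_arr), 0.8)
  expect_lte(sum(grown & !sph_arr) / sum(sph_arr), 0.05)
  expect_error(active_contour_3d(vol, array(FALSE, g$dims)), "seed")
})

test_that("progressive segmentation recovers the phantom structures (centroids and Dice)", {
  # the default phantom resolution (2 mm) resolves even the thin vessels
  ph <- generate_phantom(default_phantom_spec(noise_sd = 0))
  ss <- progressive_segment(ph$volume, default_structure_rules())
  for (nm in c("spine", "mandible", "hyoid")) {
    expect_true(nm %in% names(ss$masks$label_names))
    truth_c <- colMeans(voxel_to_world(
      which(ph$structures$labels == ph$structures$label_names[[nm]],
            arr.ind = TRUE) - 1L, ph$volume$geometry))
    expect_lt(max(abs(ss$centroids[[nm]] - truth_c)),
              2 * max(ph$volume$geometry$spacing))
  }
  for (nm in names(ss$masks$label_names)) {
    expect_gte(dice(ph$structures, ss$masks,
                    c(ph$structures$label_names[[nm]],
                      ss$masks$label_names[[nm]])), 0.85)
  }
})

test_that("segmentation is deterministic and empty rule lists are vacuous", {
  ph <- generate_phantom(small_phantom_spec(noise_sd = 6, seed = 2))
  a <- suppressWarnings(progressive_segment(ph$volume, default_structure_rules()))
  b <- suppressWarnings(progressive_segment(ph$volume, default_structure_rules()))
  expect_identical(a$masks$labels, b$masks$labels)
  empty <- progressive_segment(ph$volume, list())
  expect_length(empty$meshes, 0)
})

test_that("a rule depending on a missing structure is skipped with a warning", {
  ph <- generate_phantom(small_phantom_spec(noise_sd = 0))
  rules <- default_structure_rules()[c("spine", "mandible", "hyoid")]
  # make the mandible undetectable; hyoid depends on it
  rules$mandible$intensity_window <- c(2000, 3000)
  rules$mandible$size_window <- c(1, 2)
  expect_warning(ss <- progressive_segment(ph$volume, rules),
                 "mandible")
  expect_true("spine" %in% names(ss$masks$label_names))
  expect_false("hyoid" %in% names(ss$masks$label_names))
})

test_that("forward-referencing priors are a configuration error", {
  ph <- generate_phantom(small_phantom_spec(noise_sd = 0))
  rules <- list(
    a = structure_rule("a", c(500, 900), c(10, 400),
                       location_prior = list(ref = "b", offset = c(0, 0, 0),
                                             box = c(5, 5, 5)),
                       reliability_rank = 1L),
    b = structure_rule("b", c(500, 900), c(10, 400), reliability_rank = 2L))
  expect_error(progressive_segment(ph$volume, rules), "dependency")
})

test_that("the shipped example rule and contour files load", {
  rules <- read_structure_rules(system.file("extdata", "example_rules.yaml",
                                            package = "hnatlas"))
  expect_true(all(c("spine", "mandible", "hyoid") %in% names(rules)))
  expect_identical(rules$hyoid$location_prior$ref, "mandible")
  m <- read_contour_stack(system.file("extdata", "example_contours.json",
                                      package = "hnatlas"),
                          volume_geometry(c(96, 96, 96), c(2, 2, 2)))
  expect_true(all(c("level_1B_left", "level_2_left") %in%
                    names(m$label_names)))
  expect_gt(sum(m$labels > 0), 0)
})

test_that("rules round-trip through the YAML config reader", {
  p <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "spine:",
    "  intensity_window: [700, 900]",
    "  size_window: [250, 500]",
    "  reliability_rank: 1",
    "mandible:",
    "  intensity_window: [850, 1050]",
    "  size_window: [100, 1400]",
    "  reliability_rank: 2",
    "  location_prior:",
    "    ref: spine",
    "    offset: [0, -75, 40]",
    "    box: [20, 25, 25]"), p)
  rules <- read_structure_rules(p)
  expect_named(rules, c("spine", "mandible"))
  expect_equal(rules$mandible$location_prior$offset, c(0, -75, 40))
  expect_equal(rules$spine$intensity_window, c(700, 900))
})
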