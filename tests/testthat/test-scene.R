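full_scale_box <- c(176.64, 176.64, 500)

test_that("density converts to particle count through the box volume", {
  expect_identical(density_to_count(1.6e4, full_scale_box), 250L)
  expect_identical(density_to_count(0, full_scale_box), 0L)
  expect_identical(density_to_count(12.82e4, full_scale_box), 2000L)
  expect_error(density_to_count(-1, full_scale_box), "nonnegative")
})

test_that("Poisson-disk sampling respects count, box and minimum distance", {
  expect_identical(nrow(sample_particle_field(0, toy_box())$particles), 0L)

  one <- sample_particle_field(1, toy_box(), seed = 3)$particles
  expect_true(one$x_um > 0 && one$x_um < 32 && one$z_um > 0 && one$z_um < 40)

  fld <- sample_particle_field(50, c(100, 100, 100), min_distance_um = 2,
                               seed = 11)
  p <- as.matrix(fld$particles[, c("x_um", "y_um", "z_um")])
  d <- as.matrix(stats::dist(p))
  expect_true(all(d[upper.tri(d)] >= 2))  # all 1225 pairwise distances

  # reproducible for a fixed seed
  again <- sample_particle_field(50, c(100, 100, 100), min_distance_um = 2,
                                 seed = 11)
  expect_identical(fld$particles, again$particles)

  expect_error(sample_particle_field(1000, c(5, 5, 5), min_distance_um = 4),
               "infeasible|failed")
})

test_that("heterogeneity sampling draws uniformly around the central values", {
  fld <- sample_particle_field(20, toy_box(), seed = 1)
  fixed <- sample_heterogeneity(fld, central_dn = 0.26, delta_n_pct = 0,
                                central_D_um = 1.0, delta_D_pct = 0)
  expect_true(all(fixed$particles$dn == 0.26))
  expect_true(all(fixed$particles$diameter_um == 1.0))

  het <- sample_heterogeneity(fld, central_dn = 0.20, delta_n_pct = 50,
                              seed = 2)
  expect_true(all(het$particles$dn >= 0.10 & het$particles$dn <= 0.30))

  big <- sample_particle_field(1, c(1000, 1000, 1000), seed = 1)
  big$particles <- big$particles[rep(1, 1e4), ]
  mc <- sample_heterogeneity(big, central_dn = 0.20, delta_n_pct = 50,
                             seed = 3)
  half_width <- 0.20 * 0.5
  se <- half_width / sqrt(3) / sqrt(1e4)
  expect_lt(abs(mean(mc$particles$dn) - 0.20), 3 * se)

  expect_error(sample_heterogeneity(fld, central_dn = -0.1), "positive")
  expect_error(sample_heterogeneity(fld, central_dn = 0.2, delta_n_pct = 150),
               "\\[0, 100\\]")
})

test_that("voxelization marks exactly the voxel centers inside each sphere", {
  cfg <- toy_optics()
  gd <- grid_dimensions(cfg)

  empty <- sample_particle_field(0, toy_box())
  expect_true(all(voxelize(empty, cfg)$values == 0))

  fld <- empty
  fld$particles <- data.frame(x_um = 10.2, y_um = 20.1, z_um = 18.3,
                              diameter_um = 2.4, dn = 0.26)
  iv <- voxelize(fld, cfg)
  # brute-force oracle: scan every voxel center
  xs <- (seq_len(gd$nx) - 0.5) * 0.5
  zs <- (seq_len(gd$n_fine_z) - 0.5) * cfg$fine_axial_step_nm / 1000
  expected <- array(0, dim = c(gd$nx, gd$ny, gd$n_fine_z))
  ix <- which(abs(xs - 10.2) <= 1.2)
  iy <- which(abs(xs - 20.1) <= 1.2)
  iz <- which(abs(zs - 18.3) <= 1.2)
  for (i in ix) for (j in iy) for (k in iz) {
    if ((xs[i] - 10.2)^2 + (xs[j] - 20.1)^2 + (zs[k] - 18.3)^2 <= 1.2^2) {
      expected[i, j, k] <- 0.26
    }
  }
  expect_identical(iv$values, expected)

  two <- empty
  two$particles <- data.frame(x_um = c(8, 24), y_um = c(8, 24),
                              z_um = c(10, 30), diameter_um = c(2, 2),
                              dn = c(0.1, 0.3))
  tv <- voxelize(two, cfg)$values
  expect_setequal(unique(as.vector(tv)), c(0, 0.1, 0.3))

  clipped <- empty
  clipped$particles <- data.frame(x_um = 0.2, y_um = 16, z_um = 20,
                                  diameter_um = 2, dn = 0.26)
  expect_warning(voxelize(clipped, cfg), "clipped")

  expect_error(voxelize(sample_particle_field(0, c(10, 10, 10)), cfg),
               "does not match")
})

test_that("ground truth bins fine slices to the nearest coarse slice", {
  cfg <- toy_optics()
  gd <- grid_dimensions(cfg)

  empty <- sample_particle_field(0, toy_box())
  expect_true(all(make_ground_truth(empty, cfg)$labels == 0))

  # a 1-um sphere is thinner than the 5-um bin: exactly one occupied slice
  thin <- empty
  thin$particles <- data.frame(x_um = 16, y_um = 16, z_um = 20,
                               diameter_um = 1, dn = 0.26)
  gt <- make_ground_truth(thin, cfg)
  expect_identical(dim(gt$labels), c(gd$nx, gd$ny, gd$n_coarse_z))
  occupied <- which(apply(gt$labels, 3, sum) > 0)
  expect_length(occupied, 1L)
  # scene z = 20 um sits 20 um behind the hologram (exit) plane: slice 4
  expect_identical(occupied, 4L)
  expect_true(all(gt$labels %in% c(0L, 1L)))
})

test_that("ground-truth lateral footprint matches the fine-grid footprint", {
  cfg <- toy_optics()
  fld <- sample_particle_field(6, toy_box(), seed = 8, diameter_um = 2,
                               min_distance_um = 3)
  iv <- voxelize(fld, cfg)
  gt <- ground_truth_from_index_volume(iv)
  fine_fp <- apply(iv$values != 0, c(1, 2), any)
  coarse_fp <- apply(gt$labels == 1L, c(1, 2), any)
  expect_identical(coarse_fp, fine_fp)
})

test_that("particle tables round-trip through CSV", {
  fld <- sample_particle_field(7, toy_box(), seed = 2, diameter_um = 1.5,
                               index_contrast = 0.2)
  path <- tempfile(fileext = ".csv")
  write_particle_csv(fld, path)
  back <- read_particle_csv(path)
  expect_equal(back$particles, fld$particles, tolerance = 1e-12)
  expect_equal(back$box_um, fld$box_um)
})
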