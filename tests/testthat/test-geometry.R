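# Half-max midplane and apical-zone occupancy metrics.

# independent fine-grid oracle: densely interpolate the piecewise-linear
# profile and search the half-max crossings by brute force
oracle_midplane <- function(a, z, n_dense = 200001L) {
  zd <- seq(min(z), max(z), length.out = n_dense)
  ad <- approx(z, a, xout = zd)$y
  half <- max(ad) / 2
  above <- ad >= half
  (zd[which(above)[1]] + zd[rev(which(above))[1]]) / 2
}

test_that("midplane is the half-max midpoint: symmetric, asymmetric, and boundary-cut profiles", {
  expect_equal(nuclear_midplane(c(2, 4, 8, 4, 2), z_um = 1:5), 3.0)

  # top-heavy profile cut by the apical volume boundary is untrackable
  m <- nuclear_midplane(c(8, 8, 6, 4, 2), z_um = 1:5)
  expect_true(is.na(m))
  expect_match(attr(m, "reason"), "apical")

  a <- c(1, 3, 8, 6, 5, 2)
  expect_equal(nuclear_midplane(a, z_um = 1:6), oracle_midplane(a, 1:6),
               tolerance = 1e-4)

  expect_true(is.na(nuclear_midplane(c(0, 0, 0), z_um = 1:3)))
})

test_that("midplane is scale-invariant in area and shift-equivariant in depth", {
  a <- c(1, 3, 8, 6, 5, 2)
  z <- 1:6
  base <- nuclear_midplane(a, z_um = z)
  for (s in c(0.1, 7, 1000))
    expect_equal(nuclear_midplane(a * s, z_um = z), base, tolerance = 1e-12)
  for (delta in c(0.5, 3))
    expect_equal(nuclear_midplane(a, z_um = z + delta), base + delta,
                 tolerance = 1e-12)
})

test_that("area profiles count label voxels per plane", {
  d3 <- c(21, 21, 21)
  lab <- array(0L, d3)
  lab[raster_ball(d3, c(11, 11, 11), 8)] <- 4L
  prof <- area_profile(lab, 4L, voxel_size = c(1, 1, 1))
  # center plane area close to pi r^2 (lattice-count discretization)
  expect_lt(abs(max(prof$area_um2) - pi * 64) / (pi * 64), 0.03)
  expect_identical(which.max(prof$area_um2), 11L)
  # exact equality with a direct slice count
  expect_identical(prof$area_um2[5], sum(lab[5, , ] == 4L) * 1)

  single <- array(0L, d3); single[7, 3, 3] <- 2L
  p2 <- area_profile(single, 2L, c(1, 1, 1))
  expect_identical(sum(p2$area_um2 > 0), 1L)

  p3 <- area_profile(lab, 99L, c(1, 1, 1))
  expect_true(all(p3$area_um2 == 0))
  expect_false(attr(p3, "valid"))
})

test_that("midplane tracks the true center of rasterized ellipsoids to half a micrometre", {
  cfg <- scene_config(grid_shape = c(65L, 96L, 96L),
                      voxel_size = c(0.5, 0.5, 0.5), n_frames = 2L,
                      n_nuclei = 9L, initial_apical_depth = c(6, 26),
                      motion_mix = c(active = 0, diffusive = 1, confined = 0),
                      rng_seed = 31L)
  tr <- generate_trajectories(cfg)
  labs <- rasterize_labels(tr)
  fr <- array(labs$data[1, , , ], dim(labs$data)[2:4])
  truth1 <- tr$positions[tr$positions$frame == 1, ]
  for (id in truth1$id) {
    prof <- area_profile(fr, id, labs$voxel_size)
    mid <- nuclear_midplane(prof)
    expect_lt(abs(mid - truth1$z_um[truth1$id == id]), 0.5)
  }
})

test_that("depth categories nest and split at 2 and 10 micrometres", {
  cc <- depth_category(c(1.5, 9.9, 12))
  expect_identical(as.character(cc$category),
                   c("exclusion_zone", "apical10", "basal"))
  expect_true(cc$in_apical10[1])  # exclusion-zone nuclei are also apical-10
  expect_error(depth_category(-1), ">= 0")
})

test_that("category fractions divide by the per-frame valid population and always sum apical10 + basal = 1", {
  depths <- c(rep(1, 2), rep(5, 8), rep(15, 10))
  fr <- category_fractions(depths)
  expect_equal(fr$exclusion, 0.10)
  expect_equal(fr$apical10, 0.50)
  expect_equal(fr$basal, 0.50)
  expect_identical(fr$n_valid, 20L)

  expect_equal(category_fractions(rep(5, 7))$apical10, 1.0)
  expect_equal(category_fractions(rep(20, 7))$apical10, 0.0)

  set.seed(17)
  tab <- data.frame(frame = rep(1:6, each = 30),
                    depth_um = runif(180, 0, 32))
  tab$depth_um[sample(180, 10)] <- NA  # invalid nuclei drop from denominators
  fr2 <- category_fractions(tab)
  expect_equal(fr2$apical10 + fr2$basal, rep(1, 6), tolerance = 1e-12)
  expect_true(all(fr2$exclusion <= fr2$apical10))
})

test_that("the apical reference is the apical-most foreground slice", {
  d3 <- c(20, 10, 10)
  lab <- array(0L, d3)
  lab[raster_ball(d3, c(12, 5, 5), 3)] <- 1L
  expect_equal(apical_reference(lab, c(1, 1, 1)), 8)  # slice 9 -> depth 8 um
  per <- apical_reference(lab, c(1, 1, 1), per_label = TRUE)
  expect_equal(unname(per["1"]), 8)
})
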