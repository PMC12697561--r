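# Isotropic resampling, preprocessing, rough masks, seeds, seeded watershed.

test_that("resampling doubles z at 2:1 anisotropy, preserves constants, and is identity when isotropic", {
  vol <- volume_series(array(runif(2 * 20 * 8 * 8), c(2, 20, 8, 8)),
                       c(1, 0.5, 0.5), 15)
  iso <- resample_isotropic(vol)
  expect_identical(dim(iso$data)[2], 40L)
  expect_equal(iso$voxel_size, c(0.5, 0.5, 0.5))
  # physical z extent preserved to within half a voxel
  expect_lt(abs(dim(iso$data)[2] * 0.5 - 20 * 1), 0.5 + 1e-9)

  const <- volume_series(array(3.7, c(1, 10, 6, 6)), c(2, 0.5, 0.5), 10)
  expect_true(all(resample_isotropic(const)$data == 3.7))

  already <- volume_series(array(runif(500), c(1, 5, 10, 10)),
                           c(0.5, 0.5, 0.5), 10)
  expect_identical(resample_isotropic(already), already)
})

test_that("Gaussian preprocessing is identity at sigma 0, constant-preserving, and kernel-normalized", {
  vol <- volume_series(array(runif(1 * 12 * 12 * 12), c(1, 12, 12, 12)),
                       c(0.5, 0.5, 0.5), 10)
  expect_identical(preprocess_volume(vol, 0), vol)

  const <- volume_series(array(2, c(1, 8, 8, 8)), c(0.5, 0.5, 0.5), 10)
  expect_equal(preprocess_volume(const, 0.8)$data, const$data,
               tolerance = 1e-12)

  spike <- array(0, c(1, 21, 21, 21))
  spike[1, 11, 11, 11] <- 5
  sm <- preprocess_volume(volume_series(spike, c(0.5, 0.5, 0.5), 10), 0.6)
  expect_equal(sum(sm$data), 5, tolerance = 1e-6 * 5)
})

test_that("local thresholding recovers bright spheres and rejects flat volumes", {
  expect_false(any(rough_mask(array(1, c(20, 20, 20)), rep(0.5, 3), 8, 0.1)))

  # bright sphere, SNR 10
  set.seed(1)
  d3 <- c(40, 40, 40)
  sphere <- raster_ball(d3, c(20, 20, 20), 8)
  img <- ifelse(sphere, 1, 0) + array(rnorm(prod(d3), 0, 0.1), d3)
  img <- nucdyn:::gauss_blur3(pmax(img, 0), rep(1.2, 3))
  mask <- rough_mask(img, rep(0.5, 3), window = 12, offset = 0.4)
  expect_gt(sum(mask & sphere) / sum(sphere), 0.9)
  # mask contained in the sphere dilated by 2 voxels
  dil2 <- nucdyn:::edt3(!sphere) <= 2
  expect_true(all(!mask | dil2))

  two <- raster_ball(d3, c(20, 12, 12), 6) | raster_ball(d3, c(20, 30, 30), 6)
  img2 <- nucdyn:::gauss_blur3(ifelse(two, 1, 0) +
                                 array(rnorm(prod(d3), 0, 0.1), d3),
                               rep(1.2, 3))
  mask2 <- rough_mask(img2, rep(0.5, 3), 12, 0.4)
  comp <- nucdyn:::label_components3(mask2)
  big <- sum(tabulate(comp[comp > 0]) > 50)
  expect_identical(big, 2L)
})

test_that("erosion-derived seeds match exact ball erosion and survive thin components", {
  d3 <- c(40, 40, 40)
  sphere <- raster_ball(d3, c(20, 20, 20), 8)
  seeds <- seeds_from_mask(sphere, voxel = 1, erosion_radius = 3,
                           min_seed_voxels = 10)
  expect_identical(max(seeds), 1L)
  # erosion of a ball of radius 8 by 3 is a ball of radius ~5
  expect_identical(seeds > 0L, nucdyn:::edt3(sphere) > 3)

  # component thinner than the erosion radius still yields one seed
  thin <- raster_ball(d3, c(20, 20, 20), 2.2)
  seeds2 <- seeds_from_mask(thin, 1, erosion_radius = 3, min_seed_voxels = 10)
  info <- attr(seeds2, "seed_info")
  expect_identical(sum(seeds2 > 0L) > 0L, TRUE)
  expect_identical(max(seeds2), 1L)
  expect_true(info$reseeded)

  expect_identical(max(seeds_from_mask(array(FALSE, c(5, 5, 5)), 1, 1)), 0L)
})

test_that("fused nuclei are split into two seeds, single ellipsoids are not", {
  d3 <- c(40, 60, 40)
  fused <- raster_ball(d3, c(20, 24, 20), 8) | raster_ball(d3, c(20, 37, 20), 8)
  expect_identical(max(nucdyn:::label_components3(fused)), 1L)  # one blob
  seeds <- seeds_from_mask(fused, 1, erosion_radius = 3, min_seed_voxels = 10,
                           peak_separation = 8)
  info <- attr(seeds, "seed_info")
  expect_identical(sum(info$n_seeds), 2L)
  expect_true(info$fused_split)

  # an elongated single ellipsoid must not be split
  iz <- 1:40; iy <- 1:60; ix <- 1:40
  d2 <- outer(outer(((iz - 20) / 7)^2, ((iy - 30) / 14)^2, `+`),
              ((ix - 20) / 7)^2, `+`)
  ell <- array(d2 <= 1, d3)
  seeds2 <- seeds_from_mask(ell, 1, erosion_radius = 3, min_seed_voxels = 10,
                            peak_separation = 7)
  expect_identical(sum(attr(seeds2, "seed_info")$n_seeds), 1L)
})

test_that("seeded watershed fills single blobs, splits dumbbells at the neck, and partitions the mask", {
  d3 <- c(30, 60, 30)
  blob <- raster_ball(d3, c(15, 20, 15), 7)
  img <- nucdyn:::gauss_blur3(ifelse(blob, 1, 0), rep(1, 3))
  seeds <- array(0L, d3); seeds[15, 20, 15] <- 1L
  lab <- watershed_labels(img, seeds, blob)
  expect_identical(lab > 0L, blob)

  dumb <- raster_ball(d3, c(15, 20, 15), 7) | raster_ball(d3, c(15, 40, 15), 7)
  img2 <- nucdyn:::gauss_blur3(ifelse(dumb, 1, 0), rep(1, 3))
  seeds2 <- array(0L, d3)
  seeds2[15, 20, 15] <- 1L
  seeds2[15, 40, 15] <- 2L
  lab2 <- watershed_labels(img2, seeds2, dumb)
  expect_identical(sort(unique(lab2[lab2 > 0L])), c(1L, 2L))
  expect_identical(lab2 > 0L, dumb)  # exact partition of the mask
  # split plane near the neck (y = 30): all of label 1 on the low-y side
  co <- arrayInd(which(lab2 == 1L), d3)
  expect_lte(max(co[, 2]), 31)
  co2 <- arrayInd(which(lab2 == 2L), d3)
  expect_gte(min(co2[, 2]), 29)
})

test_that("the full segmentation is deterministic", {
  cfg <- scene_config(grid_shape = c(33L, 64L, 64L), n_frames = 2L,
                      n_nuclei = 6L, initial_apical_depth = c(6, 24),
                      motion_mix = c(active = 0, diffusive = 1, confined = 0),
                      noise = list(gaussian_sd = 0.2, poisson_scale = 0),
                      rng_seed = 12L)
  sc <- render_volume(generate_trajectories(cfg))
  s1 <- segment_series(sc$volume)
  s2 <- segment_series(sc$volume)
  expect_identical(s1$labels$data, s2$labels$data)
  expect_identical(s1$tracks, s2$tracks)
})
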