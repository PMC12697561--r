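# Synthetic-scene generator: trajectories, rendering, FRAP curves, fixtures.

test_that("noiseless ballistic nuclei move exactly linearly and scenes are seed-deterministic", {
  cfg <- scene_config(n_frames = 12L, n_nuclei = 2L,
                      motion_mix = c(active = 1, diffusive = 0, confined = 0),
                      run_speed = 0.5, pause_dwell = 0, rng_seed = 5L)
  tr <- generate_trajectories(cfg)
  for (id in 1:2) {
    z <- tr$positions$z_um[tr$positions$id == id]
    t_min <- tr$positions$t_s[tr$positions$id == id] / 60
    expect_equal(z, z[1] + 0.5 * t_min, tolerance = 1e-12)
  }
  tr2 <- generate_trajectories(cfg)
  expect_identical(tr$positions, tr2$positions)
  sc1 <- render_volume(tr)
  sc2 <- render_volume(tr2)
  expect_identical(sc1$volume$data, sc2$volume$data)
})

test_that("a motion mix not summing to one is rejected", {
  expect_error(scene_config(motion_mix = c(active = 0.5, diffusive = 0.2,
                                           confined = 0.2)),
               "sum to 1")
  expect_error(scene_config(motion_mix = c(a = 0.5, b = 0.5)), "motion_mix")
})

test_that("diffusive trajectories reproduce the Brownian MSD closed form per axis", {
  d_coef <- 0.1  # um^2/min
  cfg <- scene_config(grid_shape = c(33L, 400L, 400L), n_frames = 1001L,
                      n_nuclei = 8L, frame_interval = 15,
                      initial_apical_depth = 16,
                      motion_mix = c(active = 0, diffusive = 1, confined = 0),
                      diffusion_coeff = d_coef, rng_seed = 2L)
  tr <- generate_trajectories(cfg)
  # lateral axes are unbounded: the time-averaged MSD concentrates at short
  # lags (relative SD ~ sqrt(4 tau / 3 n)), so compare there
  for (lag in c(4L, 10L)) {
    tau_min <- lag * 15 / 60
    for (ax in c("x_um", "y_um")) {
      msd <- mean(vapply(1:8, function(id) {
        v <- tr$positions[[ax]][tr$positions$id == id]
        mean((v[(1 + lag):length(v)] - v[1:(length(v) - lag)])^2)
      }, 0))
      expect_lt(abs(msd - 2 * d_coef * tau_min) / (2 * d_coef * tau_min), 0.15)
    }
  }
})

test_that("rendered label voxel counts match the ellipsoid volume and labels partition", {
  cfg <- scene_config(grid_shape = c(60L, 64L, 64L), voxel_size = c(0.5, 0.5, 0.5),
                      n_frames = 2L, n_nuclei = 4L,
                      initial_apical_depth = c(8, 20),
                      motion_mix = c(active = 0, diffusive = 1, confined = 0),
                      noise = list(gaussian_sd = 0, poisson_scale = 0),
                      psf_sigma = c(0, 0, 0), rng_seed = 9L)
  tr <- generate_trajectories(cfg)
  sc <- render_volume(tr, background = 0)
  lab <- sc$labels$data[1, , , ]
  r <- cfg$nucleus_radii
  expected_vox <- (4 / 3) * pi * r[1] * r[2] * r[3] / prod(cfg$voxel_size)
  counts <- tabulate(lab[lab > 0L])
  expect_length(counts, 4L)
  # discretization error of a ~400-voxel ellipsoid stays below 10%
  expect_true(all(abs(counts - expected_vox) / expected_vox < 0.1))
  # zero PSF, zero noise: foreground intensity is exactly the label support
  img <- sc$volume$data[1, , , ]
  expect_identical(img > 0, lab > 0L)
})

test_that("an empty scene renders pure noise with all-zero labels", {
  cfg <- scene_config(n_frames = 2L, n_nuclei = 0L,
                      noise = list(gaussian_sd = 0.1, poisson_scale = 0),
                      rng_seed = 3L)
  sc <- render_volume(expect_silent(generate_trajectories(cfg)))
  expect_true(all(sc$labels$data == 0L))
  expect_gt(sd(sc$volume$data[1, , , ]), 0)
})

test_that("frame-mean bleaching decay follows exp(-b t)", {
  b <- 0.002
  cfg <- scene_config(grid_shape = c(33L, 64L, 64L), n_frames = 6L,
                      n_nuclei = 4L, bleach_rate = b,
                      noise = list(gaussian_sd = 0.01, poisson_scale = 0),
                      motion_mix = c(active = 0, diffusive = 0, confined = 1),
                      confinement_radius = 0.05, rng_seed = 4L)
  sc <- render_volume(generate_trajectories(cfg))
  mu <- vapply(1:6, function(t) mean(sc$volume$data[t, , , ]), 0)
  tt <- (0:5) * cfg$frame_interval
  ratio <- mu / mu[1]
  # tolerance: 3 SE of the read noise on a frame mean, plus sub-voxel
  # rasterization jitter of the slowly jiggling nuclei
  se <- 0.01 / sqrt(length(sc$volume$data[1, , , ]))
  expect_true(all(abs(ratio - exp(-b * tt)) < 3 * se / mu[1] + 2e-3))
})

test_that("synthetic FRAP obeys the half-life identity, asymptote, and raw round trip", {
  cfg <- frap_truth_config(k = log(2) / 10, plateau = 0.8, noise_sd = 0,
                           n_timepoints = 200L)
  fs <- generate_frap(cfg)
  truth <- attr(fs, "truth")
  norm <- normalize_frap(fs)
  # round trip: normalization inverts the raw construction exactly
  expect_equal(norm$N, truth$n_clean, tolerance = 1e-12)
  n_at <- function(t) norm$N[abs(norm$times - t) < 1e-9]
  expect_equal(n_at(10), 0.8 / 2, tolerance = 1e-12)
  expect_equal(n_at(199), 0.8, tolerance = 1e-4)
  expect_equal(unique(norm$N[norm$prebleach]), 1, tolerance = 1e-12)
})

test_that("ROI fixtures have the painted region means and match brute-force enumeration", {
  px <- 0.2
  fx <- generate_roi_fixture(list(roi_disk(c(5, 5), 4)), values = 100,
                             size = c(50, 50), pixel_size = px,
                             background = 10)
  expect_equal(roi_mean(fx$img, roi_disk(c(5, 5), 4), px)$mean, 100)
  annulus_px <- roi_mask(fx$img, roi_disk(c(5, 5), 7), px) &
    !roi_mask(fx$img, roi_disk(c(5, 5), 4), px)
  expect_equal(mean(fx$img[annulus_px]), 10)
  # two-level ring fixture vs exhaustive pixel enumeration
  theta <- seq(0, 2 * pi, length.out = 33)[-33]
  ring <- roi_ring(cbind(5 + 3 * cos(theta), 5 + 3 * sin(theta)),
                   stroke_px = 3)
  img2 <- fx$img
  img2[, 1:25] <- img2[, 1:25] * 2  # split the field into two levels
  got <- roi_mean(img2, ring, px)
  oracle <- brute_roi_mean(img2, ring, px)
  expect_equal(got$mean, oracle$mean, tolerance = 1e-12)
  expect_identical(got$n_pixels, oracle$n)
})
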