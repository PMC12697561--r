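# Median prefilter, apical-basal velocities, rolling MSD, gamma, activity.

test_that("the fifth-order median filter removes spikes and preserves ramps", {
  expect_equal(median_prefilter(rep(2.5, 20)), rep(2.5, 20),
               ignore_attr = TRUE)

  ramp <- seq(0, 10, length.out = 21)
  spiked <- ramp
  spiked[11] <- 50
  filt <- median_prefilter(spiked)
  # the spike is absorbed (a median of 5 tolerates 2 outliers); values near
  # the spike shift by at most one ramp step
  expect_true(all(filt < 12))
  expect_true(all(abs(filt[5:17] - ramp[5:17]) <= 0.5 + 1e-12))
  expect_equal(filt[c(5:8, 14:17)], ramp[c(5:8, 14:17)], ignore_attr = TRUE)

  # alternating +-eps noise on a ramp: interior equals the ramp exactly
  noisy <- ramp + 0.05 * rep_len(c(1, -1), 21)
  # median of 5 consecutive = middle ramp value + eps with majority sign;
  # the median element is the one matching the center's sign
  filt2 <- median_prefilter(noisy)
  expect_equal(filt2[3:19], noisy[3:19], ignore_attr = TRUE)

  expect_warning(median_prefilter(c(1, 2, 3)), "unfiltered")
})

test_that("a constant-velocity depth series yields the programmed speed in every 1-min window", {
  t_s <- seq(0, 600, by = 15)
  sp <- ab_velocity(t_s, 2 + 0.44 * t_s / 60)
  expect_equal(sp$speed_um_min, rep(0.44, nrow(sp)), tolerance = 1e-6)

  still <- ab_velocity(t_s, rep(5, length(t_s)))$speed_um_min
  expect_equal(still, rep(0, length(still)), tolerance = 1e-12)

  # triangular depth: peak equals |slope|, mean is below the peak
  z <- c(seq(0, 5, by = 0.25), seq(4.75, 0, by = -0.25))
  tt <- seq_along(z) * 15
  sp2 <- ab_velocity(tt, z)
  expect_equal(max(sp2$speed_um_min), 0.25 / 15 * 60, tolerance = 1e-9)
  expect_lt(mean(sp2$speed_um_min), max(sp2$speed_um_min))

  expect_error(ab_velocity(c(0, 15, 40), c(0, 1, 2)), "uniform")
})

test_that("rolling MSD matches the ballistic and stationary closed forms", {
  cfgm <- msd_window_config(W = 15)
  v <- 0.5 / 60  # um/s
  dt <- 15
  pos <- v * dt * (0:29)
  msd <- rolling_msd(pos, cfgm)
  for (tau in 1:14)
    expect_equal(msd[, tau], rep((v * dt * tau)^2, nrow(msd)),
                 tolerance = 1e-12)

  expect_true(all(rolling_msd(rep(1, 20), cfgm) == 0))
})

test_that("ensemble Brownian MSD is linear with slope 2 d D dt", {
  d_coef <- 0.1
  tt <- class_trajectories("diffusive", n = 60, n_frames = 200, loc_noise = 0,
                           seed = 6)
  cfgm <- msd_window_config(W = 15)
  # ensemble over all windows and nuclei, z axis only (d = 1)
  acc <- matrix(0, 0, 14)
  for (id in unique(tt$track_id))
    acc <- rbind(acc, rolling_msd(tt$z_um[tt$track_id == id], cfgm))
  m <- colMeans(acc)
  tau_min <- (1:14) * 15 / 60
  expected <- 2 * 1 * d_coef * tau_min
  expect_true(all(abs(m - expected) / expected < 0.15))
})

test_that("the log-log gamma estimator is exact on power laws and scale-invariant", {
  cfgm <- msd_window_config(W = 15)
  for (g in c(0, 0.5, 1, 1.5, 2)) {
    msd <- 3.7 * (1:14)^g
    expect_lt(abs(fit_gamma(msd, cfgm) - g), 1e-9)
    expect_lt(abs(fit_gamma(msd * 1e4, cfgm) - g), 1e-12)
  }
  # nonpositive MSD in the lag range leaves gamma undefined
  bad <- 3.7 * (1:14)
  bad[6] <- 0
  expect_true(is.na(fit_gamma(bad, cfgm)))
})

test_that("activity calls follow the gamma > 1 power-law criterion", {
  expect_true(classify_active(rep(2, 30), min_run = 5)$active)
  expect_identical(classify_active(rep(2, 30), min_run = 5)$intervals,
                   data.frame(start = 1L, end = 30L))
  expect_false(classify_active(rep(0.5, 30), min_run = 5)$active)
  expect_false(classify_active(c(rep(0.4, 10), 1.5, rep(0.4, 10)),
                               min_run = 2)$active)
  pa <- percent_active(list(rep(2, 20), rep(0.3, 20)), min_run = 2)
  expect_equal(as.numeric(pa), 50)
  expect_identical(attr(pa, "n_analyzable"), 2L)
})

test_that("percent active is non-decreasing in the generative active fraction", {
  got <- vapply(c(0, 0.5, 1), function(fa) {
    cfg <- scene_config(grid_shape = c(33L, 256L, 256L), n_frames = 60L,
                        n_nuclei = 40L, frame_interval = 15,
                        run_speed = 0.5, pause_dwell = 0,
                        motion_mix = c(active = fa, diffusive = 0,
                                       confined = 1 - fa),
                        rng_seed = 8L)
    tt <- trajectory_table(generate_trajectories(cfg), loc_noise_sd = 0.05)
    as.numeric(analyze_motion(tt)$percent_active)
  }, 0)
  expect_true(all(diff(got) >= 0))
  expect_lt(got[1], 15)
  expect_gt(got[3], 85)
})
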