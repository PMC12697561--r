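# ROI quantitation: means, annulus correction, bleach correction, line scans,
# t0 normalization, ROUT-style outlier removal.

test_that("ROI means equal brute-force pixel enumeration", {
  px <- 0.25
  set.seed(2)
  img <- matrix(runif(40 * 40, 10, 200), 40, 40)

  disk <- roi_disk(c(5, 5), 3.3)
  rect <- roi_rect(c(1.1, 2.2), c(4, 2.5))
  theta <- seq(0, 2 * pi, length.out = 25)[-25]
  ring <- roi_ring(cbind(5 + 2.5 * cos(theta), 5 + 2.5 * sin(theta)))
  for (roi in list(disk, rect, ring)) {
    got <- roi_mean(img, roi, px)
    oracle <- brute_roi_mean(img, roi, px)
    expect_equal(got$mean, oracle$mean, tolerance = 1e-12)
    expect_equal(got$integrated_density, oracle$sum, tolerance = 1e-12)
    expect_identical(got$n_pixels, oracle$n)
  }

  expect_equal(roi_mean(matrix(7, 40, 40), disk, px)$mean, 7)
  expect_error(roi_mean(img, roi_disk(c(50, 50), 0.1), px), "no pixel")
})

test_that("t0 normalization divides by the baseline and has mean 1 at t0", {
  means <- c(110, 110, 110, 60, 35)
  is_t0 <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  n <- background_subtract_normalize(means, background = 10, is_t0 = is_t0)
  expect_equal(mean(n[is_t0]), 1, tolerance = 1e-12)
  expect_equal(n[4], 0.5)
  expect_equal(background_subtract_normalize(c(110, 10), 10,
                                             c(TRUE, FALSE))[2], 0)
  # linearity: doubling signal-above-background (baseline fixed) doubles
  m2 <- means
  m2[!is_t0] <- 10 + 2 * (means[!is_t0] - 10)
  n2 <- background_subtract_normalize(m2, 10, is_t0)
  expect_equal(n2[!is_t0], 2 * n[!is_t0], tolerance = 1e-12)
  expect_error(background_subtract_normalize(c(5, 5), 10, c(TRUE, FALSE)),
               "baseline")
})

test_that("the annulus correction cancels uniform and graded backgrounds", {
  px <- 0.168
  img <- matrix(50, 60, 60)
  r <- annulus_corrected_mean(img, c(5, 5), px)
  expect_equal(r$corrected_mean, 0, tolerance = 1e-12)

  # bright spot confined to the small disk on a uniform background
  spot <- roi_mask(img, roi_disk(c(5, 5), 15 * px), px)
  img2 <- img
  img2[spot] <- 300
  r2 <- annulus_corrected_mean(img2, c(5, 5), px)
  expect_equal(r2$corrected_mean, r2$mean_small - 50, tolerance = 1e-12)
  expect_equal(r2$background, 50, tolerance = 1e-12)

  # graded background: verify against brute-force integrated densities
  img3 <- outer(seq_len(60), seq_len(60), function(i, j) 20 + 0.7 * j + 0.3 * i)
  small <- roi_disk(c(5, 5), 15 * px)
  large <- roi_disk(c(5, 5), 25 * px)
  os <- brute_roi_mean(img3, small, px)
  ol <- brute_roi_mean(img3, large, px)
  oracle <- os$mean - (ol$sum - os$sum) / (ol$n - os$n)
  r3 <- annulus_corrected_mean(img3, c(5, 5), px)
  expect_equal(r3$corrected_mean, oracle, tolerance = 1e-9)

  # invariance to a constant offset over the whole image
  r4 <- annulus_corrected_mean(img3 + 1000, c(5, 5), px)
  expect_equal(r4$corrected_mean, r3$corrected_mean, tolerance = 1e-9)

  expect_error(annulus_corrected_mean(img, c(5, 5), px, d_small_px = 25,
                                      d_large_px = 15), "exceed")
})

test_that("exponential bleach correction inverts a generative decay", {
  set.seed(3)
  base <- matrix(runif(900, 50, 150), 30, 30)
  b <- 0.03
  frames <- lapply(0:9, function(t) base * exp(-b * t))
  bc <- bleach_correct(frames)
  expect_identical(bc$method, "exponential")
  mus <- vapply(bc$frames, mean, 0)
  expect_equal(mus, rep(mean(base), 10), tolerance = 1e-6 * mean(base))

  # a static bright spot stays constant after correction
  spotted <- lapply(0:9, function(t) {
    f <- base
    f[10:12, 10:12] <- 400
    f * exp(-b * t)
  })
  bc2 <- bleach_correct(spotted)
  spots <- vapply(bc2$frames, function(f) mean(f[10:12, 10:12]), 0)
  expect_equal(spots, rep(400, 10), tolerance = 1e-4 * 400)

  # no decay: identity
  bc3 <- bleach_correct(lapply(1:6, function(i) base))
  expect_equal(vapply(bc3$frames, mean, 0), rep(mean(base), 6),
               tolerance = 1e-9 * mean(base))

  expect_error(bleach_correct(frames[1:3]), ">= 5 frames")
})

test_that("line scans are flat on uniform images and peak at generative stripe centers", {
  px <- 0.5
  img <- matrix(5, 40, 40)
  p <- line_scan(img, c(2, 10), c(18, 10), px)
  expect_true(all(p$mean == 5))

  # two vertical stripes crossed perpendicularly
  img2 <- img
  img2[, 12] <- 100  # center x = 5.75 um
  img2[, 28] <- 80   # center x = 13.75 um
  p2 <- line_scan(img2, c(0.25, 10.25), c(19.75, 10.25), px, width_px = 3)
  peaks <- p2$distance_um[order(p2$mean, decreasing = TRUE)[1:2]] + 0.25
  expect_lt(abs(sort(peaks)[1] - 5.75), px + 1e-9)
  expect_lt(abs(sort(peaks)[2] - 13.75), px + 1e-9)
})

test_that("ROUT-style removal flags gross outliers but spares clean samples", {
  set.seed(11)
  clean <- rnorm(100)
  r <- remove_outliers_rout(clean, Q = 0.01)
  expect_true(r$applied)
  expect_gte(length(r$kept), 98L)

  spiked <- c(rnorm(50), 10)   # one 10-SD spike
  r2 <- remove_outliers_rout(spiked, Q = 0.01)
  expect_true(10 %in% r2$outliers)
  expect_false(10 %in% r2$kept)

  same <- rep(3.3, 25)
  r3 <- remove_outliers_rout(same)
  expect_length(r3$outliers, 0L)

  small <- rnorm(5)
  r4 <- remove_outliers_rout(small)
  expect_false(r4$applied)
  expect_identical(r4$kept, small)
})

test_that("false-positive removals stay below 2 Q n on clean Gaussian data", {
  worst <- 0L
  for (i in 1:100) {
    set.seed(2000L + i)
    r <- remove_outliers_rout(rnorm(100), Q = 0.01)
    worst <- max(worst, length(r$outliers))
  }
  expect_lte(worst, 2L)  # 2 * Q * n = 2 at n = 100
})
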