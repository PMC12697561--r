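# Shared fixture builders. Everything is generated in code at test time.

# single-class trajectory table under the standard study conditions
class_trajectories <- function(class, n = 100, n_frames = 60, dt = 15,
                               speed = 0.5, loc_noise = 0.05, seed = 42,
                               pause_dwell = 0) {
  mix <- c(active = 0, diffusive = 0, confined = 0)
  mix[class] <- 1
  cfg <- scene_config(grid_shape = c(33L, 256L, 256L), n_frames = n_frames,
                      n_nuclei = n, frame_interval = dt, run_speed = speed,
                      pause_dwell = pause_dwell, motion_mix = mix,
                      rng_seed = seed)
  trajectory_table(generate_trajectories(cfg), loc_noise_sd = loc_noise)
}

# rasterized ball in a cubic grid, radius in voxels (voxel-center inclusion)
raster_ball <- function(dim3, center, radius) {
  a <- array(FALSE, dim3)
  iz <- seq_len(dim3[1]); iy <- seq_len(dim3[2]); ix <- seq_len(dim3[3])
  d2 <- outer(outer((iz - center[1])^2, (iy - center[2])^2, `+`),
              (ix - center[3])^2, `+`)
  a[d2 <= radius^2] <- TRUE
  a
}

# brute-force ROI mean oracle: enumerate every pixel center
brute_roi_mean <- function(img, roi, pixel_size) {
  vals <- c()
  for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img))) {
    x <- (j - 0.5) * pixel_size
    y <- (i - 0.5) * pixel_size
    inside <- switch(roi$kind,
      disk = (x - roi$center[1])^2 + (y - roi$center[2])^2 <=
        (roi$diameter / 2)^2,
      rect = x >= roi$corner[1] & x <= roi$corner[1] + roi$extent[1] &
        y >= roi$corner[2] & y <= roi$corner[2] + roi$extent[2],
      ring = {
        d <- nucdyn:::dist_to_contour(x, y, roi$contour)
        d <= roi$stroke_px * pixel_size / 2
      })
    if (inside) vals <- c(vals, img[i, j])
  }
  list(mean = mean(vals), n = length(vals), sum = sum(vals))
}
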