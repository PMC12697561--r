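# Rasterization of synthetic scenes into intensity and label volumes.

# Voxel-center coordinates along one axis: index i (1-based) -> (i-1)*step um.
axis_centers <- function(n, step) (seq_len(n) - 1) * step

#' Rasterize ground-truth nuclei into a label volume
#'
#' Paints each nucleus as a solid ellipsoid (voxel-center inclusion) with its
#' integer id. Where two nuclei overlap, the voxel goes to the nucleus whose
#' normalized ellipsoid distance is smallest, and the overlap is flagged.
#'
#' @param truth a `synthetic_truth`.
#' @param frames frame indices to rasterize (default all).
#' @param grid_shape,voxel_size grid to rasterize on; default the scene's.
#' @return `label_volume` with attribute `overlaps` (data.frame frame,
#'   n_overlap_voxels).
#' @export
rasterize_labels <- function(truth, frames = NULL,
                             grid_shape = truth$config$grid_shape,
                             voxel_size = truth$config$voxel_size) {
  cfg <- truth$config
  if (is.null(frames)) frames <- seq_len(cfg$n_frames)
  nz <- grid_shape[1]; ny <- grid_shape[2]; nx <- grid_shape[3]
  rz <- cfg$nucleus_radii[1]; ry <- cfg$nucleus_radii[2]
  rx <- cfg$nucleus_radii[3]
  zc <- axis_centers(nz, voxel_size[1])
  yc <- axis_centers(ny, voxel_size[2])
  xc <- axis_centers(nx, voxel_size[3])

  out <- array(0L, c(length(frames), nz, ny, nx))
  ov <- data.frame(frame = frames, n_overlap_voxels = 0L)

  for (fi in seq_along(frames)) {
    f <- frames[fi]
    lab <- array(0L, c(nz, ny, nx))
    best <- array(Inf, c(nz, ny, nx))
    rows <- truth$positions[truth$positions$frame == f, ]
    for (r in seq_len(nrow(rows))) {
      cx <- rows$x_um[r]; cy <- rows$y_um[r]; cz <- rows$z_um[r]
      iz <- which(abs(zc - cz) <= rz)
      iy <- which(abs(yc - cy) <= ry)
      ix <- which(abs(xc - cx) <= rx)
      if (!length(iz) || !length(iy) || !length(ix)) next
      dz2 <- ((zc[iz] - cz) / rz)^2
      dy2 <- ((yc[iy] - cy) / ry)^2
      dx2 <- ((xc[ix] - cx) / rx)^2
      d2 <- outer(outer(dz2, dy2, `+`), dx2, `+`)
      inside <- d2 <= 1
      if (!any(inside)) next
      sub_lab <- lab[iz, iy, ix, drop = FALSE]
      sub_best <- best[iz, iy, ix, drop = FALSE]
      ov$n_overlap_voxels[fi] <- ov$n_overlap_voxels[fi] +
        sum(inside & sub_lab > 0L)
      take <- inside & d2 < sub_best
      sub_lab[take] <- rows$id[r]
      sub_best[take] <- d2[take]
      lab[iz, iy, ix] <- sub_lab
      best[iz, iy, ix] <- sub_best
    }
    out[fi, , , ] <- lab
  }
  res <- label_volume(out, voxel_size, cfg$frame_interval)
  attr(res, "overlaps") <- ov
  res
}

#' Render a synthetic scene into an intensity volume series
#'
#' Rasterizes the ground-truth nuclei as unit-amplitude ellipsoids on a dim
#' background, blurs with a Gaussian PSF, applies optional exponential
#' photobleaching `exp(-bleach_rate * t)`, then corrupts with the configured
#' Poisson shot noise and additive Gaussian read noise (clipped at 0). The
#' paired ground-truth labels are returned unblurred and noise-free.
#'
#' @param truth a `synthetic_truth` from [generate_trajectories()].
#' @param config scene configuration; defaults to the one stored in `truth`.
#' @param background background intensity level (fraction of the nuclear
#'   amplitude, which is 1).
#' @return list with `volume` (a `volume_series`), `labels` (a
#'   `label_volume`), and `overlaps` (per-frame overlap voxel counts).
#' @export
render_volume <- function(truth, config = truth$config, background = 0.05) {
  validate_scene_config(config)
  labs <- rasterize_labels(truth, grid_shape = config$grid_shape,
                           voxel_size = config$voxel_size)
  nt <- dim(labs$data)[1]
  dims <- dim(labs$data)[2:4]
  sig_vox <- config$psf_sigma / config$voxel_size
  data <- array(0, c(nt, dims))

  with_seed(config$rng_seed + 7L, {
    for (f in seq_len(nt)) {
      img <- array(background, dims)
      img[labs$data[f, , , ] > 0L] <- background + 1
      if (any(sig_vox > 0)) img <- gauss_blur3(img, sig_vox)
      if (config$bleach_rate > 0)
        img <- img * exp(-config$bleach_rate * (f - 1) * config$frame_interval)
      if (config$noise$poisson_scale > 0) {
        sc <- config$noise$poisson_scale
        img <- array(rpois(length(img), pmax(img, 0) * sc) / sc, dims)
      }
      if (config$noise$gaussian_sd > 0)
        img <- img + array(rnorm(length(img), 0, config$noise$gaussian_sd),
                           dims)
      data[f, , , ] <- pmax(img, 0)
    }
  })

  list(volume = volume_series(data, config$voxel_size, config$frame_interval),
       labels = labs,
       overlaps = attr(labs, "overlaps"))
}
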