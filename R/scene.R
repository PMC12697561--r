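#' Configuration of a synthetic epithelium scene
#'
#' Defines the generative conditions for a synthetic columnar-epithelium
#' time-lapse: grid geometry, nuclear sizes, the mixture of motion classes,
#' imaging noise and optics. Defaults emulate the germband-extension stage:
#' cells about 32 um deep, nuclei starting in a common apical plane, active
#' nuclei moving basally in runs interspersed with pauses at a mean speed of
#' roughly 0.4-0.5 um/min, anisotropic voxels (fine xy, 1 um z) and
#' spinning-disk-like noise.
#'
#' @param grid_shape integer (nz, ny, nx) voxels.
#' @param voxel_size (dz, dy, dx) in um.
#' @param frame_interval seconds between frames.
#' @param n_frames number of frames (>= 2).
#' @param n_nuclei number of nuclei.
#' @param cell_height apical-basal cell height in um; trajectories are
#'   reflected into `[0, cell_height]`.
#' @param nucleus_radii ellipsoid semi-axes (rz, ry, rx) in um.
#' @param initial_apical_depth starting depth of nuclear centers (um below
#'   the apical surface): a single value for a common apical plane (jittered
#'   by 0.5 um), or a length-2 range for uniformly dispersed depths.
#' @param motion_mix named fractions for classes `active`, `diffusive`,
#'   `confined`; must sum to 1.
#' @param run_speed basal run speed of active nuclei, um/min.
#' @param run_dwell,pause_dwell mean dwell times (s) of the run and pause
#'   states of active nuclei; `pause_dwell = 0` gives uninterrupted
#'   constant-velocity runs.
#' @param diffusion_coeff diffusion coefficient of diffusive nuclei and of the
#'   in-plane jitter, um^2/min.
#' @param confinement_radius radius (um) bounding confined nuclei (2 SD of
#'   the stationary mean-reverting walk).
#' @param noise list with `gaussian_sd` (additive read noise, fraction of the
#'   unit nuclear amplitude) and `poisson_scale` (photons per intensity unit;
#'   0 disables shot noise).
#' @param psf_sigma Gaussian PSF sigma (z, y, x) in um.
#' @param bleach_rate exponential photobleaching rate, 1/s (0 = none).
#' @param rng_seed integer seed; identical seeds give bit-identical scenes.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(grid_shape = c(33L, 128L, 128L),
                         voxel_size = c(1, 0.5, 0.5),
                         frame_interval = 15,
                         n_frames = 2L,
                         n_nuclei = 12L,
                         cell_height = 32,
                         nucleus_radii = c(2.5, 2.2, 2.2),
                         initial_apical_depth = 4,
                         motion_mix = c(active = 0.7, diffusive = 0.15,
                                        confined = 0.15),
                         run_speed = 0.7,
                         run_dwell = 90,
                         pause_dwell = 45,
                         diffusion_coeff = 0.1,
                         confinement_radius = 0.5,
                         noise = list(gaussian_sd = 0.1, poisson_scale = 0),
                         psf_sigma = c(0.9, 0.35, 0.35),
                         bleach_rate = 0,
                         rng_seed = 1L) {
  cfg <- list(grid_shape = as.integer(grid_shape),
              voxel_size = as.numeric(voxel_size),
              frame_interval = as.numeric(frame_interval),
              n_frames = as.integer(n_frames),
              n_nuclei = as.integer(n_nuclei),
              cell_height = as.numeric(cell_height),
              nucleus_radii = as.numeric(nucleus_radii),
              initial_apical_depth = as.numeric(initial_apical_depth),
              motion_mix = motion_mix,
              run_speed = as.numeric(run_speed),
              run_dwell = as.numeric(run_dwell),
              pause_dwell = as.numeric(pause_dwell),
              diffusion_coeff = as.numeric(diffusion_coeff),
              confinement_radius = as.numeric(confinement_radius),
              noise = noise,
              psf_sigma = as.numeric(psf_sigma),
              bleach_rate = as.numeric(bleach_rate),
              rng_seed = as.integer(rng_seed))
  validate_scene_config(cfg)
  structure(cfg, class = "scene_config")
}

validate_scene_config <- function(cfg) {
  if (length(cfg$grid_shape) != 3L || any(cfg$grid_shape < 1L))
    stop("grid_shape must be 3 positive integers (nz, ny, nx)", call. = FALSE)
  if (length(cfg$voxel_size) != 3L || any(cfg$voxel_size <= 0))
    stop("voxel_size must be 3 positive lengths (dz, dy, dx)", call. = FALSE)
  if (cfg$n_frames < 2L) stop("n_frames must be >= 2", call. = FALSE)
  if (cfg$n_nuclei < 0L) stop("n_nuclei must be >= 0", call. = FALSE)
  stopifnot_scalar(cfg$cell_height, "cell_height")
  stopifnot_scalar(cfg$frame_interval, "frame_interval")
  if (length(cfg$nucleus_radii) != 3L || any(cfg$nucleus_radii <= 0))
    stop("nucleus_radii must be 3 positive lengths (rz, ry, rx)", call. = FALSE)
  mm <- cfg$motion_mix
  if (is.null(names(mm)) ||
      !setequal(names(mm), c("active", "diffusive", "confined")))
    stop("motion_mix must name fractions active, diffusive, confined",
         call. = FALSE)
  if (abs(sum(mm) - 1) > 1e-8)
    stop("motion_mix fractions must sum to 1", call. = FALSE)
  if (any(mm < 0)) stop("motion_mix fractions must be >= 0", call. = FALSE)
  if (cfg$run_speed < 0 || cfg$diffusion_coeff < 0 ||
      cfg$confinement_radius <= 0)
    stop("kinetic parameters must be non-negative (confinement_radius > 0)",
         call. = FALSE)
  if (cfg$noise$gaussian_sd < 0 || cfg$noise$poisson_scale < 0)
    stop("noise parameters must be >= 0", call. = FALSE)
  if (any(cfg$psf_sigma < 0)) stop("psf_sigma must be >= 0", call. = FALSE)
  if (cfg$bleach_rate < 0) stop("bleach_rate must be >= 0", call. = FALSE)
  # lateral clearance at t = 0 so no nucleus clips the xy boundary
  ry <- cfg$nucleus_radii[2]; rx <- cfg$nucleus_radii[3]
  if (cfg$n_nuclei > 0 &&
      (cfg$grid_shape[2] * cfg$voxel_size[2] <= 2 * ry ||
       cfg$grid_shape[3] * cfg$voxel_size[3] <= 2 * rx))
    stop("grid too small to hold a nucleus laterally", call. = FALSE)
  invisible(cfg)
}

#' @export
print.scene_config <- function(x, ...) {
  cat(sprintf(
    "<scene_config> %d nuclei, %d frames @ %.3gs, grid %s vox of %s um, mix a/d/c = %s\n",
    x$n_nuclei, x$n_frames, x$frame_interval,
    paste(x$grid_shape, collapse = "x"),
    paste(signif(x$voxel_size, 3), collapse = "x"),
    paste(signif(x$motion_mix[c("active", "diffusive", "confined")], 3),
          collapse = "/")))
  invisible(x)
}
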