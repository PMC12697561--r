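# Ground-truth nuclear trajectories for synthetic scenes.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

motion_class_counts <- function(mix, n) {
  mix <- mix[c("active", "diffusive", "confined")]
  cum <- round(cumsum(mix) * n)
  counts <- diff(c(0, cum))
  names(counts) <- names(mix)
  counts
}

reflect_interval <- function(x, lo, hi) {
  span <- hi - lo
  y <- (x - lo) %% (2 * span)
  lo + ifelse(y > span, 2 * span - y, y)
}

#' Generate ground-truth nuclear trajectories
#'
#' Simulates one trajectory per nucleus according to its motion class. Active
#' nuclei alternate between basally directed constant-velocity runs, pauses
#' and short diffusive interludes (a 3-state process with exponential dwell
#' times); diffusive nuclei follow an isotropic Gaussian random walk; confined
#' nuclei follow a mean-reverting (Ornstein-Uhlenbeck) walk bounded by the
#' confinement radius. Depth is measured positive basally from the apical
#' surface (z = 0) and trajectories reflect at z = 0 and at `cell_height`.
#'
#' @param config a [scene_config()].
#' @return An object of class `synthetic_truth`: list with `positions` (long
#'   data.frame: id, class, frame, t_s, x_um, y_um, z_um), `nuclei`
#'   (id, class, start positions), and the echoed `config`.
#' @export
generate_trajectories <- function(config) {
  validate_scene_config(config)
  n <- config$n_nuclei
  nt <- config$n_frames
  dt_s <- config$frame_interval
  dt_min <- dt_s / 60
  H <- config$cell_height

  counts <- motion_class_counts(config$motion_mix, n)
  classes <- rep(names(counts), counts)

  with_seed(config$rng_seed, {
    # jittered lateral grid with one-radius clearance from the boundary
    Ly <- config$grid_shape[2] * config$voxel_size[2]
    Lx <- config$grid_shape[3] * config$voxel_size[3]
    ry <- config$nucleus_radii[2]; rx <- config$nucleus_radii[3]
    if (n > 0) {
      ncol <- ceiling(sqrt(n))
      nrow <- ceiling(n / ncol)
      gx <- seq(rx * 1.2, Lx - rx * 1.2, length.out = max(ncol, 2))[seq_len(ncol)]
      gy <- seq(ry * 1.2, Ly - ry * 1.2, length.out = max(nrow, 2))[seq_len(nrow)]
      grid <- expand.grid(x = gx, y = gy)[seq_len(n), ]
      x0 <- grid$x + rnorm(n, 0, 0.15)
      y0 <- grid$y + rnorm(n, 0, 0.15)
      dep <- config$initial_apical_depth
      z0 <- if (length(dep) == 2L) runif(n, dep[1], dep[2])
            else pmax(0.5, dep + rnorm(n, 0, 0.5))
    } else {
      x0 <- y0 <- z0 <- numeric(0)
    }

    pos <- array(NA_real_, c(nt, n, 3))  # (frame, nucleus, xyz)
    if (n > 0) pos[1, , ] <- cbind(x0, y0, z0)

    sd_diff <- sqrt(2 * config$diffusion_coeff * dt_min)  # per-axis step SD
    # confined walk: OU with relaxation time 30 s, stationary SD = radius / 2
    tau_c <- 30
    a_ou <- exp(-dt_s / tau_c)
    sd_ou <- config$confinement_radius / 2

    for (i in seq_len(n)) {
      cls <- classes[i]
      p <- pos[1, i, ]
      anchor <- p
      state <- "run"
      for (f in seq_len(nt - 1L)) {
        if (cls == "active") {
          if (state == "run") {
            p[3] <- p[3] + config$run_speed * dt_min
            p[1:2] <- p[1:2] + rnorm(2, 0, sd_diff / 2)
            if (config$pause_dwell > 0 &&
                runif(1) < 1 - exp(-dt_s / config$run_dwell))
              state <- if (runif(1) < 0.5) "pause" else "diffuse"
          } else {
            if (state == "diffuse") p <- p + rnorm(3, 0, sd_diff)
            if (runif(1) < 1 - exp(-dt_s / config$pause_dwell)) state <- "run"
          }
        } else if (cls == "diffusive") {
          p <- p + rnorm(3, 0, sd_diff)
        } else {  # confined
          p <- anchor + (p - anchor) * a_ou +
            rnorm(3, 0, sd_ou * sqrt(1 - a_ou^2))
        }
        p[3] <- reflect_interval(p[3], 0, H)
        pos[f + 1L, i, ] <- p
      }
    }

    positions <- data.frame(
      id = rep(seq_len(n), each = nt),
      class = rep(classes, each = nt),
      frame = rep(seq_len(nt), times = n),
      t_s = rep((seq_len(nt) - 1L) * dt_s, times = n),
      x_um = as.vector(pos[, , 1]),
      y_um = as.vector(pos[, , 2]),
      z_um = as.vector(pos[, , 3]),
      stringsAsFactors = FALSE)
    if (n == 0) positions <- positions[0, ]

    structure(
      list(positions = positions,
           nuclei = data.frame(id = seq_len(n), class = classes,
                               x0 = x0, y0 = y0, z0 = z0),
           config = config),
      class = "synthetic_truth")
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> %d nuclei x %d frames (%s)\n",
              nrow(x$nuclei), x$config$n_frames,
              paste(names(table(x$nuclei$class)), table(x$nuclei$class),
                    sep = ":", collapse = ", ")))
  invisible(x)
}

#' Observed trajectory table with localization noise
#'
#' Converts ground-truth positions into the measured trajectory table consumed
#' by the motion metrics (columns track_id, t_s, z_um, x_um, y_um), optionally
#' adding Gaussian localization noise to every coordinate, emulating the
#' centroid/midplane estimation error of the segmentation stage.
#'
#' @param truth a `synthetic_truth`.
#' @param loc_noise_sd localization noise SD in um (0 = exact positions).
#' @param rng_seed seed for the noise draw.
#' @return data.frame with one row per nucleus per frame.
#' @export
trajectory_table <- function(truth, loc_noise_sd = 0,
                             rng_seed = truth$config$rng_seed + 1L) {
  p <- truth$positions
  out <- data.frame(track_id = p$id, t_s = p$t_s, z_um = p$z_um,
                    x_um = p$x_um, y_um = p$y_um, class = p$class,
                    stringsAsFactors = FALSE)
  if (loc_noise_sd > 0) {
    with_seed(rng_seed, {
      m <- nrow(out)
      out$z_um <- out$z_um + rnorm(m, 0, loc_noise_sd)
      out$x_um <- out$x_um + rnorm(m, 0, loc_noise_sd)
      out$y_um <- out$y_um + rnorm(m, 0, loc_noise_sd)
    })
  }
  out
}
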