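# Nuclear kinematics: median prefilter, 1-min-window apical-basal velocities,
# rolling-window MSD, power-law exponent (gamma) fit, active-motion calls.

#' Rolling MSD window configuration
#'
#' The rolling window holds `W` (odd) consecutive trajectory points. The
#' power-law exponent is fitted to integer lags between 4 and
#' `floor(3 * (W - 1) / 4)` frames - the lower bound excludes the first three
#' lags, which are dominated by localization-noise artifacts at short time
#' scales. `W` must be at least 7 so the lag range is non-empty.
#'
#' @param W odd number of points per window (default 15; at 15-20 s sampling
#'   this spans roughly 4-5 minutes).
#' @param median_filter_order order of the trajectory median prefilter.
#' @param min_run minimum number of consecutive active windows that counts as
#'   an active interval. Adjacent rolling windows share W - 1 points, so
#'   spurious exponent flips come in correlated runs; the default equals W
#'   (one window-correlation length), i.e. sustained super-diffusivity over
#'   about one full window span. Results for `min_run = 1` are reported
#'   alongside.
#' @return object of class `msd_window_config` with derived `lag_min`,
#'   `lag_max`.
#' @export
msd_window_config <- function(W = 15L, median_filter_order = 5L,
                              min_run = W) {
  W <- as.integer(W)
  if (W %% 2L == 0L) stop("W must be odd", call. = FALSE)
  if (W < 7L) stop("W must be >= 7 so that lag_max >= lag_min", call. = FALSE)
  structure(list(W = W, lag_min = 4L, lag_max = as.integer(floor(3 * (W - 1) / 4)),
                 median_filter_order = as.integer(median_filter_order),
                 min_run = as.integer(min_run)),
            class = "msd_window_config")
}

#' Median prefilter of a trajectory
#'
#' Sliding median of odd order (default 5) applied per coordinate to remove
#' localization spikes before MSD analysis; edges are padded by repeating the
#' end values. Trajectories shorter than the filter order are returned
#' unfiltered with attribute `filtered = FALSE`.
#'
#' @param x numeric vector or matrix (rows = time points).
#' @param order odd window length.
#' @return filtered object of the same shape, attribute `filtered`.
#' @export
median_prefilter <- function(x, order = 5L) {
  if (order %% 2L == 0L) stop("filter order must be odd", call. = FALSE)
  one <- function(v) {
    n <- length(v)
    if (n < order) return(v)
    r <- (order - 1L) %/% 2L
    pad <- c(rep(v[1], r), v, rep(v[n], r))
    vapply(seq_len(n), function(i) median(pad[i:(i + order - 1L)]), 0)
  }
  if (is.matrix(x)) {
    out <- apply(x, 2, one)
    attr(out, "filtered") <- nrow(x) >= order
  } else {
    out <- one(x)
    attr(out, "filtered") <- length(x) >= order
  }
  if (!attr(out, "filtered"))
    warning("trajectory shorter than filter order; returned unfiltered",
            call. = FALSE)
  out
}

#' Apical-basal velocity over a sliding 1-minute window
#'
#' Central-difference displacement of the depth coordinate over a time window
#' (default 60 s), in um/min: `v(t) = (z(t + w/2) - z(t - w/2)) / w`. Sampling
#' must be uniform; the window is rounded to the nearest even number of
#' frames.
#'
#' @param t_s times in seconds (uniformly sampled).
#' @param z_um depth series in um.
#' @param window_s window width in seconds.
#' @return data.frame: t_s (window centers), velocity_um_min (signed, basal
#'   positive), speed_um_min.
#' @export
ab_velocity <- function(t_s, z_um, window_s = 60) {
  n <- length(t_s)
  if (n < 2) stop("need >= 2 samples", call. = FALSE)
  dt <- diff(t_s)
  if (max(abs(dt - dt[1])) > 1e-6 * dt[1])
    stop("sampling must be uniform", call. = FALSE)
  dt <- dt[1]
  h <- max(1L, as.integer(round(window_s / (2 * dt))))
  if (n < 2L * h + 1L)
    stop("trajectory shorter than the velocity window", call. = FALSE)
  i <- (h + 1L):(n - h)
  v <- (z_um[i + h] - z_um[i - h]) / (2 * h * dt) * 60
  data.frame(t_s = t_s[i], velocity_um_min = v, speed_um_min = abs(v))
}

#' Rolling-window time-averaged MSD
#'
#' For every window of `W` consecutive points, the time-averaged MSD at lag
#' `tau` frames is the mean squared displacement over all overlapping pairs
#' inside the window, summed over the supplied coordinates:
#' `MSD(tau) = mean_i |p(i + tau) - p(i)|^2`, `tau = 1 .. W - 1`.
#'
#' @param pos numeric vector (depth only) or matrix (columns = coordinates).
#' @param config an [msd_window_config()].
#' @return matrix of dim (n_windows, W - 1): `MSD[s, tau]` for the window
#'   starting at point `s`; units um^2, lag in frames. Attribute `centers`
#'   gives the window center indices.
#' @export
rolling_msd <- function(pos, config = msd_window_config()) {
  if (!is.matrix(pos)) pos <- matrix(pos, ncol = 1)
  n <- nrow(pos)
  W <- config$W
  if (n < W) stop("trajectory shorter than the MSD window", call. = FALSE)
  nwin <- n - W + 1L
  out <- matrix(NA_real_, nwin, W - 1L)
  for (tau in seq_len(W - 1L)) {
    sq <- rowSums((pos[(1L + tau):n, , drop = FALSE] -
                     pos[1L:(n - tau), , drop = FALSE])^2)
    cs <- c(0, cumsum(sq))
    m <- W - tau                       # pairs per window at this lag
    s <- seq_len(nwin)
    out[s, tau] <- (cs[s + m] - cs[s]) / m
  }
  attr(out, "centers") <- seq_len(nwin) + (W - 1L) %/% 2L
  out
}

#' Power-law exponent of an MSD curve
#'
#' Ordinary least-squares slope of `log MSD` versus `log tau` over the
#' configured integer lag range (4 to `floor(3(W-1)/4)`); a linear fit in log
#' space rather than a nonlinear power-law fit. Windows with any nonpositive
#' MSD in the range have no defined exponent (`NA`) and are excluded from
#' classification.
#'
#' @param msd numeric MSD vector indexed by lag (frames), or the matrix from
#'   [rolling_msd()] (one exponent per row).
#' @param config an [msd_window_config()].
#' @return numeric gamma (vector for a matrix input).
#' @export
fit_gamma <- function(msd, config = msd_window_config()) {
  lags <- config$lag_min:config$lag_max
  lx <- log(lags)
  lxc <- lx - mean(lx)
  den <- sum(lxc^2)
  one <- function(v) {
    y <- v[lags]
    if (any(!is.finite(y)) || any(y <= 0)) return(NA_real_)
    sum(lxc * log(y)) / den
  }
  if (is.matrix(msd)) apply(msd, 1, one) else one(msd)
}

#' Classify active motion from a gamma series
#'
#' A window is active when its exponent exceeds 1 (super-diffusive, upward
#' MSD curvature); an active interval is a run of at least `min_run`
#' consecutive active windows; a nucleus is active when it has at least one
#' active interval. Undefined exponents break runs. On trajectories shorter
#' than `min_run + W - 1` points the requirement is capped at the available
#' window count, i.e. every window must be active.
#'
#' @param gamma numeric gamma per window (NA allowed).
#' @param min_run minimum run length in windows.
#' @return list: `active` (scalar logical), `window_active` (logical vector),
#'   `intervals` (data.frame start, end in window indices), `analyzable`
#'   (any finite gamma).
#' @export
classify_active <- function(gamma, min_run = 2L) {
  min_run <- max(1L, min(as.integer(min_run), length(gamma)))
  act <- !is.na(gamma) & gamma > 1
  r <- rle(act)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  intervals <- data.frame(start = starts[keep], end = ends[keep])
  list(active = nrow(intervals) > 0L, window_active = act,
       intervals = intervals, analyzable = any(is.finite(gamma)))
}

#' Percent of nuclei with active-motion periods
#'
#' @param gamma_list list of per-nucleus gamma vectors.
#' @param min_run minimum run length defining an active interval.
#' @return percentage (0-100) of analyzable nuclei with at least one active
#'   interval; attribute `n_analyzable`.
#' @export
percent_active <- function(gamma_list, min_run = 2L) {
  cls <- lapply(gamma_list, classify_active, min_run = min_run)
  ok <- vapply(cls, `[[`, TRUE, "analyzable")
  if (!any(ok)) {
    out <- NA_real_
    attr(out, "n_analyzable") <- 0L
    return(out)
  }
  act <- vapply(cls[ok], `[[`, TRUE, "active")
  out <- 100 * mean(act)
  attr(out, "n_analyzable") <- sum(ok)
  out
}

#' Per-nucleus motion analysis of a trajectory table
#'
#' Runs the full kinematic chain per track: fifth-order median prefilter of
#' the depth series, rolling-window MSD and gamma over the depth coordinate,
#' active classification, and 1-minute-window speeds (each nucleus
#' contributes one mean and one peak speed).
#'
#' @param traj data.frame with columns track_id, t_s, z_um.
#' @param config an [msd_window_config()].
#' @param velocity_window_s speed window, s.
#' @return list: `per_window` (track_id, window center frame, gamma, active),
#'   `per_track` (track_id, mean_speed_um_min, peak_speed_um_min, active,
#'   analyzable), `percent_active`.
#' @export
analyze_motion <- function(traj, config = msd_window_config(),
                           velocity_window_s = 60) {
  stopifnot(all(c("track_id", "t_s", "z_um") %in% names(traj)))
  per_window <- list()
  per_track <- list()
  gammas <- list()
  for (id in unique(traj$track_id)) {
    tr <- traj[traj$track_id == id, ]
    tr <- tr[order(tr$t_s), ]
    z <- suppressWarnings(
      median_prefilter(tr$z_um, config$median_filter_order))
    if (nrow(tr) >= config$W) {
      msd <- rolling_msd(as.numeric(z), config)
      gam <- fit_gamma(msd, config)
      centers <- attr(msd, "centers")
    } else {
      gam <- numeric(0)
      centers <- integer(0)
    }
    gammas[[as.character(id)]] <- gam
    cls <- classify_active(gam, config$min_run)
    if (length(gam))
      per_window[[length(per_window) + 1L]] <- data.frame(
        track_id = id, center = centers, gamma = gam,
        active = cls$window_active)
    sp <- tryCatch(ab_velocity(tr$t_s, as.numeric(z), velocity_window_s),
                   error = function(e) NULL)
    per_track[[length(per_track) + 1L]] <- data.frame(
      track_id = id,
      mean_speed_um_min = if (is.null(sp)) NA_real_ else mean(sp$speed_um_min),
      peak_speed_um_min = if (is.null(sp)) NA_real_ else max(sp$speed_um_min),
      active = cls$active,
      active_single_window = classify_active(gam, 1L)$active,
      analyzable = cls$analyzable)
  }
  list(per_window = if (length(per_window)) do.call(rbind, per_window)
         else data.frame(track_id = integer(0), center = integer(0),
                         gamma = numeric(0), active = logical(0)),
       per_track = do.call(rbind, per_track),
       percent_active = percent_active(gammas, config$min_run))
}
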