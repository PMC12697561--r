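# Generative twin of the FRAP analysis: known plateau, rate and noise.

#' Configuration of a synthetic FRAP experiment
#'
#' @param prebleach_level normalized prebleach intensity (typically 1).
#' @param bleach_depth fraction of the prebleach signal removed at t = 0
#'   (1 = complete bleach, so recovery starts at 0).
#' @param k recovery rate constant, 1/s.
#' @param plateau normalized recovery plateau; must satisfy
#'   `0 <= plateau <= prebleach_level`.
#' @param noise_sd additive Gaussian noise SD in normalized units.
#' @param n_timepoints number of post-bleach samples.
#' @param dt sampling interval, s.
#' @param n_prebleach number of prebleach samples.
#' @param rng_seed integer seed.
#' @return object of class `frap_truth_config`.
#' @export
frap_truth_config <- function(prebleach_level = 1, bleach_depth = 1,
                              k = log(2) / 10, plateau = 0.8,
                              noise_sd = 0, n_timepoints = 60L, dt = 1,
                              n_prebleach = 5L, rng_seed = 1L) {
  if (plateau < 0 || plateau > prebleach_level)
    stop("plateau must lie in [0, prebleach_level]", call. = FALSE)
  if (k <= 0) stop("rate k must be > 0", call. = FALSE)
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (bleach_depth < 0 || bleach_depth > 1)
    stop("bleach_depth must lie in [0, 1]", call. = FALSE)
  structure(list(prebleach_level = prebleach_level,
                 bleach_depth = bleach_depth, k = k, plateau = plateau,
                 noise_sd = noise_sd, n_timepoints = as.integer(n_timepoints),
                 dt = dt, n_prebleach = as.integer(n_prebleach),
                 rng_seed = as.integer(rng_seed)),
            class = "frap_truth_config")
}

#' Generate a synthetic FRAP series with known truth
#'
#' Produces the normalized one-phase-association recovery
#' `N(t) = N0 + (plateau - N0) * (1 - exp(-k t))` for `t >= 0` (with
#' `N0 = prebleach_level * (1 - bleach_depth)`), prebleach samples at
#' `prebleach_level`, plus Gaussian noise. It also emits a raw measurement
#' table (photobleached and reference region intensities, areas, background)
#' algebraically consistent with the two-region normalization
#' `N = ((Ip - b) * Ap) / ((Inp - b) * Anp)`, including a slow drift of the
#' reference intensity, so the normalization can be tested round-trip.
#'
#' @param config a [frap_truth_config()].
#' @return a `frap_series` (see [frap_series()]) with attribute `truth`
#'   holding the generative parameters and the noise-free normalized curve.
#' @export
generate_frap <- function(config) {
  stopifnot(inherits(config, "frap_truth_config"))
  n0 <- config$prebleach_level * (1 - config$bleach_depth)
  t_post <- seq(0, by = config$dt, length.out = config$n_timepoints)
  t_pre <- seq(-config$n_prebleach * config$dt, -config$dt, by = config$dt)
  times <- c(t_pre, t_post)
  prebleach <- times < 0

  n_clean <- ifelse(prebleach, config$prebleach_level,
                    n0 + (config$plateau - n0) * (1 - exp(-config$k * times)))
  n_obs <- n_clean
  if (config$noise_sd > 0)
    n_obs <- with_seed(config$rng_seed,
                       n_clean + rnorm(length(n_clean), 0, config$noise_sd))

  # raw series consistent with the normalization formula; reference region
  # drifts slowly (focal drift) and Ip is constructed by inversion
  b <- 100
  ap <- 80
  anp <- 400
  inp <- b + 500 * exp(-5e-4 * (times - times[1]))
  ip <- b + n_obs * (inp - b) * anp / ap

  out <- frap_series(times = times, ip = ip, ap = ap, inp = inp, anp = anp,
                     b = b, prebleach = prebleach)
  attr(out, "truth") <- list(config = config, n_clean = n_clean, n0 = n0)
  out
}
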