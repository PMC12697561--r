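# FRAP normalization, one-phase-association fitting, half-time and immobile
# fraction.

# Robust nonlinear least squares: Levenberg-Marquardt over a ladder of
# starting points, falling back to nls 'port'. Exponential models can drive
# the rate parameter toward its lower bound, where the Jacobian degenerates
# and a single attempt fails spuriously. Returns the first convergent fit,
# or the last error.
try_nls <- function(formula, data, starts, lower) {
  err <- NULL
  for (st in starts) {
    f <- tryCatch(
      minpack.lm::nlsLM(formula, data = data, start = st, lower = lower,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e)
    if (!inherits(f, "error") && all(is.finite(coef(f)))) return(f)
    if (inherits(f, "error")) err <- f
  }
  for (st in starts) {
    f <- tryCatch(
      stats::nls(formula, data = data, start = st, lower = lower,
                 algorithm = "port",
                 control = stats::nls.control(maxiter = 200,
                                              warnOnly = FALSE)),
      error = function(e) e)
    if (!inherits(f, "error") && all(is.finite(coef(f)))) return(f)
    if (inherits(f, "error")) err <- f
  }
  if (is.null(err)) simpleError("nonlinear fit failed") else err
}

#' Construct a FRAP measurement series
#'
#' Holds the raw region measurements of one FRAP experiment: mean intensity
#' and area of the photobleached region, mean intensity and area of one or two
#' non-photobleached reference regions (used to correct focal-plane and
#' biological drift), and the background level. The bleach event is at t = 0;
#' samples with `prebleach = TRUE` precede it.
#'
#' @param times acquisition times in seconds (bleach at 0).
#' @param ip mean intensity of the photobleached region per time point.
#' @param ap area of the photobleached region (scalar or per time point).
#' @param inp mean intensity of the reference region; for two references give
#'   a 2-column matrix.
#' @param anp reference area(s), scalar/vector matching `inp` columns.
#' @param b background intensity (scalar or per time point).
#' @param prebleach logical vector flagging prebleach samples; default
#'   `times < 0`.
#' @return object of class `frap_series`.
#' @export
frap_series <- function(times, ip, ap, inp, anp, b, prebleach = times < 0) {
  inp <- as.matrix(inp)
  n <- length(times)
  if (length(ip) != n || nrow(inp) != n)
    stop("ip and inp must have one value per time point", call. = FALSE)
  anp <- rep(as.numeric(anp), length.out = ncol(inp))
  if (any(ap <= 0) || any(anp <= 0)) stop("areas must be > 0", call. = FALSE)
  if (sum(!prebleach) < 3)
    stop("need >= 3 post-bleach samples", call. = FALSE)
  structure(list(times = as.numeric(times), ip = as.numeric(ip),
                 ap = rep(as.numeric(ap), length.out = n), inp = inp,
                 anp = anp, b = rep(as.numeric(b), length.out = n),
                 prebleach = as.logical(prebleach),
                 n_reference = ncol(inp)),
            class = "frap_series")
}

#' Two-region FRAP normalization
#'
#' Normalized intensity `N = ((Ip - b) * Ap) / ((Inp - b) * Anp)`, where the
#' denominator for two reference regions is the mean of their
#' background-subtracted, area-weighted intensities. Time points where the
#' reference falls to or below background are dropped and flagged rather than
#' silently kept.
#'
#' @param series a [frap_series()].
#' @param rescale_prebleach if TRUE, divide the whole curve by the mean
#'   prebleach value so that prebleach = 1.
#' @return data.frame with times, N, prebleach flag; attribute `dropped`
#'   gives indices of rejected time points, attribute `n_reference` the
#'   reference-region count.
#' @export
normalize_frap <- function(series, rescale_prebleach = FALSE) {
  stopifnot(inherits(series, "frap_series"))
  denom_terms <- sweep(sweep(series$inp, 1, series$b, `-`), 2, series$anp, `*`)
  bad <- apply(sweep(series$inp, 1, series$b, `-`) <= 0, 1, any)
  denom <- rowMeans(denom_terms)
  num <- (series$ip - series$b) * series$ap
  n <- num / denom
  keep <- !bad
  out <- data.frame(times = series$times[keep], N = n[keep],
                    prebleach = series$prebleach[keep])
  if (rescale_prebleach) {
    pb <- mean(out$N[out$prebleach])
    if (!is.finite(pb) || pb <= 0)
      stop("cannot rescale: no positive prebleach samples", call. = FALSE)
    out$N <- out$N / pb
  }
  attr(out, "dropped") <- which(bad)
  attr(out, "n_reference") <- series$n_reference
  attr(out, "rescaled") <- rescale_prebleach
  out
}

#' Fit a one-phase-association recovery
#'
#' Nonlinear least-squares fit of `N(t) = N0 + (plateau - N0) * (1 - e^(-k t))`
#' to the post-bleach samples; the bleach-frame acquisition at t = 0 is
#' excluded by default. The recovery half-time is `t50 = ln(2) / k`.
#' Initialization is derivative-free: plateau from the last-quartile mean,
#' `N0` from the first post-bleach sample, and `k` from the time at which the
#' curve first reaches halfway between the two.
#'
#' @param times,N post-bleach (or full, with `prebleach`) time series;
#'   alternatively pass the data.frame from [normalize_frap()] as `times`.
#' @param prebleach optional logical flagging prebleach samples to drop.
#' @param exclude_bleach_frame drop the t = 0 acquisition from the fit.
#' @return object of class `frap_fit`: plateau, k, t50, N0, residual norm,
#'   convergence flag and message.
#' @export
fit_recovery <- function(times, N = NULL, prebleach = NULL,
                         exclude_bleach_frame = TRUE) {
  if (is.data.frame(times)) {
    df <- times
    times <- df$times
    N <- df$N
    prebleach <- df$prebleach
  }
  if (is.null(prebleach)) prebleach <- times < 0
  post <- !prebleach
  if (exclude_bleach_frame) post <- post & times > 0
  t <- times[post]
  y <- N[post]
  if (length(t) < 3) stop("need >= 3 post-bleach samples to fit", call. = FALSE)

  q <- max(3L, ceiling(length(y) / 4))
  plateau0 <- mean(tail(y, q))
  n00 <- y[1]
  half <- n00 + (plateau0 - n00) / 2
  ih <- which(y >= half)[1]
  th <- if (is.na(ih) || t[ih] <= 0) median(t) else t[ih]
  k0 <- max(log(2) / th, 1e-6)

  starts <- list(list(n0 = n00, plateau = plateau0, k = k0),
                 list(n0 = n00, plateau = plateau0, k = 3 * k0),
                 list(n0 = n00, plateau = max(y), k = k0 / 3),
                 list(n0 = 0, plateau = max(plateau0, 1e-3), k = k0))
  fit <- try_nls(y ~ n0 + (plateau - n0) * (1 - exp(-k * t)),
                 data = list(t = t, y = y), starts = starts,
                 lower = c(n0 = -Inf, plateau = -Inf, k = 1e-9))

  if (inherits(fit, "error")) {
    return(structure(list(plateau = NA_real_, k = NA_real_, t50 = NA_real_,
                          N0 = NA_real_, resid_norm = NA_real_,
                          converged = FALSE, message = conditionMessage(fit),
                          n_fit = length(t)),
                     class = "frap_fit"))
  }
  cf <- coef(fit)
  structure(list(plateau = unname(cf["plateau"]), k = unname(cf["k"]),
                 t50 = log(2) / unname(cf["k"]), N0 = unname(cf["n0"]),
                 resid_norm = sqrt(sum(residuals(fit)^2)),
                 converged = TRUE, message = "converged", n_fit = length(t)),
            class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf(
    "<frap_fit> plateau = %.4g, k = %.4g 1/s, t50 = %.4g s (%s, n = %d)\n",
    x$plateau, x$k, x$t50, x$message, x$n_fit))
  invisible(x)
}

#' Immobile fraction of a FRAP recovery
#'
#' The population that fails to recover: prebleach level minus fitted plateau,
#' expressed relative to the prebleach level so the result stays a fraction
#' when the prebleach normalization drifts from 1 (it reduces to the plain
#' subtraction when prebleach = 1). A plateau above prebleach (overshoot)
#' yields a negative value, flagged rather than clipped.
#'
#' @param prebleach_N mean normalized prebleach intensity.
#' @param plateau fitted recovery plateau.
#' @return numeric immobile fraction with attribute `overshoot`.
#' @export
immobile_fraction <- function(prebleach_N, plateau) {
  if (prebleach_N <= 0) stop("prebleach_N must be > 0", call. = FALSE)
  f <- (prebleach_N - plateau) / prebleach_N
  attr(f, "overshoot") <- plateau > prebleach_N
  f
}

#' Analyze a FRAP series end-to-end
#'
#' Normalize, fit the one-phase association, and report t50 and immobile
#' fraction under both prebleach conventions (raw and rescaled-to-1).
#'
#' @param series a [frap_series()].
#' @param rescale_prebleach passed to [normalize_frap()].
#' @return list with `normalized`, `fit`, `t50`, `immobile_fraction`,
#'   `prebleach_N`.
#' @export
analyze_frap <- function(series, rescale_prebleach = FALSE) {
  norm <- normalize_frap(series, rescale_prebleach = rescale_prebleach)
  fit <- fit_recovery(norm)
  pb <- mean(norm$N[norm$prebleach])
  imm <- if (fit$converged) immobile_fraction(pb, fit$plateau) else NA_real_
  list(normalized = norm, fit = fit, t50 = fit$t50,
       immobile_fraction = imm, prebleach_N = pb)
}
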