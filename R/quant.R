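# ROI intensity quantitation: disk / ring / rectangle / line ROIs,
# annulus-corrected centrosome means, t0 normalization, exponential bleach
# correction, and robust FDR-based outlier removal.

# Images are 2D matrices indexed [y, x]; pixel (i, j) has its center at
# ((j - 0.5) * px, (i - 0.5) * px) um. ROI membership is center-inclusion:
# a pixel belongs to an ROI iff its center lies inside the geometry, which
# keeps brute-force pixel enumeration an exact oracle.

pixel_centers <- function(img, pixel_size) {
  list(x = (seq_len(ncol(img)) - 0.5) * pixel_size,
       y = (seq_len(nrow(img)) - 0.5) * pixel_size)
}

#' ROI specifications
#'
#' Constructors for the ROI kinds used in the quantitation workflows. All
#' geometry is in micrometres unless noted.
#'
#' @param center disk center c(x, y), um.
#' @param diameter disk diameter, um.
#' @return list of class `roi_spec`.
#' @export
roi_disk <- function(center, diameter) {
  stopifnot(length(center) == 2, diameter > 0)
  structure(list(kind = "disk", center = center, diameter = diameter),
            class = "roi_spec")
}

#' @rdname roi_disk
#' @param corner rectangle corner c(x, y) (lowest coordinates), um.
#' @param extent rectangle extent c(width, height), um.
#' @export
roi_rect <- function(corner, extent) {
  stopifnot(length(corner) == 2, all(extent > 0))
  structure(list(kind = "rect", corner = corner, extent = extent),
            class = "roi_spec")
}

#' @rdname roi_disk
#' @param contour closed contour, matrix with columns x, y (um); the last
#'   vertex is joined to the first.
#' @param stroke_px stroke thickness in pixels (freehand ring ROIs are drawn
#'   with a 3-pixel stroke).
#' @export
roi_ring <- function(contour, stroke_px = 3) {
  contour <- as.matrix(contour)
  stopifnot(ncol(contour) == 2, nrow(contour) >= 3, stroke_px > 0)
  structure(list(kind = "ring", contour = contour, stroke_px = stroke_px),
            class = "roi_spec")
}

#' @rdname roi_disk
#' @param from,to line endpoints c(x, y), um.
#' @param width_px line width in pixels.
#' @export
roi_line <- function(from, to, width_px = 3) {
  stopifnot(length(from) == 2, length(to) == 2, width_px > 0)
  structure(list(kind = "line", from = from, to = to, width_px = width_px),
            class = "roi_spec")
}

# distance from points (px, py) to the closed polyline `contour`
dist_to_contour <- function(px, py, contour) {
  v <- rbind(contour, contour[1, , drop = FALSE])
  best <- rep(Inf, length(px))
  for (s in seq_len(nrow(v) - 1L)) {
    ax <- v[s, 1]; ay <- v[s, 2]
    bx <- v[s + 1L, 1]; by <- v[s + 1L, 2]
    dx <- bx - ax; dy <- by - ay
    len2 <- dx^2 + dy^2
    tt <- if (len2 == 0) rep(0, length(px))
          else pmin(pmax(((px - ax) * dx + (py - ay) * dy) / len2, 0), 1)
    d <- sqrt((px - (ax + tt * dx))^2 + (py - (ay + tt * dy))^2)
    best <- pmin(best, d)
  }
  best
}

#' Logical pixel mask of an ROI
#'
#' @param img 2D image matrix `[y, x]`.
#' @param roi an `roi_spec`.
#' @param pixel_size um per pixel.
#' @return logical matrix of the image shape.
#' @export
roi_mask <- function(img, roi, pixel_size) {
  pc <- pixel_centers(img, pixel_size)
  X <- matrix(pc$x, nrow(img), ncol(img), byrow = TRUE)
  Y <- matrix(pc$y, nrow(img), ncol(img))
  switch(roi$kind,
    disk = (X - roi$center[1])^2 + (Y - roi$center[2])^2 <=
      (roi$diameter / 2)^2,
    rect = X >= roi$corner[1] & X <= roi$corner[1] + roi$extent[1] &
      Y >= roi$corner[2] & Y <= roi$corner[2] + roi$extent[2],
    ring = {
      d <- dist_to_contour(as.vector(X), as.vector(Y), roi$contour)
      matrix(d <= roi$stroke_px * pixel_size / 2, nrow(img))
    },
    line = {
      d <- dist_to_contour(as.vector(X), as.vector(Y),
                           rbind(roi$from, roi$to, roi$from))
      matrix(d <= roi$width_px * pixel_size / 2, nrow(img))
    },
    stop("unknown ROI kind", call. = FALSE))
}

#' Mean intensity over an ROI
#'
#' Mean over pixels whose centers fall inside the ROI geometry.
#'
#' @inheritParams roi_mask
#' @return list: mean, n_pixels, integrated_density (sum).
#' @export
roi_mean <- function(img, roi, pixel_size) {
  m <- roi_mask(img, roi, pixel_size)
  n <- sum(m)
  if (n == 0L) stop("ROI covers no pixel centers", call. = FALSE)
  list(mean = mean(img[m]), n_pixels = n, integrated_density = sum(img[m]))
}

#' Background subtraction and t0 normalization
#'
#' Normalized intensity per measurement: background-subtracted mean divided
#' by the average background-subtracted mean at time 0, so the t0 population
#' mean of the normalized values is 1 by construction.
#'
#' @param means raw ROI means.
#' @param background background mean(s), scalar or per measurement.
#' @param is_t0 logical flagging the baseline (0 min) measurements.
#' @return numeric normalized series.
#' @export
background_subtract_normalize <- function(means, background, is_t0) {
  background <- rep(background, length.out = length(means))
  corr <- means - background
  baseline <- mean(corr[is_t0])
  if (!is.finite(baseline) || baseline <= 0)
    stop("baseline (t0 mean above background) must be > 0", call. = FALSE)
  corr / baseline
}

#' Annulus-corrected centrosomal mean
#'
#' Local-background-corrected spot intensity from two concentric disk ROIs:
#' the annulus mean, `(ID_large - ID_small) / (A_large - A_small)` computed
#' from integrated densities and pixel counts, is subtracted from the
#' small-disk mean. Diameters are given in pixels at a reference resolution
#' (0.168 um/px) and rescaled to the image's pixel size.
#'
#' @param img 2D image matrix.
#' @param center spot center c(x, y), um.
#' @param pixel_size um per pixel of `img`.
#' @param d_small_px,d_large_px disk diameters in pixels at `ref_px_um`.
#' @param ref_px_um reference resolution the diameters refer to.
#' @return list: corrected_mean, mean_small, background (annulus mean),
#'   n_small, n_annulus.
#' @export
annulus_corrected_mean <- function(img, center, pixel_size,
                                   d_small_px = 15, d_large_px = 25,
                                   ref_px_um = 0.168) {
  if (d_large_px <= d_small_px)
    stop("large diameter must exceed small diameter", call. = FALSE)
  small <- roi_mean(img, roi_disk(center, d_small_px * ref_px_um), pixel_size)
  large <- roi_mean(img, roi_disk(center, d_large_px * ref_px_um), pixel_size)
  if (large$n_pixels <= small$n_pixels)
    stop("annulus covers no pixels", call. = FALSE)
  bg <- (large$integrated_density - small$integrated_density) /
    (large$n_pixels - small$n_pixels)
  list(corrected_mean = small$mean - bg, mean_small = small$mean,
       background = bg, n_small = small$n_pixels,
       n_annulus = large$n_pixels - small$n_pixels)
}

#' Exponential photobleaching correction of a time series of frames
#'
#' Fits the frame means to `a * exp(-b * t) + c` by nonlinear least squares
#' and divides every frame by `fit(t) / fit(0)`, leaving the first frame
#' unchanged. If the exponential fit fails, falls back to simple ratio
#' correction (frame mean / first frame mean), flagged in the result.
#'
#' @param frames list of 2D matrices, or a 3D array (t, y, x).
#' @param t_s frame times, s (default frame index - 1).
#' @return list: frames (corrected, same form), method ("exponential" or
#'   "ratio"), fit coefficients.
#' @export
bleach_correct <- function(frames, t_s = NULL) {
  as_list <- !is.array(frames) || is.list(frames)
  if (!as_list) frames <- lapply(seq_len(dim(frames)[1]),
                                 function(t) frames[t, , ])
  nt <- length(frames)
  if (nt < 5) stop("need >= 5 frames", call. = FALSE)
  if (is.null(t_s)) t_s <- seq_len(nt) - 1
  mu <- vapply(frames, mean, 0)

  b0 <- max(1e-6, log(max(mu[1], 1e-12) / max(mu[nt], 1e-12)) /
              max(t_s[nt], 1))
  starts <- list(
    list(a = max(mu[1] - min(mu), 1e-6 * mu[1]), b = b0, c0 = min(mu) * 0.9),
    list(a = mu[1], b = b0, c0 = 0),
    list(a = mu[1] / 2, b = 3 * b0, c0 = min(mu) / 2))
  fit <- try_nls(mu ~ a * exp(-b * t_s) + c0,
                 data = list(t_s = t_s, mu = mu), starts = starts,
                 lower = c(a = 0, b = 0, c0 = -Inf))
  if (inherits(fit, "error")) fit <- NULL

  if (!is.null(fit)) {
    pred <- predict(fit, list(t_s = t_s))
    if (any(pred <= 0)) fit <- NULL
  }
  if (is.null(fit)) {
    factor <- mu / mu[1]
    method <- "ratio"
    coefs <- NULL
  } else {
    pred <- predict(fit, list(t_s = t_s))
    factor <- pred / pred[1]
    method <- "exponential"
    coefs <- coef(fit)
  }
  corrected <- Map(function(f, s) f / s, frames, as.list(factor))
  list(frames = corrected, method = method, fit = coefs, factor = factor)
}

#' Line-scan intensity profile
#'
#' Mean intensity across a stroke of `width_px` pixels, sampled at pixel
#' pitch along the line: at each sample position the values of the
#' `width_px` pixels straddling the line perpendicular are averaged
#' (nearest-pixel lookup).
#'
#' @param img 2D image matrix.
#' @param from,to endpoints c(x, y), um.
#' @param pixel_size um per pixel.
#' @param width_px stroke width in pixels.
#' @return data.frame: distance_um along the line, mean intensity.
#' @export
line_scan <- function(img, from, to, pixel_size, width_px = 3) {
  vec <- to - from
  len <- sqrt(sum(vec^2))
  if (len <= 0) stop("degenerate line", call. = FALSE)
  u <- vec / len
  nvec <- c(-u[2], u[1])
  svals <- seq(0, len, by = pixel_size)
  offs <- (seq_len(width_px) - (width_px + 1) / 2) * pixel_size
  prof <- vapply(svals, function(s) {
    pts <- matrix(from + s * u, length(offs), 2, byrow = TRUE) +
      outer(offs, nvec)
    jx <- pmin(pmax(ceiling(pts[, 1] / pixel_size), 1L), ncol(img))
    iy <- pmin(pmax(ceiling(pts[, 2] / pixel_size), 1L), nrow(img))
    mean(img[cbind(iy, jx)])
  }, 0)
  data.frame(distance_um = svals, mean = prof)
}

#' Robust FDR-controlled outlier removal (ROUT-style, constant model)
#'
#' Identifies outliers of a univariate sample by fitting a robust location
#' (the median), scaling residuals by the robust standard deviation of the
#' residuals (the 68.27th percentile of absolute residuals with a small-n
#' correction), and testing the largest absolute residuals against a t
#' distribution with a Benjamini-Hochberg step-up at false-discovery rate
#' `Q`. At most 30 percent of the sample can be flagged. Samples smaller
#' than 10 are returned untouched and flagged as too small. This is a
#' location-model approximation of the ROUT procedure used by common
#' plotting software; removed points are always reported, never silently
#' dropped.
#'
#' @param values numeric sample.
#' @param Q false-discovery rate (default 0.01, i.e. Q = 1 percent).
#' @return list: kept (values), outliers (values), is_outlier (logical per
#'   input), applied (FALSE when n < 10).
#' @export
remove_outliers_rout <- function(values, Q = 0.01) {
  n <- length(values)
  if (n < 10L)
    return(list(kept = values, outliers = values[0],
                is_outlier = rep(FALSE, n), applied = FALSE))
  resid <- values - median(values)
  # robust SD of the residuals: 68.27th percentile of |resid|, df-corrected
  rsdr <- quantile(abs(resid), 0.6827, names = FALSE) * n / (n - 1)
  if (rsdr <= 0)
    return(list(kept = values, outliers = values[0],
                is_outlier = rep(FALSE, n), applied = TRUE))
  tstat <- abs(resid) / rsdr
  p <- 2 * pt(tstat, df = n - 1, lower.tail = FALSE)
  ord <- order(p)
  max_out <- floor(0.3 * n)
  is_out <- rep(FALSE, n)
  # BH step-up over the most extreme max_out residuals
  thr <- Q * seq_len(n) / n
  passed <- which(p[ord] <= thr)
  k <- if (length(passed)) min(max(passed), max_out) else 0L
  if (k > 0L) is_out[ord[seq_len(k)]] <- TRUE
  list(kept = values[!is_out], outliers = values[is_out],
       is_outlier = is_out, applied = TRUE)
}

#' Synthetic ROI fixture with known region means
#'
#' Builds a 2D test image from a background level and a list of shapes
#' (painted in order), recording for each shape its painted value; because
#' painting and measurement both use pixel-center inclusion, an ROI matching
#' a shape measures exactly the painted value on uniform regions, and
#' arbitrary overlaps can be checked against brute-force enumeration.
#'
#' @param shape_list list of `roi_spec` objects.
#' @param values intensity per shape.
#' @param size image size in pixels c(ny, nx).
#' @param pixel_size um per pixel.
#' @param background background level.
#' @return list: img, shapes, values, pixel_size, background.
#' @export
generate_roi_fixture <- function(shape_list, values, size = c(64, 64),
                                 pixel_size = 0.168, background = 0) {
  stopifnot(length(shape_list) == length(values))
  img <- matrix(background, size[1], size[2])
  for (i in seq_along(shape_list))
    img[roi_mask(img, shape_list[[i]], pixel_size)] <- values[i]
  list(img = img, shapes = shape_list, values = values,
       pixel_size = pixel_size, background = background)
}
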