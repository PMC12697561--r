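# 3D nuclear segmentation: isotropic resampling, Gaussian preprocessing,
# local-threshold rough masks, erosion-derived seeds, gradient seeded
# watershed.

#' Segmentation parameters
#'
#' All lengths in micrometres; converted to voxels internally against the
#' (isotropic) voxel size of the volume being segmented.
#'
#' @param gaussian_sigma preprocessing Gaussian sigma (um).
#' @param local_window edge length of the cubic local-threshold window (um);
#'   about 1.5 nuclear diameters works well.
#' @param local_offset threshold offset as a fraction of the robust
#'   (1st-99th percentile) global intensity range.
#' @param erosion_radius ball radius (um) eroding rough masks into seeds.
#' @param min_seed_voxels components smaller than this never yield a seed.
#' @param min_overlap_fraction minimum overlap/size for track linking.
#' @param peak_separation minimum separation (um) between distance-transform
#'   maxima for a rough component to be split into multiple seeds; defaults
#'   to one nuclear radius (2.2 um).
#' @return object of class `segmentation_params`.
#' @export
segmentation_params <- function(gaussian_sigma = 0.7,
                                local_window = 8,
                                local_offset = 0.4,
                                erosion_radius = 1.2,
                                min_seed_voxels = 100L,
                                min_overlap_fraction = 0.3,
                                peak_separation = 2.2) {
  p <- list(gaussian_sigma = gaussian_sigma, local_window = local_window,
            local_offset = local_offset, erosion_radius = erosion_radius,
            min_seed_voxels = as.integer(min_seed_voxels),
            min_overlap_fraction = min_overlap_fraction,
            peak_separation = peak_separation)
  if (any(unlist(p[c("gaussian_sigma", "local_window", "local_offset",
                     "erosion_radius", "peak_separation")]) <= 0) ||
      p$min_seed_voxels <= 0)
    stop("all segmentation parameters must be positive", call. = FALSE)
  if (p$min_overlap_fraction <= 0 || p$min_overlap_fraction > 1)
    stop("min_overlap_fraction must be in (0, 1]", call. = FALSE)
  structure(p, class = "segmentation_params")
}

#' Resample a volume series to isotropic voxels
#'
#' Linearly interpolates along z so that the voxel edge equals the (equal)
#' lateral edge dx = dy; the z extent in micrometres is preserved to within
#' half a voxel. Already-isotropic input is returned unchanged. Label volumes
#' are resampled by nearest neighbour instead (labels must never blend).
#'
#' @param vol a [volume_series()] or [label_volume()].
#' @return `volume_series` (or `label_volume`) with voxel size (dx, dx, dx).
#' @export
resample_isotropic <- function(vol) {
  stopifnot(inherits(vol, c("volume_series", "label_volume")))
  vs <- vol$voxel_size
  if (abs(vs[2] - vs[3]) > 1e-9)
    stop("lateral voxel sizes dy and dx must be equal", call. = FALSE)
  dx <- vs[2]
  if (abs(vs[1] - dx) < 1e-9) return(vol)
  if (vs[1] < dx)
    stop("expected axial voxel size >= lateral (dz >= dx)", call. = FALSE)

  d <- dim(vol$data)
  nz_in <- d[2]
  nz_out <- max(2L, as.integer(round(nz_in * vs[1] / dx)))
  # input slice centers at (i-1)*dz, output at (j-1)*dx; clamp at the ends
  zi <- (seq_len(nz_out) - 1) * dx / vs[1] + 1
  zi <- pmin(pmax(zi, 1), nz_in)
  lo <- pmin(floor(zi), nz_in - 1L)
  w <- zi - lo
  is_label <- inherits(vol, "label_volume")
  out <- array(if (is_label) 0L else 0, c(d[1], nz_out, d[3], d[4]))
  for (t in seq_len(d[1])) {
    fr <- array(vol$data[t, , , ], d[2:4])
    m <- matrix(fr, nrow = nz_in)  # z by (y*x)
    res <- if (is_label) m[round(zi), , drop = FALSE]  # nearest neighbour
           else m[lo, , drop = FALSE] * (1 - w) + m[lo + 1L, , drop = FALSE] * w
    out[t, , , ] <- array(res, c(nz_out, d[3], d[4]))
  }
  if (is_label) label_volume(out, c(dx, dx, dx), vol$frame_interval)
  else volume_series(out, c(dx, dx, dx), vol$frame_interval)
}

#' Gaussian preprocessing of a volume
#'
#' Separable 3D Gaussian smoothing; `sigma` is given in micrometres and
#' converted to voxels per axis. Kernels are normalized, so a constant volume
#' passes through unchanged and total intensity is conserved away from the
#' borders. `sigma = 0` is the identity.
#'
#' @param vol a `volume_series`.
#' @param sigma Gaussian sigma in um (scalar, applied per axis).
#' @return smoothed `volume_series`.
#' @export
preprocess_volume <- function(vol, sigma) {
  stopifnot(inherits(vol, "volume_series"))
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (sigma == 0) return(vol)
  d <- dim(vol$data)
  sig_vox <- sigma / vol$voxel_size
  out <- vol$data
  for (t in seq_len(d[1]))
    out[t, , , ] <- gauss_blur3(array(vol$data[t, , , ], d[2:4]), sig_vox)
  volume_series(out, vol$voxel_size, vol$frame_interval)
}

#' Rough nuclear mask by local thresholding
#'
#' A voxel is foreground iff its intensity exceeds the local mean over a
#' cubic window plus an offset scaled by the robust (1st-99th percentile)
#' global intensity range. A flat volume therefore yields an empty mask.
#'
#' @param frame 3D (z,y,x) intensity array.
#' @param voxel_size voxel edge lengths (dz, dy, dx), um.
#' @param window window edge length, um (must exceed the voxel size).
#' @param offset offset fraction of the robust range.
#' @return logical 3D array.
#' @export
rough_mask <- function(frame, voxel_size, window, offset) {
  if (window <= max(voxel_size))
    stop("local window must exceed the voxel size", call. = FALSE)
  w_vox <- pmax(3L, as.integer(round(window / voxel_size)))
  local_mean <- box_mean3(frame, w_vox)
  rng <- diff(quantile(frame, c(0.01, 0.99), names = FALSE))
  frame > local_mean + offset * rng
}

# Greedy non-maximum suppression: peaks of the distance transform `dist` at
# voxel coordinates `coords`, accepted in decreasing order if at least
# `min_sep` voxels from every accepted peak, at least `rel` of the strongest
# value, and separated from the nearest accepted peak by a genuine valley
# (the distance transform dips below `valley_rel` of the weaker peak along
# the straight line between them). The valley test keeps the ridge of a
# single elongated nucleus from being split.
select_peaks <- function(coords, values, min_sep, dist, rel = 0.5,
                         valley_rel = 0.7) {
  ord <- order(values, decreasing = TRUE)
  vmax <- values[ord[1]]
  acc <- matrix(numeric(0), ncol = 3)
  accv <- numeric(0)
  d <- dim(dist)
  has_valley <- function(p, q, vp, vq) {
    n <- max(3L, 2L * ceiling(sqrt(sum((p - q)^2))))
    tt <- seq(0, 1, length.out = n)
    pts <- cbind(round(p[1] + tt * (q[1] - p[1])),
                 round(p[2] + tt * (q[2] - p[2])),
                 round(p[3] + tt * (q[3] - p[3])))
    min(dist[pts]) < valley_rel * min(vp, vq)
  }
  for (i in ord) {
    if (values[i] < rel * vmax) break
    p <- coords[i, ]
    if (nrow(acc) == 0) {
      acc <- rbind(acc, p)
      accv <- c(accv, values[i])
      next
    }
    dd <- sqrt(rowSums((acc - matrix(p, nrow(acc), 3, byrow = TRUE))^2))
    j <- which.min(dd)
    if (dd[j] >= min_sep && has_valley(p, acc[j, ], values[i], accv[j])) {
      acc <- rbind(acc, p)
      accv <- c(accv, values[i])
    }
  }
  acc
}

#' Seeds from a rough mask by morphological erosion
#'
#' Erodes the mask by a ball of `erosion_radius` (via the Euclidean distance
#' transform) and labels the surviving cores as seeds. Two automated repairs
#' replace interactive seed editing: (1) a rough component whose core is
#' eroded away entirely is re-seeded at its internal distance-transform
#' maximum, and (2) a component showing several well-separated
#' distance-transform maxima (fused nuclei) is split into one small seed per
#' maximum. Both events are flagged in the returned metadata.
#'
#' @param mask logical 3D array (isotropic voxels).
#' @param voxel voxel edge length, um.
#' @param erosion_radius ball radius, um.
#' @param min_seed_voxels minimum rough-component size to seed at all.
#' @param peak_separation minimum peak separation (um) for fused splitting.
#' @return integer 3D seed label array with attribute `seed_info`
#'   (data.frame: component, n_seeds, reseeded, fused_split).
#' @export
seeds_from_mask <- function(mask, voxel, erosion_radius, min_seed_voxels = 100L,
                            peak_separation = 2.2) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  if (!any(mask)) {
    out <- array(0L, dim(mask))
    attr(out, "seed_info") <- data.frame(component = integer(0),
                                         n_seeds = integer(0),
                                         reseeded = logical(0),
                                         fused_split = logical(0))
    return(out)
  }
  er_vox <- erosion_radius / voxel
  sep_vox <- peak_separation / voxel
  dist <- edt3(mask)                     # voxel units (isotropic)
  comp <- label_components3(mask)
  eroded <- dist > er_vox

  seeds <- array(0L, dim(mask))
  nxt <- 0L
  info <- list()
  comp_sizes <- tabulate(comp[comp > 0L])
  ball_r <- max(1.5, er_vox / 2)

  for (ci in seq_along(comp_sizes)) {
    if (comp_sizes[ci] < min_seed_voxels) next
    in_comp <- comp == ci
    idx <- which(in_comp)
    dvals <- dist[idx]
    coords <- arrayInd(idx, dim(mask))
    peaks <- select_peaks(coords, dvals, sep_vox, dist)
    reseeded <- FALSE
    fused <- FALSE
    if (nrow(peaks) >= 2L) {
      # fused component: one small ball seed per separated maximum
      fused <- TRUE
      for (p in seq_len(nrow(peaks))) {
        nxt <- nxt + 1L
        seeds <- paint_ball(seeds, peaks[p, ], ball_r, nxt)
      }
      n_here <- nrow(peaks)
    } else {
      core <- in_comp & eroded
      if (!any(core)) {
        # thin component: re-seed at the distance maximum
        reseeded <- TRUE
        nxt <- nxt + 1L
        pk <- coords[which.max(dvals), ]
        seeds <- paint_ball(seeds, pk, max(1, er_vox / 2), nxt)
        n_here <- 1L
      } else {
        sub <- label_components3(core)
        labs <- sort(unique(sub[sub > 0L]))
        for (l in labs) {
          nxt <- nxt + 1L
          seeds[sub == l] <- nxt
        }
        n_here <- length(labs)
      }
    }
    info[[length(info) + 1L]] <-
      data.frame(component = ci, n_seeds = n_here, reseeded = reseeded,
                 fused_split = fused)
  }
  attr(seeds, "seed_info") <-
    if (length(info)) do.call(rbind, info)
    else data.frame(component = integer(0), n_seeds = integer(0),
                    reseeded = logical(0), fused_split = logical(0))
  seeds
}

# Paint a ball of radius r (voxels) around center (z,y,x voxel indices) with
# `value`, but never overwrite an existing seed label.
paint_ball <- function(arr, center, r, value) {
  d <- dim(arr)
  rr <- ceiling(r)
  iz <- max(1, center[1] - rr):min(d[1], center[1] + rr)
  iy <- max(1, center[2] - rr):min(d[2], center[2] + rr)
  ix <- max(1, center[3] - rr):min(d[3], center[3] + rr)
  d2 <- outer(outer((iz - center[1])^2, (iy - center[2])^2, `+`),
              (ix - center[3])^2, `+`)
  sub <- arr[iz, iy, ix, drop = FALSE]
  take <- d2 <= r^2 & sub == 0L
  sub[take] <- as.integer(value)
  arr[iz, iy, ix] <- sub
  arr
}

#' Seeded watershed on the intensity gradient
#'
#' Marker-imposed watershed of the gradient-magnitude volume (nuclear edges
#' have the steepest intensity change), restricted to the rough mask: the
#' background is never flooded, every seed grows into exactly one label, and
#' the labels partition the mask.
#'
#' @param frame 3D intensity array (preprocessed, isotropic).
#' @param seeds integer 3D seed label array.
#' @param mask logical 3D rough mask.
#' @return integer 3D label array.
#' @export
watershed_labels <- function(frame, seeds, mask) {
  stopifnot(all(dim(frame) == dim(seeds)), all(dim(frame) == dim(mask)))
  if (!any(seeds > 0L)) return(array(0L, dim(frame)))
  grad <- gradient_magnitude3(frame)
  d <- dim(frame)
  lab <- cpp_seeded_watershed(as.numeric(grad), as.integer(seeds),
                              as.logical(mask | seeds > 0L), as.integer(d))
  array(lab, d)
}

#' Segment one frame end-to-end
#'
#' Resampling must already have been applied (isotropic voxels). Runs
#' Gaussian preprocessing, local thresholding, seed extraction and the seeded
#' gradient watershed.
#'
#' @param frame 3D (z,y,x) intensity array with isotropic voxels.
#' @param voxel voxel edge length, um.
#' @param params a [segmentation_params()].
#' @return integer label array with attribute `seed_info`.
#' @export
segment_frame <- function(frame, voxel, params = segmentation_params()) {
  sm <- gauss_blur3(frame, rep(params$gaussian_sigma / voxel, 3))
  mask <- rough_mask(sm, rep(voxel, 3), params$local_window,
                     params$local_offset)
  seeds <- seeds_from_mask(mask, voxel, params$erosion_radius,
                           params$min_seed_voxels, params$peak_separation)
  lab <- watershed_labels(sm, seeds, mask)
  attr(lab, "seed_info") <- attr(seeds, "seed_info")
  lab
}

#' Segment and track a whole volume series
#'
#' Resamples to isotropic voxels, segments every frame, and links labels
#' across frames by maximal overlap so that labels are track ids.
#'
#' @param vol a `volume_series`.
#' @param params a [segmentation_params()].
#' @return list with `labels` (a track-consistent `label_volume` on the
#'   isotropic grid), `tracks` (the centroid table from [tracks_table()]),
#'   and `seed_info` per frame.
#' @export
segment_series <- function(vol, params = segmentation_params()) {
  iso <- resample_isotropic(vol)
  d <- dim(iso$data)
  voxel <- iso$voxel_size[2]
  labs <- array(0L, d)
  seed_info <- vector("list", d[1])
  prev <- NULL
  next_id <- 0L
  for (t in seq_len(d[1])) {
    fr <- array(iso$data[t, , , ], d[2:4])
    lab <- segment_frame(fr, voxel, params)
    seed_info[[t]] <- attr(lab, "seed_info")
    if (is.null(prev)) {
      ids <- sort(unique(lab[lab > 0L]))
      relab <- lab
      if (length(ids)) {
        map <- integer(max(ids))
        map[ids] <- seq_along(ids)
        relab[lab > 0L] <- map[lab[lab > 0L]]
        next_id <- length(ids)
      }
    } else {
      lk <- link_tracks(prev, lab, params$min_overlap_fraction,
                        next_track_id = next_id + 1L)
      relab <- array(0L, d[2:4])
      pos <- lab > 0L
      map <- integer(max(lab))
      map[lk$label] <- lk$track_id
      relab[pos] <- map[lab[pos]]
      next_id <- max(next_id, lk$track_id)
    }
    labs[t, , , ] <- relab
    prev <- relab
  }
  lv <- label_volume(labs, iso$voxel_size, iso$frame_interval)
  list(labels = lv, tracks = tracks_table(lv), seed_info = seed_info)
}
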