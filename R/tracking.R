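# Overlap-based track linking of label volumes across frames.

label_centroids <- function(lab, voxel_size = c(1, 1, 1)) {
  idx <- which(lab > 0L)
  if (!length(idx))
    return(data.frame(label = integer(0), z = numeric(0), y = numeric(0),
                      x = numeric(0), n_voxels = integer(0)))
  co <- arrayInd(idx, dim(lab))
  l <- lab[idx]
  agg <- function(v) tapply(v, l, mean)
  n <- tapply(l, l, length)
  data.frame(label = as.integer(names(n)),
             z = unname(agg((co[, 1] - 1) * voxel_size[1])),
             y = unname(agg((co[, 2] - 1) * voxel_size[2])),
             x = unname(agg((co[, 3] - 1) * voxel_size[3])),
             n_voxels = as.integer(n))
}

#' Link labels across two consecutive frames by maximal overlap
#'
#' Each label of the later frame inherits the track id of the earlier-frame
#' label with which it shares the most voxels, provided the shared voxels are
#' at least `min_overlap_fraction` of the later label's size. A track id is
#' given to at most one label per frame; competing claims are resolved by
#' larger overlap, then smaller centroid distance. Labels with no admissible
#' parent start new tracks.
#'
#' @param lab_prev,lab_next integer 3D label arrays on the same grid;
#'   `lab_prev` labels are track ids.
#' @param min_overlap_fraction minimum overlap / size(next label).
#' @param next_track_id first id to assign to newly started tracks; defaults
#'   to one above the largest id seen.
#' @return data.frame: label (in `lab_next`), track_id, new_track, overlap.
#' @export
link_tracks <- function(lab_prev, lab_next, min_overlap_fraction = 0.3,
                        next_track_id = NULL) {
  if (!all(dim(lab_prev) == dim(lab_next)))
    stop("label grids must have identical shape", call. = FALSE)
  labels_next <- sort(unique(lab_next[lab_next > 0L]))
  if (!length(labels_next))
    return(data.frame(label = integer(0), track_id = integer(0),
                      new_track = logical(0), overlap = integer(0)))
  if (is.null(next_track_id))
    next_track_id <- max(0L, lab_prev) + 1L

  both <- which(lab_next > 0L)
  a <- lab_prev[both]
  b <- lab_next[both]
  size_next <- tabulate(b)
  keep <- a > 0L
  ov <- if (any(keep)) {
    tb <- table(prev = a[keep], nxt = b[keep])
    df <- as.data.frame(tb, stringsAsFactors = FALSE)
    df <- df[df$Freq > 0, ]
    data.frame(prev = as.integer(df$prev), nxt = as.integer(df$nxt),
               overlap = as.integer(df$Freq))
  } else {
    data.frame(prev = integer(0), nxt = integer(0), overlap = integer(0))
  }
  ov <- ov[ov$overlap / size_next[ov$nxt] >= min_overlap_fraction, ,
           drop = FALSE]

  # centroid distances for tie-breaks
  if (nrow(ov)) {
    cp <- label_centroids(lab_prev)
    cn <- label_centroids(lab_next)
    rownames(cp) <- cp$label
    rownames(cn) <- cn$label
    pd <- cp[as.character(ov$prev), c("z", "y", "x")]
    nd <- cn[as.character(ov$nxt), c("z", "y", "x")]
    ov$dist <- sqrt(rowSums((pd - nd)^2))
    ov <- ov[order(-ov$overlap, ov$dist), ]
  }

  assigned_prev <- integer(0)
  track_of <- integer(0)
  for (r in seq_len(nrow(ov))) {
    p <- ov$prev[r]; nl <- ov$nxt[r]
    if (p %in% assigned_prev) next
    if (as.character(nl) %in% names(track_of)) next
    track_of[as.character(nl)] <- p
    assigned_prev <- c(assigned_prev, p)
  }

  out <- data.frame(label = labels_next, track_id = NA_integer_,
                    new_track = FALSE, overlap = 0L)
  for (i in seq_along(labels_next)) {
    nl <- as.character(labels_next[i])
    if (nl %in% names(track_of)) {
      out$track_id[i] <- track_of[[nl]]
      out$overlap[i] <- ov$overlap[ov$nxt == labels_next[i] &
                                     ov$prev == track_of[[nl]]][1]
    } else {
      out$track_id[i] <- next_track_id
      out$new_track[i] <- TRUE
      next_track_id <- next_track_id + 1L
    }
  }
  out
}

#' Centroid table of a track-consistent label volume
#'
#' @param labels a `label_volume` whose labels are track ids.
#' @return data.frame: track_id, frame, t_s, z_um, y_um, x_um, n_voxels.
#' @export
tracks_table <- function(labels) {
  stopifnot(inherits(labels, "label_volume"))
  d <- dim(labels$data)
  rows <- vector("list", d[1])
  for (t in seq_len(d[1])) {
    cen <- label_centroids(array(labels$data[t, , , ], d[2:4]),
                           labels$voxel_size)
    if (nrow(cen))
      rows[[t]] <- data.frame(track_id = cen$label, frame = t,
                              t_s = (t - 1) * labels$frame_interval,
                              z_um = cen$z, y_um = cen$y, x_um = cen$x,
                              n_voxels = cen$n_voxels)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(track_id = integer(0), frame = integer(0),
                      t_s = numeric(0), z_um = numeric(0), y_um = numeric(0),
                      x_um = numeric(0), n_voxels = integer(0))
  out[order(out$track_id, out$frame), ]
}
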