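# Apical-basal nuclear positioning: half-max midplane and zone occupancy.

#' Cross-sectional area profile of one nucleus
#'
#' Per z-plane voxel count of a label times the lateral voxel area, ordered
#' apical to basal. Depths are voxel-center positions relative to the apical
#' reference plane.
#'
#' @param lab 3D (z,y,x) integer label array for one frame.
#' @param label the label (track id) to profile.
#' @param voxel_size (dz, dy, dx) in um.
#' @param apical_z_um depth of z index 1 relative to the apical surface
#'   (0 when the first slice is the apical reference).
#' @return data.frame (z_um, area_um2) with attribute `valid` = FALSE when
#'   the label is absent.
#' @export
area_profile <- function(lab, label, voxel_size, apical_z_um = 0) {
  nz <- dim(lab)[1]
  z_um <- apical_z_um + (seq_len(nz) - 1) * voxel_size[1]
  hit <- lab == label
  counts <- if (any(hit)) {
    idx <- which(hit)
    zi <- ((idx - 1L) %% nz) + 1L
    tabulate(zi, nbins = nz)
  } else rep(0L, nz)
  out <- data.frame(z_um = z_um,
                    area_um2 = counts * voxel_size[2] * voxel_size[3])
  attr(out, "valid") <- any(counts > 0L)
  out
}

#' Nuclear midplane from the half-max flanks of an area profile
#'
#' Nuclei in this tissue are often top-heavy, so the widest section is a poor
#' positional readout; instead the midplane is the midpoint between the two
#' half-maximum crossings of the cross-sectional area profile. The maximal
#' area A* is located (plateaus use the plateau midpoint), the outermost
#' apical and basal crossings of A*/2 are found by linear interpolation
#' between adjacent planes, and their midpoint is returned. Profiles whose
#' flanks cannot be tracked - the profile enters or leaves the volume above
#' A*/2 - are invalid and excluded from analysis.
#'
#' @param profile data.frame (z_um, area_um2) from [area_profile()], or two
#'   vectors via `z_um`.
#' @param z_um optional depth vector when `profile` is an area vector.
#' @return midplane depth in um, or `NA` (invalid) with attribute `reason`.
#' @export
nuclear_midplane <- function(profile, z_um = NULL) {
  if (is.data.frame(profile)) {
    a <- profile$area_um2
    z <- profile$z_um
  } else {
    a <- as.numeric(profile)
    z <- z_um
  }
  bad <- function(reason) structure(NA_real_, reason = reason)
  if (!length(a) || all(a <= 0)) return(bad("empty profile"))
  if (any(diff(z) <= 0)) stop("z must be strictly increasing", call. = FALSE)

  amax <- max(a)
  half <- amax / 2
  # flanks untrackable if the profile is cut by the volume boundary above A*/2
  if (a[1] >= half) return(bad("apical flank untrackable"))
  if (a[length(a)] >= half) return(bad("basal flank untrackable"))

  cross_up <- which(a[-length(a)] < half & a[-1] >= half)
  cross_dn <- which(a[-length(a)] >= half & a[-1] < half)
  if (!length(cross_up) || !length(cross_dn)) return(bad("no half-max flank"))

  interp <- function(i, rising) {
    # crossing of `half` between samples i and i+1
    z[i] + (half - a[i]) / (a[i + 1] - a[i]) * (z[i + 1] - z[i])
  }
  z_apical <- interp(min(cross_up))        # outermost apical crossing
  z_basal <- interp(max(cross_dn))         # outermost basal crossing
  (z_apical + z_basal) / 2
}

#' Apical reference depth of a frame
#'
#' The tissue-wide apical reference is the apical-most z slice containing
#' foreground signal at that frame; `per_label = TRUE` instead returns one
#' reference per label (per-cell convention).
#'
#' @param lab 3D label (or logical foreground) array.
#' @param voxel_size (dz, dy, dx), um.
#' @param per_label logical.
#' @return depth in um of the reference plane (or named vector per label).
#' @export
apical_reference <- function(lab, voxel_size, per_label = FALSE) {
  nz <- dim(lab)[1]
  if (!per_label) {
    zs <- which(apply(lab > 0L, 1, any))
    if (!length(zs)) return(NA_real_)
    return((min(zs) - 1) * voxel_size[1])
  }
  idx <- which(lab > 0L)
  zi <- ((idx - 1L) %% nz) + 1L
  mins <- tapply(zi, lab[idx], min)
  (mins - 1) * voxel_size[1]
}

#' Depth category of a nucleus
#'
#' Assigns each depth below the apical surface to the positional categories
#' used for dispersion scoring: the apical-most 2 um (exclusion zone,
#' normally nucleus-free), the apical 10 um (the apical third of a 30-35 um
#' cell), and deeper than 10 um (basal). Exclusion-zone membership implies
#' apical-10 membership.
#'
#' @param depth_um depth(s) below the apical surface, um; must be >= 0.
#' @param exclusion_um,apical_um zone boundaries (defaults 2 and 10 um).
#' @return data.frame: depth_um, category (factor exclusion_zone / apical10 /
#'   basal, the finest category), in_exclusion, in_apical10, in_basal.
#' @export
depth_category <- function(depth_um, exclusion_um = 2, apical_um = 10) {
  if (any(depth_um < 0, na.rm = TRUE))
    stop("depth must be >= 0 (below the apical surface)", call. = FALSE)
  in_ex <- depth_um <= exclusion_um
  in_ap <- depth_um <= apical_um
  cat <- ifelse(in_ex, "exclusion_zone", ifelse(in_ap, "apical10", "basal"))
  data.frame(depth_um = depth_um,
             category = factor(cat, levels = c("exclusion_zone", "apical10",
                                               "basal")),
             in_exclusion = in_ex, in_apical10 = in_ap, in_basal = !in_ap)
}

#' Population fractions per depth category
#'
#' Divides the population in each category by the total valid nuclear
#' population at each time point. Exclusion-zone nuclei also count toward the
#' apical-10 fraction, so `apical10 + basal = 1` at every frame while
#' `exclusion <= apical10`.
#'
#' @param depths data.frame with columns `frame` (or `t_s`) and `depth_um`
#'   (NA = invalid nucleus, dropped), or a numeric vector for one frame.
#' @param exclusion_um,apical_um zone boundaries, um.
#' @return data.frame per frame: frame, n_valid, exclusion, apical10, basal.
#' @export
category_fractions <- function(depths, exclusion_um = 2, apical_um = 10) {
  if (is.numeric(depths))
    depths <- data.frame(frame = 1L, depth_um = depths)
  if (!"frame" %in% names(depths)) depths$frame <- depths$t_s
  rows <- lapply(split(depths, depths$frame), function(df) {
    d <- df$depth_um[!is.na(df$depth_um)]
    if (!length(d))
      return(data.frame(frame = df$frame[1], n_valid = 0L,
                        exclusion = NA_real_, apical10 = NA_real_,
                        basal = NA_real_))
    cc <- depth_category(d, exclusion_um, apical_um)
    data.frame(frame = df$frame[1], n_valid = length(d),
               exclusion = mean(cc$in_exclusion),
               apical10 = mean(cc$in_apical10),
               basal = mean(cc$in_basal))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Midplane depth metrics for every track and frame
#'
#' Computes the area profile and half-max midplane for every (track, frame)
#' of a track-consistent label volume, relative to the tissue-wide apical
#' reference of that frame (or a fixed reference, e.g. 0 for synthetic truth).
#'
#' @param labels a `label_volume` with track-consistent labels.
#' @param apical_reference_um fixed apical reference depth, or NULL to
#'   estimate it per frame from the foreground.
#' @return data.frame: track_id, frame, t_s, midplane_um, valid, category.
#' @export
midplane_metrics <- function(labels, apical_reference_um = NULL) {
  stopifnot(inherits(labels, "label_volume"))
  d <- dim(labels$data)
  vs <- labels$voxel_size
  rows <- list()
  for (t in seq_len(d[1])) {
    fr <- array(labels$data[t, , , ], d[2:4])
    ref <- if (is.null(apical_reference_um)) apical_reference(fr, vs)
           else apical_reference_um
    ids <- sort(unique(fr[fr > 0L]))
    for (id in ids) {
      prof <- area_profile(fr, id, vs, apical_z_um = -ref)
      mid <- nuclear_midplane(prof)
      rows[[length(rows) + 1L]] <- data.frame(
        track_id = id, frame = t, t_s = (t - 1) * labels$frame_interval,
        midplane_um = as.numeric(mid), valid = is.finite(mid))
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(track_id = integer(0), frame = integer(0),
                      t_s = numeric(0), midplane_um = numeric(0),
                      valid = logical(0), category = character(0)))
  out$category <- NA_character_
  ok <- out$valid & out$midplane_um >= 0
  out$category[ok] <-
    as.character(depth_category(out$midplane_um[ok])$category)
  out
}
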