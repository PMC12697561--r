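# Volume and table I/O: multi-page TIFF with a YAML calibration sidecar,
# CSV tables, YAML configurations.

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".yaml")

#' Write a volume series (or label volume) as multi-page TIFF plus sidecar
#'
#' Pages are ordered t-major, z-minor (frame 1 slices apical to basal, then
#' frame 2, ...). Integer-valued data up to 65535 is stored as 16-bit and
#' round-trips bit-identically; other data is stored as 32-bit float at that
#' precision. Physical calibration (axis order, voxel size, frame interval)
#' goes into a YAML sidecar next to the TIFF; reading requires it, the axes
#' are never guessed.
#'
#' @param vol a `volume_series` or `label_volume`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, c("volume_series", "label_volume")))
  d <- dim(vol$data)
  a <- vol$data
  is_label <- inherits(vol, "label_volume")
  integerish <- all(a == round(a)) && max(a) <= 65535 && min(a) >= 0
  if (integerish) {
    scale <- 65535
    bits <- 16L
  } else {
    scale <- max(a, 1e-12)
    bits <- 32L
  }
  pages <- vector("list", d[1] * d[2])
  k <- 0L
  for (t in seq_len(d[1])) for (z in seq_len(d[2])) {
    k <- k + 1L
    pages[[k]] <- matrix(a[t, z, , ] / scale, d[3], d[4])
  }
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  yaml::write_yaml(list(axes = "tzyx", shape = as.integer(d),
                        voxel_size_um = vol$voxel_size,
                        frame_interval_s = vol$frame_interval,
                        scale = scale, bits = bits,
                        kind = if (is_label) "label" else "intensity"),
                   sidecar_path(path))
  invisible(path)
}

#' Read a volume written by [write_volume()]
#'
#' @param path TIFF path; the YAML sidecar must sit next to it.
#' @return a `volume_series` or `label_volume` per the sidecar's `kind`.
#' @export
read_volume <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop("missing calibration sidecar '", sc,
         "': voxel size and axis order are never guessed", call. = FALSE)
  meta <- yaml::read_yaml(sc)
  if (is.null(meta$axes) || !identical(meta$axes, "tzyx"))
    stop("sidecar must declare axes: tzyx (got '",
         if (is.null(meta$axes)) "none" else meta$axes,
         "'); re-export the volume with a time axis", call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- as.integer(meta$shape)
  if (length(pages) != d[1] * d[2])
    stop("page count does not match sidecar shape", call. = FALSE)
  a <- array(0, d)
  k <- 0L
  for (t in seq_len(d[1])) for (z in seq_len(d[2])) {
    k <- k + 1L
    a[t, z, , ] <- pages[[k]] * meta$scale
  }
  if (identical(meta$bits, 16L) || meta$bits == 16) a <- round(a)
  if (identical(meta$kind, "label"))
    label_volume(array(as.integer(a), d), meta$voxel_size_um,
                 meta$frame_interval_s)
  else
    volume_series(a, meta$voxel_size_um, meta$frame_interval_s)
}

#' Write / read tabular artifacts as CSV
#'
#' Column names carry their units (e.g. `z_um`, `t_s`, `speed_um_min`).
#'
#' @param df data.frame.
#' @param path CSV path.
#' @return the path / the data.frame.
#' @export
write_table_csv <- function(df, path) {
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) read.csv(path, stringsAsFactors = FALSE)

#' Write / read a scene configuration as YAML
#'
#' @param config a [scene_config()].
#' @param path YAML path.
#' @export
write_scene_config <- function(config, path) {
  stopifnot(inherits(config, "scene_config"))
  lst <- unclass(config)
  lst$motion_mix <- as.list(lst$motion_mix)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_scene_config
#' @export
read_scene_config <- function(path) {
  lst <- yaml::read_yaml(path)
  lst$motion_mix <- unlist(lst$motion_mix)
  do.call(scene_config, lst)
}
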