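#' Construct a 4D volume series
#'
#' The raw imaging container used throughout the pipeline: a 4D intensity grid
#' in axis order (t, z, y, x) together with its physical calibration. The z
#' axis points basally, i.e. slice index 1 is the apical-most plane and
#' physical depth increases with slice index. Voxel centers sit at
#' `(index - 1) * voxel_size` micrometres so that the apical-most slice center
#' defines depth 0.
#'
#' @param data numeric 4D array, dimensions (t, z, y, x), finite and >= 0.
#' @param voxel_size numeric length 3, voxel edge lengths (dz, dy, dx) in
#'   micrometres.
#' @param frame_interval time between frames in seconds.
#' @return An object of class `volume_series`.
#' @export
volume_series <- function(data, voxel_size, frame_interval) {
  if (length(dim(data)) == 3L) dim(data) <- c(1L, dim(data))
  if (length(dim(data)) != 4L)
    stop("'data' must be a 4D (t,z,y,x) array", call. = FALSE)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("'voxel_size' must be 3 positive numbers (dz, dy, dx) in um",
         call. = FALSE)
  stopifnot_scalar(frame_interval, "frame_interval")
  if (any(!is.finite(data)) || any(data < 0))
    stop("intensities must be finite and >= 0", call. = FALSE)
  structure(
    list(data = data, voxel_size = as.numeric(voxel_size),
         frame_interval = as.numeric(frame_interval)),
    class = "volume_series")
}

#' @export
print.volume_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<volume_series> %d frame(s), %d x %d x %d (z,y,x) voxels of %.3g x %.3g x %.3g um, dt = %.3g s\n",
    d[1], d[2], d[3], d[4], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
    x$frame_interval))
  invisible(x)
}

#' Extract one frame of a volume series as a 3D (z,y,x) array
#' @param vol a `volume_series` or `label_volume`.
#' @param t frame index (1-based).
#' @return 3D array.
#' @export
get_frame <- function(vol, t) {
  d <- dim(vol$data)
  if (t < 1 || t > d[1]) stop("frame index out of range", call. = FALSE)
  array(vol$data[t, , , ], d[2:4])
}

#' Construct a label volume aligned to a volume series
#'
#' Integer-labelled segmentation grid, 0 = background. Labels within one frame
#' identify objects; `track_map` (optional) maps frame-local labels to track
#' ids when labels are already track-consistent it can be omitted.
#'
#' @param labels integer 4D array (t, z, y, x).
#' @param voxel_size,frame_interval physical calibration, as [volume_series()].
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, voxel_size, frame_interval) {
  if (length(dim(labels)) == 3L) dim(labels) <- c(1L, dim(labels))
  if (length(dim(labels)) != 4L)
    stop("'labels' must be a 4D (t,z,y,x) array", call. = FALSE)
  if (any(labels < 0)) stop("labels must be >= 0", call. = FALSE)
  structure(
    list(data = labels, voxel_size = as.numeric(voxel_size),
         frame_interval = as.numeric(frame_interval)),
    class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<label_volume> %d frame(s), %d x %d x %d voxels, %d label(s)\n",
              d[1], d[2], d[3], d[4], length(setdiff(unique(as.vector(x$data)), 0L))))
  invisible(x)
}
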