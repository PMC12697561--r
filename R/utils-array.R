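# Internal helpers for 3D (z,y,x) volumes stored as base R arrays.

stopifnot_scalar <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}

#' Gaussian kernel sampled at integer offsets, normalized to sum 1
#' @noRd
gauss_kernel <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-((-r):r)^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# Apply a 1D kernel along one axis of a 3D array (edge-replicate padding).
conv_axis <- function(a, kernel, axis) {
  if (length(kernel) == 1L) return(a * kernel)
  d <- dim(a)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  b <- aperm(a, perm)
  db <- dim(b)
  m <- cpp_conv1_first(matrix(b, nrow = db[1]), kernel)
  b <- array(m, dim = db)
  aperm(b, order(perm))
}

# Separable Gaussian smoothing of a 3D array; sigma in voxels per axis (z,y,x).
gauss_blur3 <- function(a, sigma_vox) {
  for (ax in 1:3) a <- conv_axis(a, gauss_kernel(sigma_vox[ax]), ax)
  a
}

# Separable local (moving) mean over a cubic window; width in voxels per axis.
box_mean3 <- function(a, width_vox) {
  for (ax in 1:3) {
    w <- max(1L, as.integer(width_vox[ax]))
    if (w %% 2L == 0L) w <- w + 1L
    if (w > 1L) a <- conv_axis(a, rep(1 / w, w), ax)
  }
  a
}

# Central-difference gradient magnitude of a 3D array (unit voxel spacing).
gradient_magnitude3 <- function(a) {
  d <- dim(a)
  g2 <- array(0, d)
  for (ax in 1:3) {
    n <- d[ax]
    ip <- pmin(seq_len(n) + 1L, n)
    im <- pmax(seq_len(n) - 1L, 1L)
    if (ax == 1) dx <- (a[ip, , , drop = FALSE] - a[im, , , drop = FALSE]) / 2
    if (ax == 2) dx <- (a[, ip, , drop = FALSE] - a[, im, , drop = FALSE]) / 2
    if (ax == 3) dx <- (a[, , ip, drop = FALSE] - a[, , im, drop = FALSE]) / 2
    g2 <- g2 + dx^2
  }
  sqrt(g2)
}

# Euclidean distance transform of a logical 3D array: distance from each TRUE
# voxel to the nearest FALSE voxel, in the units of `spacing`.
edt3 <- function(mask, spacing = c(1, 1, 1)) {
  d <- dim(mask)
  sq <- cpp_edt3d(as.logical(mask), as.integer(d), as.numeric(spacing))
  array(sqrt(sq), d)
}

# 6-connected component labelling of a logical 3D array.
label_components3 <- function(mask) {
  d <- dim(mask)
  array(cpp_cclabel3d(as.logical(mask), as.integer(d)), d)
}
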