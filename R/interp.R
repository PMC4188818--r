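# Low-level volume operations: trilinear sampling, separable Gaussian
# smoothing, dyadic downsampling, central-difference gradients.  All volumes
# are plain 3D numeric arrays; continuous voxel coordinates are 1-based.

#' Sample a volume at continuous voxel coordinates (trilinear)
#'
#' @param vol 3D numeric array.
#' @param coords n x 3 matrix of continuous 1-based voxel coordinates.
#' @param fill value returned for coordinates outside the volume.
#' @return numeric vector of length n.
#' @export
trilinear_sample <- function(vol, coords, fill = NA_real_) {
  d <- dim(vol)
  stopifnot(length(d) == 3)
  coords <- matrix(as.numeric(coords), ncol = 3)
  xi <- coords[, 1]; yi <- coords[, 2]; zi <- coords[, 3]
  inside <- xi >= 1 & xi <= d[1] & yi >= 1 & yi <= d[2] & zi >= 1 & zi <= d[3] &
    is.finite(xi) & is.finite(yi) & is.finite(zi)
  out <- rep(fill, nrow(coords))
  if (!any(inside)) return(out)
  xi <- xi[inside]; yi <- yi[inside]; zi <- zi[inside]
  # lower corner, clamped so points exactly on the far face still
  # interpolate; singleton axes collapse to a single sample with weight 0
  x0 <- pmax(pmin(floor(xi), d[1] - 1L), 1)
  y0 <- pmax(pmin(floor(yi), d[2] - 1L), 1)
  z0 <- pmax(pmin(floor(zi), d[3] - 1L), 1)
  x1 <- pmin(x0 + 1, d[1]); y1 <- pmin(y0 + 1, d[2]); z1 <- pmin(z0 + 1, d[3])
  fx <- xi - x0; fy <- yi - y0; fz <- zi - z0
  lin <- function(i, j, k) ((k - 1) * d[2] + (j - 1)) * d[1] + i
  v <- as.numeric(vol)
  c000 <- v[lin(x0, y0, z0)]
  c100 <- v[lin(x1, y0, z0)]
  c010 <- v[lin(x0, y1, z0)]
  c110 <- v[lin(x1, y1, z0)]
  c001 <- v[lin(x0, y0, z1)]
  c101 <- v[lin(x1, y0, z1)]
  c011 <- v[lin(x0, y1, z1)]
  c111 <- v[lin(x1, y1, z1)]
  out[inside] <-
    (1 - fz) * ((1 - fy) * ((1 - fx) * c000 + fx * c100) +
                 fy       * ((1 - fx) * c010 + fx * c110)) +
    fz       * ((1 - fy) * ((1 - fx) * c001 + fx * c101) +
                 fy       * ((1 - fx) * c011 + fx * c111))
  out
}

#' Nearest-neighbour sampling (for masks and label volumes)
#' @inheritParams trilinear_sample
#' @export
nearest_sample <- function(vol, coords, fill = NA_real_) {
  d <- dim(vol)
  coords <- matrix(as.numeric(coords), ncol = 3)
  xi <- round(coords[, 1]); yi <- round(coords[, 2]); zi <- round(coords[, 3])
  inside <- xi >= 1 & xi <= d[1] & yi >= 1 & yi <= d[2] & zi >= 1 & zi <= d[3] &
    is.finite(xi) & is.finite(yi) & is.finite(zi)
  out <- rep(fill, nrow(coords))
  lin <- ((zi[inside] - 1) * d[2] + (yi[inside] - 1)) * d[1] + xi[inside]
  out[inside] <- as.numeric(vol)[lin]
  out
}

# shift an array by an integer offset along one axis, replicating edges
shift_axis <- function(vol, offset, axis) {
  d <- dim(vol)
  idx <- pmin(pmax(seq_len(d[axis]) + offset, 1L), d[axis])
  switch(axis, vol[idx, , , drop = FALSE], vol[, idx, , drop = FALSE],
         vol[, , idx, drop = FALSE])
}

#' Separable Gaussian smoothing of a 3D array
#'
#' Edge handling is replicate-padding; the kernel is truncated at 3 sigma and
#' renormalized.  \code{sigma} is in voxels, one value per axis (recycled).
#'
#' @param vol 3D numeric array.
#' @param sigma Gaussian SD in voxels (scalar or length 3).
#' @export
gaussian_smooth <- function(vol, sigma = 1) {
  sigma <- rep_len(sigma, 3)
  out <- vol
  for (axis in 1:3) {
    s <- sigma[axis]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    w <- exp(-(seq(-r, r))^2 / (2 * s^2))
    w <- w / sum(w)
    acc <- array(0, dim(vol))
    for (o in seq(-r, r)) acc <- acc + w[o + r + 1] * shift_axis(out, o, axis)
    out <- acc
  }
  out
}

# smooth then take every other voxel; spacing doubles along axes with >= 4
# voxels (thin axes are left at full resolution so tiny z-extents survive)
downsample2 <- function(vol, spacing) {
  d <- dim(vol)
  sm_sigma <- ifelse(d >= 4, 1, 0)
  sm <- gaussian_smooth(vol, sm_sigma)
  ix <- lapply(1:3, function(a) if (d[a] >= 4) seq(1L, d[a], by = 2L) else seq_len(d[a]))
  list(vol = sm[ix[[1]], ix[[2]], ix[[3]], drop = FALSE],
       spacing = spacing * ifelse(d >= 4, 2, 1))
}

#' Central-difference gradient of a volume in mm units
#' @param vol 3D numeric array.
#' @param spacing voxel spacing in mm (length 3).
#' @return list of three arrays: the partial derivatives along x, y, z.
#' @export
volume_gradient <- function(vol, spacing) {
  lapply(1:3, function(axis)
    (shift_axis(vol, 1L, axis) - shift_axis(vol, -1L, axis)) / (2 * spacing[axis]))
}

# mm coordinates of every voxel of a grid, as an n x 3 matrix (grid order)
grid_mm_coords <- function(dim3, spacing) {
  cbind(rep((seq_len(dim3[1]) - 1) * spacing[1], times = dim3[2] * dim3[3]),
        rep(rep((seq_len(dim3[2]) - 1) * spacing[2], each = dim3[1]), times = dim3[3]),
        rep((seq_len(dim3[3]) - 1) * spacing[3], each = dim3[1] * dim3[2]))
}

#' Resample a volume under an affine transform
#'
#' The transform maps output-grid mm coordinates to input-volume mm
#' coordinates (pull-back); intensities are interpolated trilinearly.
#'
#' @param vol 3D numeric array (the source).
#' @param transform \code{affine3d} mapping output mm to source mm.
#' @param spacing source voxel spacing (mm).
#' @param out_dim,out_spacing output grid; default: same as the source.
#' @param fill value for voxels mapping outside the source.
#' @export
resample_volume <- function(vol, transform, spacing,
                            out_dim = dim(vol), out_spacing = spacing,
                            fill = NA_real_) {
  pts <- grid_mm_coords(out_dim, out_spacing)
  src_mm <- affine_apply(transform, pts)
  src_vox <- sweep(src_mm, 2, spacing, `/`) + 1
  array(trilinear_sample(vol, src_vox, fill = fill), out_dim)
}
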