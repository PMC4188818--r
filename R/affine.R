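#' Affine transforms in scanner (mm) space
#'
#' An \code{affine3d} is a 4x4 homogeneous matrix acting on 3D points in
#' millimetre coordinates: \code{y = A x + t}, with \code{A} the 3x3 linear
#' part and \code{t} the translation.  The package convention for resampling
#' is the pull-back map: a transform passed to [resample_volume()] or
#' [resample_map()] maps points of the \emph{output} (reference) grid to
#' points of the \emph{input} (source) volume.
#'
#' Voxel \code{(i, j, k)} (1-based) of a volume with spacing
#' \code{s = (sx, sy, sz)} sits at mm position \code{(i-1)*sx, (j-1)*sy,
#' (k-1)*sz}; no additional origin or orientation is modelled.
#'
#' @param linear 3x3 linear part (must be invertible).
#' @param translation length-3 translation in mm.
#' @return An object of class \code{affine3d} (a 4x4 numeric matrix).
#' @export
affine3d <- function(linear = diag(3), translation = c(0, 0, 0)) {
  linear <- as.matrix(linear)
  stopifnot(identical(dim(linear), c(3L, 3L)), length(translation) == 3)
  if (abs(det(linear)) < .Machine$double.eps * 64)
    stop("affine3d: linear part is not invertible (det ~ 0)")
  m <- diag(4)
  m[1:3, 1:3] <- linear
  m[1:3, 4] <- as.numeric(translation)
  class(m) <- c("affine3d", "matrix")
  m
}

#' @rdname affine3d
#' @export
affine_identity <- function() affine3d()

#' @rdname affine3d
#' @param params length-12 parameter vector: the 9 entries of the linear part
#'   (row-major) followed by the translation.
#' @export
affine_from_params <- function(params) {
  stopifnot(length(params) == 12)
  affine3d(matrix(params[1:9], 3, 3, byrow = TRUE), params[10:12])
}

#' @rdname affine3d
#' @param transform an \code{affine3d}.
#' @export
affine_params <- function(transform) {
  c(t(transform[1:3, 1:3]), transform[1:3, 4])
}

#' Compose two affine transforms
#'
#' \code{affine_compose(a, b)} returns the transform applying \code{b} first,
#' then \code{a} (i.e. \code{x -> a(b(x))}).
#'
#' @param a,b \code{affine3d} objects.
#' @export
affine_compose <- function(a, b) {
  m <- unclass(a) %*% unclass(b)
  class(m) <- c("affine3d", "matrix")
  m
}

#' Invert an affine transform
#' @param transform an \code{affine3d}.
#' @export
affine_invert <- function(transform) {
  a <- transform[1:3, 1:3]
  ai <- solve(a)
  affine3d(ai, -ai %*% transform[1:3, 4])
}

#' Apply an affine transform to points
#' @param transform an \code{affine3d}.
#' @param pts n x 3 matrix of mm coordinates.
#' @return n x 3 matrix of transformed coordinates.
#' @export
affine_apply <- function(transform, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  sweep(pts %*% t(transform[1:3, 1:3]), 2, transform[1:3, 4], `+`)
}

#' Translation-only transform given in voxel units
#' @param voxels length-3 shift in voxels.
#' @param spacing length-3 voxel spacing in mm.
#' @export
affine_translate_voxels <- function(voxels, spacing) {
  affine3d(diag(3), as.numeric(voxels) * as.numeric(spacing))
}

#' Serialize / deserialize a transform as JSON
#'
#' Written as a row-major 4x4 homogeneous matrix in mm units together with a
#' convention string, so that transforms survive a round trip to disk.
#'
#' @param transform an \code{affine3d}.
#' @param path file path.
#' @export
write_affine_json <- function(transform, path) {
  jsonlite::write_json(
    list(convention = "output_mm_to_input_mm, y = A x + t, row-major 4x4",
         matrix = matrix(unclass(transform), 4, 4)),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_affine_json
#' @export
read_affine_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- matrix(as.numeric(obj$matrix), 4, 4)  # rowmajor written => read back as rows
  affine3d(m[1:3, 1:3], m[1:3, 4])
}

#' @export
print.affine3d <- function(x, ...) {
  cat("affine3d (mm space, y = A x + t):\n")
  print(unclass(x))
  invisible(x)
}
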