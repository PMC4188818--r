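#' Robust affine multiresolution registration of ADC maps
#'
#' Aligns \code{moving} to \code{reference} with a 12-parameter affine
#' transform estimated coarse-to-fine over a Gaussian resolution pyramid.
#' At each level the linearized brightness constraint is solved by
#' iteratively reweighted least squares under a Geman-McClure robust error
#' norm on the intensity residuals, so that focal signal change (e.g. a
#' responding tumor) does not drag the global alignment.  The affine is
#' parameterized about the reference-volume centre for numerical
#' conditioning.
#'
#' Quality control follows the duplicate-baseline convention: the Pearson
#' correlation between the two maps over the whole volume (on the
#' intersection of their validity masks) is reported before and after
#' registration.  If registration would lower the correlation by more than
#' \code{qc_tol}, the identity transform is returned instead and the QC
#' record is flagged (\code{fallback = TRUE}) with a warning.
#'
#' @param moving,reference [adc_map()] objects on grids with equal spacing.
#' @param levels pyramid depth (>= 1); each level halves the resolution
#'   (axes with < 4 voxels are kept at full resolution).
#' @param max_iter maximum IRLS iterations per level.
#' @param tol convergence threshold on the scaled parameter-update norm
#'   (translations are measured relative to the volume half-extent).
#' @param qc_tol largest tolerated QC degradation before falling back to
#'   the identity transform.
#' @param intensity_match \code{"none"} (maps share an intensity scale, the
#'   default for same-contrast ADC maps) or \code{"affine"}: a per-iteration
#'   linear intensity mapping \code{a M + b} is estimated alongside the
#'   geometry, making the similarity invariant to global contrast
#'   differences (correlation-like), as needed when aligning different
#'   b-value images of one session.
#' @return list with \code{transform} (an [affine3d()] mapping reference mm
#'   coordinates to moving mm coordinates), \code{qc} (a
#'   \code{registration_qc}: \code{before}, \code{after}, \code{n_voxels},
#'   \code{fallback}), and \code{trace} (per-level iteration counts).
#' @export
register_affine <- function(moving, reference, levels = 3, max_iter = 50,
                            tol = 1e-4, qc_tol = 0.01,
                            intensity_match = c("none", "affine")) {
  intensity_match <- match.arg(intensity_match)
  stopifnot(inherits(moving, "adc_map"), inherits(reference, "adc_map"),
            levels >= 1)
  if (max(abs(moving$spacing - reference$spacing)) > 1e-9)
    stop("register_affine: maps must share voxel spacing")

  qc_before <- registration_qc_cor(moving, reference, affine_identity())
  if (is.na(qc_before$r))
    stop("register_affine: validity masks have empty overlap")

  pyr_ref <- build_pyramid(reference, levels)
  pyr_mov <- build_pyramid(moving, levels)
  centre <- (dim(reference$data) - 1) * reference$spacing / 2
  half_extent <- max((dim(reference$data) - 1) * reference$spacing) / 2

  A <- diag(3); tr <- c(0, 0, 0)   # T(x) = A (x - c) + c + tr
  trace <- integer(0)
  for (lev in seq(levels, 1)) {
    rl <- pyr_ref[[lev]]; ml <- pyr_mov[[lev]]
    sel <- which(rl$valid)
    if (length(sel) < 60) { trace <- c(trace, 0L); next }
    Xc <- sweep(grid_mm_coords(dim(rl$vol), rl$spacing)[sel, , drop = FALSE],
                2, centre, `-`)
    Rv <- rl$vol[sel]
    grad <- volume_gradient(ml$vol, ml$spacing)
    iters <- 0L
    for (it in seq_len(max_iter)) {
      iters <- it
      src_mm <- Xc %*% t(A) + rep(centre + tr, each = nrow(Xc))
      src_vox <- sweep(src_mm, 2, ml$spacing, `/`) + 1
      Mw <- trilinear_sample(ml$vol, src_vox)
      Vw <- trilinear_sample(ml$validnum, src_vox, fill = 0)
      g1 <- trilinear_sample(grad[[1]], src_vox)
      g2 <- trilinear_sample(grad[[2]], src_vox)
      g3 <- trilinear_sample(grad[[3]], src_vox)
      ok <- is.finite(Mw) & Vw > 0.99 & is.finite(g1) & is.finite(g2) &
        is.finite(g3)
      if (sum(ok) < 60) break
      ia <- 1; ib <- 0
      if (intensity_match == "affine" && stats::var(Mw[ok]) > 0) {
        ia <- stats::cov(Mw[ok], Rv[ok]) / stats::var(Mw[ok])
        ib <- mean(Rv[ok]) - ia * mean(Mw[ok])
      }
      e <- ia * Mw[ok] + ib - Rv[ok]
      # self-tuning robust scale: the 90% quantile of |residual| keeps the
      # fit close to least squares while grossly misaligned (almost no
      # voxel is an outlier) yet strongly downweights focal signal change
      # once the bulk of the volume agrees; floored so large perfectly-
      # matching regions cannot collapse the scale
      s <- max(stats::quantile(abs(e), 0.9), 0.02 * stats::sd(Rv), 1e-8)
      w <- 1 / (1 + (e / s)^2)^2
      X1 <- Xc[ok, 1]; X2 <- Xc[ok, 2]; X3 <- Xc[ok, 3]
      h1 <- ia * g1[ok]; h2 <- ia * g2[ok]; h3 <- ia * g3[ok]
      J <- cbind(h1 * X1, h1 * X2, h1 * X3,
                 h2 * X1, h2 * X2, h2 * X3,
                 h3 * X1, h3 * X2, h3 * X3,
                 h1, h2, h3)
      sw <- sqrt(w)
      Jw <- J * sw
      JtJ <- crossprod(Jw)
      diag(JtJ) <- diag(JtJ) * (1 + 1e-8) + 1e-12
      delta <- tryCatch(solve(JtJ, -crossprod(Jw, e * sw)),
                        error = function(err) NULL)
      if (is.null(delta)) break
      # robust cost under the current scale, for step control
      gm_cost <- function(A2, t2) {
        sm <- Xc %*% t(A2) + rep(centre + t2, each = nrow(Xc))
        Mw2 <- trilinear_sample(ml$vol, sweep(sm, 2, ml$spacing, `/`) + 1)
        ok2 <- is.finite(Mw2)
        e2 <- (ia * Mw2[ok2] + ib - Rv[ok2]) / s
        sum(e2^2 / (1 + e2^2)) + (sum(ok) - sum(ok2))  # leaving the FOV costs
      }
      cost0 <- gm_cost(A, tr)
      step <- 1
      repeat {
        dA <- step * matrix(delta[1:9], 3, 3, byrow = TRUE)
        dt <- step * delta[10:12]
        if (gm_cost(A + dA, tr + dt) <= cost0 || step < 0.2) break
        step <- step / 2
      }
      A <- A + dA
      tr <- tr + dt
      upd <- sqrt(sum(dA^2) + sum((dt / half_extent)^2))
      if (!is.finite(upd) || upd < tol) break
    }
    trace <- c(trace, iters)
  }

  transform <- affine3d(A, centre - A %*% centre + tr)
  qc_after <- registration_qc_cor(moving, reference, transform)
  fallback <- is.na(qc_after$r) || qc_after$r < qc_before$r - qc_tol
  if (fallback) {
    warning("register_affine: similarity not improved; returning identity")
    transform <- affine_identity()
    qc_after <- qc_before
  }
  qc <- structure(list(before = qc_before$r, after = qc_after$r,
                       n_voxels = qc_after$n, fallback = fallback),
                  class = "registration_qc")
  list(transform = transform, qc = qc, trace = rev(trace))
}

#' @export
print.registration_qc <- function(x, ...) {
  cat(sprintf("registration QC: Pearson r %.3f -> %.3f over %d voxels%s\n",
              x$before, x$after, x$n_voxels,
              if (isTRUE(x$fallback)) " [fallback to identity]" else ""))
  invisible(x)
}

# whole-volume Pearson correlation of two maps under a candidate transform
registration_qc_cor <- function(moving, reference, transform) {
  warped <- resample_map(moving, transform, reference)
  both <- warped$valid & reference$valid
  n <- sum(both)
  if (n < 3) return(list(r = NA_real_, n = n))
  if (stats::sd(warped$data[both]) == 0 || stats::sd(reference$data[both]) == 0)
    return(list(r = NA_real_, n = n))
  list(r = stats::cor(warped$data[both], reference$data[both]), n = n)
}

# Gaussian pyramid of (volume, validity) pairs; level 1 = full resolution.
# Invalid voxels are infilled with the valid median before smoothing so they
# do not bleed NA into their neighbourhood; validity is tracked alongside.
build_pyramid <- function(map, levels) {
  vol <- map$data
  vol[!map$valid] <- stats::median(map$data[map$valid])
  validnum <- array(as.numeric(map$valid), dim(map$valid))
  out <- vector("list", levels)
  spacing <- map$spacing
  out[[1]] <- list(vol = gaussian_smooth(vol, 1), validnum = validnum,
                   valid = map$valid, spacing = spacing)
  cur <- vol; curv <- validnum
  for (lev in seq_len(levels - 1)) {
    dn <- downsample2(cur, spacing)
    dv <- downsample2(curv, spacing)
    cur <- dn$vol; curv <- dv$vol; spacing <- dn$spacing
    out[[lev + 1]] <- list(vol = gaussian_smooth(cur, 1), validnum = curv,
                           valid = curv > 0.5, spacing = spacing)
  }
  out
}

#' Resample an ADC map onto a reference grid
#'
#' Intensities are interpolated trilinearly; the validity mask is propagated
#' conservatively: an output voxel is valid only if every source voxel
#' contributing to its interpolated value was valid and inside the volume.
#' This erosion prevents partial-volume contamination of lesion statistics
#' at mask borders.
#'
#' @param map an [adc_map()].
#' @param transform [affine3d()] mapping reference mm to source mm.
#' @param reference_grid an \code{adc_map} (grid copied from it) or a list
#'   with elements \code{dim} and \code{spacing}.
#' @return an [adc_map()] on the reference grid with registration
#'   provenance recorded.
#' @export
resample_map <- function(map, transform, reference_grid) {
  stopifnot(inherits(map, "adc_map"))
  if (inherits(reference_grid, "adc_map"))
    grid <- list(dim = dim(reference_grid$data),
                 spacing = reference_grid$spacing,
                 session = reference_grid$session)
  else grid <- reference_grid
  vol <- map$data
  vol[!map$valid] <- 0  # value irrelevant: masked out below
  dat <- resample_volume(vol, transform, map$spacing,
                         out_dim = grid$dim, out_spacing = grid$spacing)
  vnum <- resample_volume(array(as.numeric(map$valid), dim(map$valid)),
                          transform, map$spacing,
                          out_dim = grid$dim, out_spacing = grid$spacing,
                          fill = 0)
  valid <- vnum > 1 - 1e-9  # all 8 contributing voxels valid
  adc_map(dat, valid = valid,
          spacing = grid$spacing, session = map$session,
          provenance = list(transform = unclass(transform),
                            reference = grid$session %||% "grid"))
}

#' Resample a binary mask onto a reference grid (nearest neighbour)
#'
#' @param mask 3D logical array.
#' @param transform [affine3d()] mapping reference mm to source mm.
#' @param spacing source spacing (mm).
#' @param out_dim,out_spacing output grid (defaults: source grid).
#' @export
resample_mask <- function(mask, transform, spacing, out_dim = dim(mask),
                          out_spacing = spacing) {
  pts <- grid_mm_coords(out_dim, out_spacing)
  src_vox <- sweep(affine_apply(transform, pts), 2, spacing, `/`) + 1
  array(nearest_sample(array(as.numeric(mask), dim(mask)), src_vox,
                       fill = 0) > 0.5, out_dim)
}

#' Pearson product-moment correlation with guards
#'
#' The coregistration quality indicator: the standard product-moment
#' correlation, computed only when both sequences have at least 3 paired
#' values and nonzero variance (a degenerate input is a descriptive error,
#' not a silent NA).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation in [-1, 1].
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("pearson_correlation: unequal lengths")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("pearson_correlation: fewer than 3 paired values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("pearson_correlation: zero variance in an input")
  stats::cor(x, y)
}
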