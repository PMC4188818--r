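#' Fit an ADC map by mono-exponential (log-linear) regression
#'
#' At each voxel, ordinary least squares of \code{log(S(b))} against \code{b}
#' over all b-values of the series; the ADC is minus the slope, reported in
#' 1e-3 mm^2/s.  A voxel enters the fit only if every one of its signals is
#' at least \code{min_signal}; otherwise it is marked invalid in the
#' fit-validity mask (value \code{NA}), never raised as an error.  With the
#' b = 100/600/800 s/mm^2 protocol the lowest b-value is deliberately
#' non-zero (perfusion suppression), so no extrapolation to b = 0 is done
#' and S0 is never reported.
#'
#' @param series a [dwi_series()].
#' @param min_signal signal floor (same units as the volumes); voxels with
#'   any signal below it are excluded. Default 1.
#' @return an [adc_map()] for the series' session.
#' @examples
#' b <- c(100, 600, 800)
#' vols <- lapply(b, function(bb) array(1000 * exp(-bb * 1e-3), c(2, 2, 2)))
#' names(vols) <- b
#' fit <- fit_adc_map(dwi_series(vols, spacing = c(2, 2, 6)))
#' fit$data[1, 1, 1]  # 1.000 (x1e-3 mm^2/s)
#' @export
fit_adc_map <- function(series, min_signal = 1) {
  stopifnot(inherits(series, "dwi_series"), min_signal > 0)
  b <- series$bvalues
  d <- dim(series$volumes[[1]])
  sig <- vapply(series$volumes, as.numeric, numeric(prod(d)))  # nvox x nb
  valid <- rowSums(sig < min_signal | !is.finite(sig)) == 0
  if (!any(valid))
    stop("fit_adc_map: no voxel has all signals >= min_signal; map would be empty")
  cb <- b - mean(b)
  sxx <- sum(cb^2)
  slope <- rep(NA_real_, nrow(sig))
  slope[valid] <- (log(sig[valid, , drop = FALSE]) %*% cb) / sxx
  adc <- array(-slope * 1000, d)  # mm^2/s -> 1e-3 mm^2/s
  adc_map(adc, valid = array(valid, d), spacing = series$spacing,
          session = series$session)
}

#' Correct eddy-current-induced warping within a session
#'
#' Diffusion-weighted echo-planar volumes are geometrically warped by eddy
#' currents in a b-value-dependent way.  Each higher-b volume is affinely
#' registered to the lowest-b volume of the same session by the robust
#' multiresolution algorithm of [register_affine()].  The b-value images
#' differ in contrast by (approximately) a monotone intensity map, so each
#' higher-b volume is first quantile-matched to the lowest-b volume —
#' making the similarity correlation-like and contrast-insensitive — and
#' the resulting transform is applied to the original signals.  If
#' registration fails to improve the correlation
#' for a volume, that volume is returned unchanged and a warning is
#' recorded on the series — data are never silently distorted.
#'
#' @param series a [dwi_series()].
#' @param levels resolution-pyramid depth passed to [register_affine()].
#' @return a new \code{dwi_series} with higher-b volumes aligned to the
#'   lowest-b volume; estimated transforms are stored in
#'   \code{$eddy_transforms}, warnings in \code{$warnings}.
#' @export
correct_eddy_warp <- function(series, levels = 3) {
  stopifnot(inherits(series, "dwi_series"))
  refvol <- series$volumes[[1]]
  ref <- adc_map(refvol, spacing = series$spacing, session = series$session)
  probs <- seq(0, 1, length.out = 256)
  rq <- stats::quantile(refvol, probs)
  out <- series
  out$eddy_transforms <- vector("list", length(series$bvalues))
  names(out$eddy_transforms) <- names(series$volumes)
  out$eddy_transforms[[1]] <- affine_identity()
  for (i in seq_along(series$volumes)[-1]) {
    v <- series$volumes[[i]]
    mq <- stats::quantile(v, probs)
    matched <- array(stats::approx(mq, rq, xout = as.numeric(v), rule = 2,
                                   ties = "ordered")$y, dim(v))
    mov <- adc_map(matched, spacing = series$spacing, session = series$session)
    reg <- register_affine(mov, ref, levels = levels)
    if (isTRUE(reg$qc$fallback)) {
      out$warnings <- c(out$warnings, sprintf(
        "eddy correction: registration of b=%s did not improve similarity; volume left unchanged",
        names(series$volumes)[i]))
      out$eddy_transforms[[i]] <- affine_identity()
      next
    }
    out$eddy_transforms[[i]] <- reg$transform
    out$volumes[[i]] <- resample_volume(series$volumes[[i]], reg$transform,
                                        series$spacing, fill = 0)
  }
  out
}
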