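#' DWI series: one session's stack of b-value volumes
#'
#' Container for a single imaging session: a named list of 3D signal volumes
#' keyed by b-value (s/mm^2), a voxel spacing in mm, and a session label
#' (\code{"baseline1"}, \code{"baseline2"}, \code{"week1"}, \code{"week2"},
#' \code{"week6"}, or any other identifier).
#'
#' @param volumes named list of 3D arrays; names are b-values in s/mm^2.
#' @param spacing length-3 voxel spacing in mm.
#' @param session session label.
#' @return object of class \code{dwi_series}.
#' @export
dwi_series <- function(volumes, spacing, session = "unlabelled") {
  bvals <- suppressWarnings(as.numeric(names(volumes)))
  if (length(volumes) < 2 || anyNA(bvals) || anyDuplicated(bvals) ||
      any(bvals <= 0))
    stop("dwi_series: need >= 2 distinct positive b-values as volume names")
  dims <- lapply(volumes, dim)
  if (any(vapply(dims, length, 1L) != 3) ||
      !all(vapply(dims, identical, TRUE, dims[[1]])))
    stop("dwi_series: all volumes must be 3D arrays of identical shape")
  stopifnot(length(spacing) == 3, all(spacing > 0))
  structure(list(volumes = volumes[order(bvals)],
                 bvalues = sort(bvals),
                 spacing = as.numeric(spacing),
                 session = session,
                 warnings = character(0)),
            class = "dwi_series")
}

#' @export
print.dwi_series <- function(x, ...) {
  cat(sprintf("dwi_series '%s': %s voxels @ %s mm, b = %s s/mm^2\n",
              x$session, paste(dim(x$volumes[[1]]), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x"),
              paste(x$bvalues, collapse = "/")))
  invisible(x)
}

#' ADC map: apparent diffusion coefficients for one session
#'
#' A 3D scalar field of ADC values in units of 1e-3 mm^2/s, together with a
#' fit-validity mask (voxels where the mono-exponential fit was admissible),
#' the voxel spacing, the session label, and registration provenance (the
#' transform applied and the reference session, once coregistered).
#' Invalid voxels carry \code{NA} and are excluded from every downstream
#' statistic (means, thresholds, fDM denominators).
#'
#' @param data 3D numeric array, ADC in 1e-3 mm^2/s (NA where invalid).
#' @param valid 3D logical array, the fit-validity mask.
#' @param spacing length-3 voxel spacing in mm.
#' @param session session label.
#' @param provenance list recording registration history (may be empty).
#' @return object of class \code{adc_map}.
#' @export
adc_map <- function(data, valid = NULL, spacing, session = "unlabelled",
                    provenance = list()) {
  stopifnot(length(dim(data)) == 3, length(spacing) == 3, all(spacing > 0))
  if (is.null(valid)) valid <- is.finite(data) & !is.na(data)
  stopifnot(identical(dim(valid), dim(data)))
  if (any(valid & !is.finite(data)))
    stop("adc_map: non-finite values on the validity mask")
  data[!valid] <- NA_real_
  structure(list(data = data, valid = valid, spacing = as.numeric(spacing),
                 session = session, provenance = provenance),
            class = "adc_map")
}

#' @export
print.adc_map <- function(x, ...) {
  cat(sprintf(
    "adc_map '%s': %s voxels @ %s mm, %d valid, median %.3f x1e-3 mm^2/s\n",
    x$session, paste(dim(x$data), collapse = "x"),
    paste(signif(x$spacing, 3), collapse = "x"), sum(x$valid),
    stats::median(x$data[x$valid])))
  if (length(x$provenance))
    cat(sprintf("  coregistered to '%s'\n",
                x$provenance$reference %||% "?"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
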