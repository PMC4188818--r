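# NIfTI I/O.  Volumes travel as RNifti images with pixdim carrying the
# voxel spacing; ADC maps get a JSON sidecar recording units, session and
# registration provenance, so no information is lost in the round trip.

#' Write / read a volume as NIfTI
#'
#' @param vol 3D numeric or logical array.
#' @param spacing voxel spacing in mm.
#' @param path output path (\code{.nii} or \code{.nii.gz}).
#' @export
write_volume_nifti <- function(vol, spacing, path) {
  img <- RNifti::asNifti(array(as.numeric(vol), dim(vol)))
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  list(vol = array(as.numeric(img), dim(img)),
       spacing = RNifti::pixdim(img)[1:3])
}

#' Write / read an ADC map as NIfTI plus JSON sidecar
#'
#' The NIfTI carries the ADC values (NA for invalid voxels); the sidecar
#' records the unit (1e-3 mm^2/s), session label and registration
#' provenance.  The validity mask is reconstructed from finiteness on read.
#'
#' @param map an [adc_map()].
#' @param path output NIfTI path; the sidecar replaces the extension with
#'   \code{.json}.
#' @export
write_adc_nifti <- function(map, path) {
  stopifnot(inherits(map, "adc_map"))
  write_volume_nifti(map$data, map$spacing, path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(units = "1e-3 mm^2/s", session = map$session,
                            provenance = map$provenance),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_adc_nifti
#' @export
read_adc_nifti <- function(path) {
  v <- read_volume_nifti(path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  meta <- if (file.exists(sidecar))
    jsonlite::read_json(sidecar, simplifyVector = TRUE) else list()
  adc_map(v$vol, spacing = v$spacing,
          session = meta$session %||% "unlabelled",
          provenance = as.list(meta$provenance %||% list()))
}

#' Write a DWI series as one NIfTI per b-value
#'
#' Files are named \code{<prefix>_b<bvalue>.nii.gz}.
#'
#' @param series a [dwi_series()].
#' @param prefix path prefix.
#' @export
write_series_nifti <- function(series, prefix) {
  paths <- sprintf("%s_b%g.nii.gz", prefix, series$bvalues)
  for (i in seq_along(paths))
    write_volume_nifti(series$volumes[[i]], series$spacing, paths[i])
  invisible(paths)
}

#' @rdname write_series_nifti
#' @param session session label for the reconstructed series.
#' @export
read_series_nifti <- function(prefix, session = "unlabelled") {
  paths <- Sys.glob(sprintf("%s_b*.nii.gz", prefix))
  if (!length(paths)) stop("read_series_nifti: no files match ", prefix)
  b <- as.numeric(sub(".*_b([0-9.]+)\\.nii\\.gz$", "\\1", paths))
  vols <- list(); spacing <- NULL
  for (i in order(b)) {
    v <- read_volume_nifti(paths[i])
    vols[[as.character(b[i])]] <- v$vol
    spacing <- v$spacing
  }
  dwi_series(vols, spacing = spacing, session = session)
}

#' Write an fDM label volume as integer NIfTI with coding sidecar
#'
#' @param result an \code{fdm_result} (see [fdm_fractions()]) or a raw
#'   label array with the [FDM_LABELS] coding.
#' @param spacing voxel spacing in mm.
#' @param path output path.
#' @export
write_fdm_nifti <- function(result, spacing, path) {
  labels <- if (inherits(result, "fdm_result")) result$labels else result
  write_volume_nifti(labels, spacing, path)
  jsonlite::write_json(
    list(coding = as.list(FDM_LABELS),
         description = "fDM labels: 0 outside ROI, 1 unchanged (green), 2 significant ADC increase (red), 3 significant ADC decrease (blue)"),
    sub("\\.nii(\\.gz)?$", ".json", path), auto_unbox = TRUE)
  invisible(path)
}
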