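# Synthetic longitudinal DWI phantom: lung-like lesions with known ADC
# fields, known voxelwise response labels, Rician noise and known
# inter-session misalignment.  Every downstream stage of the pipeline is
# testable against the stored ground truth without any patient data.

#' Specification of a synthetic DWI patient dataset
#'
#' Defaults mirror the acquisition and lesion characteristics of a
#' chemotherapy-monitoring lung DWI study: b = 100/600/800 s/mm^2, 2 x 2 mm
#' in-plane voxels with 6 mm slices, a lesion of a few centimetres with
#' baseline ADC around 1.4e-3 mm^2/s and smooth internal texture, S0 = 1000
#' with Rician noise sigma = 55 (chosen so the per-lesion repeatability
#' limit lands in the observed 0.26-0.89e-3 mm^2/s range), and a treatment
#' change field applied from the first follow-up onwards in
#' piecewise-constant blocks large enough to survive the 6-voxel cluster
#' filter.
#'
#' @param grid_shape voxels per axis.
#' @param spacing voxel spacing in mm.
#' @param lesions list of lesions; each a list with \code{center} (mm) and
#'   \code{radii} (mm) of an ellipsoid (a lesion may be a union of several
#'   ellipsoids by listing multiple entries with the same \code{id}).
#' @param adc_mean,adc_texture_sd,texture_corr_mm baseline lesion ADC field:
#'   mean level (1e-3 mm^2/s), SD of the smooth Gaussian-random-field
#'   texture, and its correlation length in mm.
#' @param adc_background background-tissue ADC (distinct from the lesion so
#'   masking errors are detectable).
#' @param frac_increase,frac_decrease fractions of lesion voxels given a
#'   treatment-induced ADC increase / decrease (each in [0,1], sum <= 1).
#' @param change_magnitude magnitude of the induced ADC change
#'   (1e-3 mm^2/s).
#' @param s0,s0_background unattenuated signal inside the lesion and in the
#'   (low-signal) background.
#' @param noise_sigma Rician noise sigma in signal units (>= 0).
#' @param bvalues diffusion b-values in s/mm^2 (distinct, positive).
#' @param misalignment named list session -> [affine3d()] subject-motion
#'   transform; sessions not listed stay aligned.
#' @param block_shape voxel dimensions of the piecewise-constant change
#'   blocks.
#' @param isolated_voxels number of additional single-voxel (sub-cluster)
#'   changes to inject, for testing the cluster filter; 0 by default.
#' @param seed integer random seed; generation is a pure function of the
#'   spec including this seed.
#' @return validated object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(grid_shape = c(40, 40, 12),
                         spacing = c(2, 2, 6),
                         lesions = NULL,
                         adc_mean = 1.4, adc_texture_sd = 0.15,
                         texture_corr_mm = 6,
                         adc_background = 0.3,
                         frac_increase = 0.25, frac_decrease = 0.10,
                         change_magnitude = 1.2,
                         s0 = 1000, s0_background = 200,
                         noise_sigma = 55,
                         bvalues = c(100, 600, 800),
                         misalignment = list(),
                         block_shape = c(3, 3, 1),
                         isolated_voxels = 0L,
                         seed = 1L) {
  if (is.null(lesions)) {
    centre <- (grid_shape - 1) * spacing / 2
    lesions <- list(list(id = "lesion1", center = centre,
                         radii = c(16, 14, 13)))
  }
  spec <- structure(
    list(grid_shape = as.integer(grid_shape), spacing = as.numeric(spacing),
         lesions = lesions, adc_mean = adc_mean,
         adc_texture_sd = adc_texture_sd, texture_corr_mm = texture_corr_mm,
         adc_background = adc_background, frac_increase = frac_increase,
         frac_decrease = frac_decrease, change_magnitude = change_magnitude,
         s0 = s0, s0_background = s0_background, noise_sigma = noise_sigma,
         bvalues = as.numeric(bvalues), misalignment = misalignment,
         block_shape = as.integer(block_shape),
         isolated_voxels = as.integer(isolated_voxels),
         seed = as.integer(seed)),
    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (length(grid_shape) != 3 || any(grid_shape < 4))
      stop("phantom_spec: grid_shape must be 3 axes of >= 4 voxels")
    if (any(spacing <= 0)) stop("phantom_spec: spacing must be positive")
    if (frac_increase < 0 || frac_increase > 1 || frac_decrease < 0 ||
        frac_decrease > 1 || frac_increase + frac_decrease > 1)
      stop("phantom_spec: change fractions must lie in [0,1] and sum to <= 1")
    if (noise_sigma < 0) stop("phantom_spec: noise_sigma must be >= 0")
    if (length(bvalues) < 2 || any(bvalues <= 0) || anyDuplicated(bvalues))
      stop("phantom_spec: b-values must be >= 2, positive and distinct")
    extent <- (grid_shape - 1) * spacing
    for (les in lesions) {
      if (any(les$radii <= 0)) stop("phantom_spec: lesion radii must be > 0")
      if (any(les$center - les$radii < 0) ||
          any(les$center + les$radii > extent))
        stop(sprintf(
          "phantom_spec: lesion '%s' extends outside the grid (center %s mm, radii %s mm, grid extent %s mm)",
          les$id %||% "?", paste(round(les$center, 1), collapse = ","),
          paste(les$radii, collapse = ","),
          paste(round(extent, 1), collapse = ",")))
    }
  })
  invisible(spec)
}

#' Add Rician noise to a magnitude volume
#'
#' Magnitude-MR noise model: each voxel value v is replaced by
#' \code{sqrt((v + n1)^2 + n2^2)} with n1, n2 independent zero-mean
#' Gaussians of SD \code{sigma}.  With \code{sigma = 0} the volume is
#' returned untouched.
#'
#' @param volume numeric array.
#' @param sigma noise SD in signal units (>= 0).
#' @param seed optional integer; when given, the draw is reproducible and
#'   the caller's RNG state is left untouched.
#' @export
add_rician_noise <- function(volume, sigma, seed = NULL) {
  if (sigma < 0) stop("add_rician_noise: sigma must be >= 0")
  if (sigma == 0) return(volume)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  n <- length(volume)
  array(sqrt((volume + stats::rnorm(n, 0, sigma))^2 +
             stats::rnorm(n, 0, sigma)^2), dim(volume))
}

#' Apply a subject-motion misalignment to a DWI series
#'
#' Resamples every b-value volume of the session under the given affine
#' (trilinear interpolation, air value 0 outside), emulating inter-session
#' patient repositioning.  The transform maps output mm coordinates to
#' source mm coordinates, so registering the misaligned series back to the
#' original recovers the inverse transform.
#'
#' @param series a [dwi_series()].
#' @param transform an invertible [affine3d()].
#' @export
apply_misalignment <- function(series, transform) {
  stopifnot(inherits(series, "dwi_series"), inherits(transform, "affine3d"))
  affine_invert(transform)  # errors if not invertible
  out <- series
  out$volumes <- lapply(series$volumes, resample_volume,
                        transform = transform, spacing = series$spacing,
                        fill = 0)
  out$misalignment <- transform
  out
}

# smooth standardized Gaussian random field with given correlation length
gaussian_random_field <- function(dim3, spacing, corr_mm, sd) {
  white <- array(stats::rnorm(prod(dim3)), dim3)
  sm <- gaussian_smooth(white, corr_mm / spacing)
  sm <- (sm - mean(sm)) / stats::sd(sm)
  sm * sd
}

lesion_mask_from_spec <- function(spec) {
  xyz <- grid_mm_coords(spec$grid_shape, spec$spacing)
  mask <- rep(FALSE, nrow(xyz))
  for (les in spec$lesions) {
    r <- sweep(sweep(xyz, 2, les$center, `-`), 2, les$radii, `/`)
    mask <- mask | rowSums(r^2) <= 1
  }
  array(mask, spec$grid_shape)
}

# assign piecewise-constant change blocks inside the lesion; returns an
# integer label array (FDM_LABELS coding) giving the true voxelwise change
assign_change_labels <- function(spec, mask) {
  d <- spec$grid_shape
  bs <- spec$block_shape
  block_id <- array(0L, d)
  bi <- (slice.index(block_id, 1) - 1L) %/% bs[1]
  bj <- (slice.index(block_id, 2) - 1L) %/% bs[2]
  bk <- (slice.index(block_id, 3) - 1L) %/% bs[3]
  block_id <- 1L + bi + (max(bi) + 1L) * (bj + (max(bj) + 1L) * bk)
  inside <- block_id[mask]
  sizes <- table(inside)
  # only blocks comfortably above the cluster-filter minimum get a change,
  # so that true labels always survive filtering
  eligible <- as.integer(names(sizes)[sizes >= 8])
  eligible <- sample(eligible)
  n_lesion <- sum(mask)
  labels <- array(FDM_LABELS[["outside"]], d)
  labels[mask] <- FDM_LABELS[["green"]]
  assign_colour <- function(labels, target_frac, code, pool) {
    got <- 0L
    used <- integer(0)
    for (b in pool) {
      if (got / n_lesion >= target_frac) break
      sel <- mask & block_id == b & labels == FDM_LABELS[["green"]]
      labels[sel] <- code
      got <- got + sum(sel)
      used <- c(used, b)
    }
    list(labels = labels, used = used)
  }
  up <- assign_colour(labels, spec$frac_increase, FDM_LABELS[["red"]], eligible)
  pool2 <- setdiff(eligible, up$used)
  dn <- assign_colour(up$labels, spec$frac_decrease, FDM_LABELS[["blue"]], pool2)
  labels <- dn$labels
  if (spec$isolated_voxels > 0) {
    cand <- sample(which(labels == FDM_LABELS[["green"]]))
    changed <- arrayInd(which(labels == FDM_LABELS[["red"]] |
                              labels == FDM_LABELS[["blue"]]), d)
    chosen <- integer(0)
    for (v in cand) {
      if (length(chosen) >= spec$isolated_voxels) break
      co <- arrayInd(v, d)
      blockers <- rbind(changed, arrayInd(chosen, d))
      if (nrow(blockers) == 0 ||
          all(pmax(abs(blockers[, 1] - co[1]), abs(blockers[, 2] - co[2]),
                   abs(blockers[, 3] - co[3])) > 2))
        chosen <- c(chosen, v)
    }
    labels[chosen] <- FDM_LABELS[["red"]]
  }
  labels
}

#' Generate a full synthetic longitudinal patient dataset
#'
#' Produces five imaging sessions — two duplicate baselines and follow-ups
#' at weeks 1, 2 and 6 — as multi-b-value DWI series with per-session
#' lesion masks and a complete ground-truth record.  The forward model is
#' mono-exponential decay \code{S(b) = S0 exp(-b ADC)} voxelwise; the two
#' baselines share one true ADC field and differ only by noise (and any
#' configured misalignment); follow-up sessions carry the treatment-induced
#' change field.  Rician noise is applied after any misalignment, as
#' acquisition noise would be.
#'
#' @param spec a [phantom_spec()].
#' @return list with \code{series} (named list of [dwi_series()]),
#'   \code{masks} (named list of per-session lesion masks), and
#'   \code{truth}: the \code{phantom_truth} record holding per-session true
#'   ADC fields, the true voxel label volume ([FDM_LABELS] coding), true
#'   red/blue/green fractions over lesion voxels, applied transforms,
#'   lesion mask and seed.
#' @export
generate_patient_dataset <- function(spec) {
  validate_phantom_spec(spec)
  set.seed(spec$seed)
  sessions <- c("baseline1", "baseline2", "week1", "week2", "week6")
  mask <- lesion_mask_from_spec(spec)
  if (!any(mask)) stop("generate_patient_dataset: lesion mask is empty")

  texture <- gaussian_random_field(spec$grid_shape, spec$spacing,
                                   spec$texture_corr_mm, spec$adc_texture_sd)
  adc_base <- array(spec$adc_background, spec$grid_shape)
  adc_base[mask] <- pmax(spec$adc_mean + texture[mask], 0.2)
  labels <- assign_change_labels(spec, mask)
  adc_post <- adc_base
  adc_post[labels == FDM_LABELS[["red"]]] <-
    adc_post[labels == FDM_LABELS[["red"]]] + spec$change_magnitude
  adc_post[labels == FDM_LABELS[["blue"]]] <-
    pmax(adc_post[labels == FDM_LABELS[["blue"]]] - spec$change_magnitude, 0.05)

  s0_map <- array(spec$s0_background, spec$grid_shape)
  s0_map[mask] <- spec$s0

  lab_lesion <- labels[mask]
  truth <- structure(list(
    adc = list(baseline1 = adc_base, baseline2 = adc_base,
               week1 = adc_post, week2 = adc_post, week6 = adc_post),
    labels = labels,
    fractions = c(f_red = mean(lab_lesion == FDM_LABELS[["red"]]),
                  f_blue = mean(lab_lesion == FDM_LABELS[["blue"]]),
                  f_green = mean(lab_lesion == FDM_LABELS[["green"]])),
    transforms = list(), lesion_mask = mask, seed = spec$seed),
    class = "phantom_truth")

  series <- list(); masks <- list()
  for (ses in sessions) {
    adc <- truth$adc[[ses]]
    vols <- lapply(spec$bvalues, function(b) s0_map * exp(-b * adc / 1000))
    names(vols) <- spec$bvalues
    ser <- dwi_series(vols, spacing = spec$spacing, session = ses)
    tf <- spec$misalignment[[ses]]
    if (!is.null(tf)) {
      ser <- apply_misalignment(ser, tf)
      masks[[ses]] <- resample_mask(mask, tf, spec$spacing)
    } else {
      tf <- affine_identity()
      masks[[ses]] <- mask
    }
    truth$transforms[[ses]] <- tf
    if (spec$noise_sigma > 0)
      ser$volumes <- lapply(ser$volumes, add_rician_noise,
                            sigma = spec$noise_sigma)
    series[[ses]] <- ser
  }
  list(series = series, masks = masks, truth = truth)
}
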