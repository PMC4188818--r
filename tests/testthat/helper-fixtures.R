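# shared fixture builders for the test suite

# adc_map from a vector/array of values on a small grid
make_map <- function(values, dim3 = NULL, spacing = c(2, 2, 6), ...) {
  if (is.null(dim3)) dim3 <- c(length(values), 1, 1)
  adc_map(array(values, dim3), spacing = spacing, ...)
}

# smooth Gaussian-random-field map on an isotropic grid: the "smooth
# phantom" used for transform-recovery checks
smooth_map <- function(n = 32, spacing = c(2, 2, 2), seed = 1,
                       smooth_vox = 2) {
  set.seed(seed)
  vol <- gaussian_smooth(array(stats::rnorm(n^3), rep(n, 3)), smooth_vox)
  adc_map(vol - min(vol) + 0.2, spacing = spacing)
}

# isotropic lesion phantom spec used by registration-oriented tests
iso_phantom_spec <- function(n = 32, ...) {
  phantom_spec(grid_shape = rep(n, 3), spacing = c(2, 2, 2),
               lesions = list(list(id = "l", center = rep((n - 1), 3),
                                   radii = c(16, 14, 13))),
               ...)
}

# mm coordinates of lesion voxels, for displacement measurements
lesion_mm <- function(mask, spacing) {
  sweep(which(mask, arr.ind = TRUE) - 1, 2, spacing, `*`)
}

mean_displacement <- function(transform_residual, pts_mm) {
  d <- affine_apply(transform_residual, pts_mm) - pts_mm
  mean(sqrt(rowSums(d^2)))
}

# run threshold -> classify -> filter -> fractions for one timepoint
fdm_for_timepoint <- function(maps, roi, timepoint, min_cluster = 6) {
  thr <- estimate_repeatability_threshold(maps$baseline1, maps$baseline2, roi)
  lab <- classify_voxels(maps$baseline1, maps[[timepoint]], roi, thr)
  lab <- filter_clusters(lab, min_cluster = min_cluster)
  fdm_fractions(lab, roi, timepoint = timepoint, threshold = thr,
                min_cluster = min_cluster)
}
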