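# Functional diffusion maps: per-lesion significance thresholds from
# duplicate baseline ADC maps, voxelwise red/blue/green classification,
# cluster-size filtering, and fraction computation on the ROI intersection.

#' Label coding used by fDM label volumes
#'
#' Integer coding of fDM label volumes: 0 = outside the ROI, 1 = unchanged
#' (green), 2 = significant ADC increase (red), 3 = significant ADC
#' decrease (blue).  The same coding is used when labels are written to
#' NIfTI.
#' @format named integer vector.
#' @export
FDM_LABELS <- c(outside = 0L, green = 1L, red = 2L, blue = 3L)

# repeatability coefficient: the difference between two replicate
# measurements on the same subject exceeds 2.77 * s_w by chance only 5% of
# the time (Bland-Altman convention)
REPEATABILITY_COEF <- 2.77

#' Estimate the per-lesion repeatability threshold from duplicate baselines
#'
#' The fDM significance threshold is the repeatability limit of the tumor
#' tissue, estimated directly in the lesion by comparing the two
#' pretreatment ADC maps with one-way ANOVA: each valid ROI voxel is a
#' subject with two replicate measurements, the within-subject variance is
#' \eqn{s_w^2 = \mathrm{mean}_i(d_i^2 / 2)} with \eqn{d_i} the
#' between-replicate difference at voxel i, and the threshold is
#' \eqn{2.77 \, s_w} (the repeatability coefficient for two replicates).
#'
#' @param baseline1,baseline2 [adc_map()] objects; \code{baseline2} must
#'   already be coregistered to \code{baseline1}.
#' @param roi 3D logical lesion mask on the baseline1 grid.
#' @param lesion_id identifier carried into the result.
#' @return object of class \code{repeatability_threshold}: list with
#'   \code{threshold} and \code{s_w} (1e-3 mm^2/s), \code{n} (voxels used),
#'   \code{lesion_id}.
#' @examples
#' # four voxels with replicate pairs (1.0,1.2), (1.1,0.9), (1.3,1.3), (0.8,1.0)
#' a <- function(v) adc_map(array(v, c(4, 1, 1)), spacing = c(2, 2, 6))
#' thr <- estimate_repeatability_threshold(a(c(1.0, 1.1, 1.3, 0.8)),
#'                                         a(c(1.2, 0.9, 1.3, 1.0)),
#'                                         array(TRUE, c(4, 1, 1)))
#' thr$threshold  # 2.77 * sqrt(0.015) ~ 0.339
#' @export
estimate_repeatability_threshold <- function(baseline1, baseline2, roi,
                                             lesion_id = "lesion") {
  stopifnot(inherits(baseline1, "adc_map"), inherits(baseline2, "adc_map"),
            identical(dim(roi), dim(baseline1$data)),
            identical(dim(roi), dim(baseline2$data)))
  use <- roi & baseline1$valid & baseline2$valid
  n <- sum(use)
  if (n < 2)
    stop("estimate_repeatability_threshold: fewer than 2 valid ROI voxels")
  d <- baseline2$data[use] - baseline1$data[use]
  s_w <- sqrt(mean(d^2 / 2))
  structure(list(threshold = REPEATABILITY_COEF * s_w, s_w = s_w, n = n,
                 lesion_id = lesion_id),
            class = "repeatability_threshold")
}

#' @export
print.repeatability_threshold <- function(x, ...) {
  cat(sprintf(
    "repeatability threshold [%s]: %.4f x1e-3 mm^2/s (s_w = %.4f, n = %d)\n",
    x$lesion_id, x$threshold, x$s_w, x$n))
  invisible(x)
}

#' Classify lesion voxels into red / blue / green
#'
#' Voxelwise ADC change \eqn{\Delta = post - pre}; a voxel is red
#' (significant increase) when \eqn{\Delta} exceeds \code{+threshold}, blue
#' (significant decrease) when below \code{-threshold}, green otherwise.
#' The inequality is strict: a change exactly at the repeatability limit is
#' not called significant.  Voxels of the ROI where either map is invalid
#' are left at 0 (outside) and excluded downstream.
#'
#' @param pre,post [adc_map()] objects; \code{post} coregistered to
#'   \code{pre}.
#' @param intersection_roi 3D logical mask (intersection of baseline and
#'   posttreatment ROIs) on the pre grid.
#' @param threshold a \code{repeatability_threshold} or a single
#'   non-negative number (1e-3 mm^2/s).
#' @return integer label array, coded as in [FDM_LABELS].
#' @export
classify_voxels <- function(pre, post, intersection_roi, threshold) {
  stopifnot(inherits(pre, "adc_map"), inherits(post, "adc_map"),
            identical(dim(intersection_roi), dim(pre$data)),
            identical(dim(intersection_roi), dim(post$data)))
  if (inherits(threshold, "repeatability_threshold"))
    threshold <- threshold$threshold
  stopifnot(is.numeric(threshold), length(threshold) == 1, threshold >= 0)
  use <- intersection_roi & pre$valid & post$valid
  if (!any(use)) stop("classify_voxels: empty (or fully invalid) ROI")
  labels <- array(FDM_LABELS[["outside"]], dim(pre$data))
  delta <- post$data - pre$data
  labels[use] <- FDM_LABELS[["green"]]
  labels[use & delta > threshold] <- FDM_LABELS[["red"]]
  labels[use & delta < -threshold] <- FDM_LABELS[["blue"]]
  labels
}

#' Remove small significant clusters from an fDM label volume
#'
#' Isolated significant voxels are most likely false positives; connected
#' components are computed separately for red and for blue voxels, and any
#' component smaller than \code{min_cluster} voxels is relabelled green.
#' Green voxels are never changed and the ROI footprint is preserved.
#'
#' @param labels integer label array coded as in [FDM_LABELS].
#' @param min_cluster minimum component size in voxels (default 6, the
#'   conventional fDM cluster-size threshold).
#' @param connectivity neighbourhood for components (default 26; masks span
#'   thick slices, so in-plane diagonal contact counts).
#' @return relabelled integer array.
#' @export
filter_clusters <- function(labels, min_cluster = 6, connectivity = 26) {
  stopifnot(min_cluster >= 1)
  if (min_cluster == 1) return(labels)
  for (colr in c("red", "blue")) {
    code <- FDM_LABELS[[colr]]
    comp <- label_components(labels == code, connectivity = connectivity)
    if (!max(comp)) next
    sizes <- tabulate(comp[comp > 0L])
    small <- which(sizes < min_cluster)
    if (length(small))
      labels[comp %in% small] <- FDM_LABELS[["green"]]
  }
  labels
}

#' Red / blue / green fractions over the intersection ROI
#'
#' @param labels integer label array coded as in [FDM_LABELS].
#' @param intersection_roi 3D logical mask; only labelled (non-outside)
#'   voxels inside it enter the denominator.
#' @param lesion_id,timepoint,threshold,min_cluster metadata carried into
#'   the result.
#' @return object of class \code{fdm_result}: list with \code{f_red},
#'   \code{f_blue}, \code{f_green} (fractions summing to 1), \code{n}
#'   (denominator voxels), \code{labels}, and the metadata.
#' @export
fdm_fractions <- function(labels, intersection_roi, lesion_id = "lesion",
                          timepoint = NA_character_, threshold = NA_real_,
                          min_cluster = NA_integer_) {
  stopifnot(identical(dim(labels), dim(intersection_roi)))
  lab <- labels[intersection_roi]
  lab <- lab[lab != FDM_LABELS[["outside"]]]
  n <- length(lab)
  if (!n) stop("fdm_fractions: empty intersection ROI")
  if (inherits(threshold, "repeatability_threshold"))
    threshold <- threshold$threshold
  structure(list(f_red = sum(lab == FDM_LABELS[["red"]]) / n,
                 f_blue = sum(lab == FDM_LABELS[["blue"]]) / n,
                 f_green = sum(lab == FDM_LABELS[["green"]]) / n,
                 n = n, labels = labels, lesion_id = lesion_id,
                 timepoint = timepoint, threshold = threshold,
                 min_cluster = min_cluster),
            class = "fdm_result")
}

#' @export
print.fdm_result <- function(x, ...) {
  cat(sprintf(
    "fDM [%s, %s]: red %.1f%% / blue %.1f%% / green %.1f%% over %d voxels\n",
    x$lesion_id, x$timepoint, 100 * x$f_red, 100 * x$f_blue,
    100 * x$f_green, x$n))
  invisible(x)
}
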