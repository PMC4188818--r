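# Lesion- and cohort-level response statistics: ROI means, RECIST
# classification, exact Wilcoxon signed-rank, group summaries,
# repeated-measures ANOVA with covariate / between-subjects factor,
# sphericity diagnostics, lesion-size-weighted patient means, and
# correlations with the progression-free interval.

#' Mean ADC of a lesion ROI
#'
#' Arithmetic mean over ROI voxels that are valid in the map's fit-validity
#' mask; invalid voxels never enter the mean.
#'
#' @param adc an [adc_map()].
#' @param roi 3D logical lesion mask.
#' @return mean ADC in 1e-3 mm^2/s.
#' @export
lesion_mean_adc <- function(adc, roi) {
  stopifnot(inherits(adc, "adc_map"), identical(dim(roi), dim(adc$data)))
  use <- roi & adc$valid
  if (!any(use)) stop("lesion_mean_adc: no valid ROI voxel")
  mean(adc$data[use])
}

#' RECIST classification from CT diameters
#'
#' Percent change = 100 (after - before) / before; a lesion is a partial
#' response when the diameter decrease exceeds 30%, otherwise stable
#' disease.  A decrease of exactly 30% is classified as stable disease (the
#' criterion requires the decrease to exceed 30%).
#'
#' @param before_cm,after_cm longest axial diameters in cm (> 0); vectors
#'   are accepted.
#' @return data.frame with \code{percent_change} and \code{recist_class}
#'   (\code{"partial_response"} / \code{"stable_disease"}).
#' @export
recist_classify <- function(before_cm, after_cm) {
  if (any(before_cm <= 0) || any(after_cm <= 0))
    stop("recist_classify: diameters must be positive")
  pct <- 100 * (after_cm - before_cm) / before_cm
  data.frame(percent_change = pct,
             recist_class = ifelse(pct < -30, "partial_response",
                                   "stable_disease"))
}

#' Exact two-sided Wilcoxon signed-rank test
#'
#' Paired test on \code{before} vs \code{after}.  Zero differences are
#' dropped before ranking (Wilcoxon's original treatment) and tied absolute
#' differences receive mid-ranks.  For n <= \code{exact_max} the two-sided
#' p-value is exact, obtained from the full distribution of the positive
#' rank sum over all 2^n sign assignments (computed by generating-function
#' convolution, so mid-ranks are handled exactly); above that the normal
#' approximation with tie-corrected variance and continuity correction is
#' used.
#'
#' @param before,after paired numeric vectors.
#' @param exact_max largest n for which the exact distribution is
#'   enumerated (default 20).
#' @return list with \code{statistic} (V, the positive rank sum),
#'   \code{p_value} (two-sided), \code{n} (non-zero differences) and
#'   \code{method}.
#' @export
wilcoxon_signed_rank_exact <- function(before, after, exact_max = 20) {
  stopifnot(length(before) == length(after))
  d <- after - before
  d <- d[d != 0]
  n <- length(d)
  if (!n) stop("wilcoxon_signed_rank_exact: all differences are zero")
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= exact_max) {
    # distribution of sum of a random subset of the ranks; double the ranks
    # so mid-ranks (halves) become integers
    r2 <- round(2 * r)
    total <- sum(r2)
    pmf <- c(1, rep(0, total))  # pmf[k+1] = #assignments with doubled sum k
    for (rr in r2) {
      shifted <- c(rep(0, rr), pmf[seq_len(total + 1 - rr)])
      pmf <- pmf + shifted
    }
    pmf <- pmf / 2^n
    v2 <- round(2 * v)
    p_lo <- sum(pmf[seq_len(v2 + 1)])          # P(V <= v)
    p_hi <- sum(pmf[seq(v2 + 1, total + 1)])   # P(V >= v)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact (sign-assignment enumeration)"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  }
  list(statistic = v, p_value = p, n = n, method = method)
}

#' Per-class mean relative ADC change at each follow-up week
#'
#' Joins a lesion ADC table with a lesion CT table (on patient and lesion
#' ids), computes each lesion's relative ADC change
#' (100 x change / baseline) at weeks 1, 2 and 6, classifies lesions by
#' RECIST from the CT diameters, and averages the relative changes within
#' the partial-response and stable-disease classes.
#'
#' @param adc_records data.frame with columns \code{patient_id},
#'   \code{lesion_id}, \code{adc_baseline}, \code{adc_change_w1},
#'   \code{adc_change_w2}, \code{adc_change_w6}.
#' @param ct_records data.frame with columns \code{patient_id},
#'   \code{lesion_id}, \code{diameter_pre_cm}, \code{diameter_post_cm}.
#' @return list with \code{lesions} (per-lesion table incl. relative
#'   changes and class) and \code{group_means} (data.frame: class x week
#'   mean relative change, %).
#' @export
group_summary <- function(adc_records, ct_records) {
  key_a <- paste(adc_records$patient_id, adc_records$lesion_id)
  key_c <- paste(ct_records$patient_id, ct_records$lesion_id)
  if (!all(key_a %in% key_c))
    stop("group_summary: ADC record(s) without matching CT record: ",
         paste(setdiff(key_a, key_c), collapse = "; "))
  m <- match(key_a, key_c)
  cls <- recist_classify(ct_records$diameter_pre_cm[m],
                         ct_records$diameter_post_cm[m])
  lesions <- data.frame(
    patient_id = adc_records$patient_id, lesion_id = adc_records$lesion_id,
    recist_class = cls$recist_class, ct_percent_change = cls$percent_change,
    rel_w1 = 100 * adc_records$adc_change_w1 / adc_records$adc_baseline,
    rel_w2 = 100 * adc_records$adc_change_w2 / adc_records$adc_baseline,
    rel_w6 = 100 * adc_records$adc_change_w6 / adc_records$adc_baseline)
  gm <- do.call(rbind, lapply(split(lesions, lesions$recist_class), function(g)
    data.frame(recist_class = g$recist_class[1], n = nrow(g),
               week1 = mean(g$rel_w1), week2 = mean(g$rel_w2),
               week6 = mean(g$rel_w6))))
  rownames(gm) <- NULL
  list(lesions = lesions, group_means = gm)
}

#' Repeated-measures ANOVA with a size covariate or between-subjects factor
#'
#' Classical univariate repeated-measures decomposition for one
#' within-subject factor (time, 3 levels) and one between-subjects term:
#' either a continuous covariate (centred before fitting) or a two-level
#' group factor.  Fitted with \code{stats::aov} using an
#' \code{Error(unit/time)} stratum structure; the between term is tested
#' against the between-unit stratum and time terms against the within
#' stratum.  When Mauchly's test rejects sphericity (p < 0.05) a
#' Greenhouse-Geisser-corrected p-value is reported alongside the
#' uncorrected one for the within-subject terms.
#'
#' @param data data.frame in long format with columns \code{unit} (lesion
#'   id), \code{time} (factor or coercible, 3 levels), \code{value}, and
#'   either \code{group} (factor) or \code{covariate} (numeric, constant
#'   within unit).
#' @param between \code{"group"} or \code{"covariate"}.
#' @return data.frame ANOVA table: term, df, sum_sq, F, p, and (where
#'   applicable) \code{p_gg}; attribute \code{"mauchly"} holds the
#'   sphericity test.
#' @export
rm_anova <- function(data, between = c("group", "covariate")) {
  between <- match.arg(between)
  data$unit <- factor(data$unit)
  data$time <- factor(data$time)
  if (nlevels(data$time) < 2) stop("rm_anova: need >= 2 timepoints")
  # listwise deletion of units with missing cells
  complete <- tapply(is.finite(data$value), data$unit, all)
  keep_units <- names(complete)[complete &
    tapply(data$value, data$unit, length)[names(complete)] == nlevels(data$time)]
  data <- droplevels(data[data$unit %in% keep_units, ])
  if (nlevels(data$unit) < 3) stop("rm_anova: fewer than 3 complete units")

  if (between == "group") {
    data$group <- factor(data$group)
    if (nlevels(data$group) < 2 || any(table(unique(data[c("unit", "group")])$group) < 2))
      stop("rm_anova: need >= 2 units per group")
    fml <- value ~ group * time + Error(unit / time)
    bterm <- "group"
  } else {
    data$covariate <- data$covariate - mean(tapply(data$covariate, data$unit, mean))
    fml <- value ~ covariate * time + Error(unit / time)
    bterm <- "covariate"
  }
  fit <- stats::aov(fml, data = data)
  smy <- summary(fit)
  tab <- do.call(rbind, lapply(smy, function(s) {
    s <- as.data.frame(s[[1]])
    s$term <- trimws(rownames(s))
    s
  }))
  rownames(tab) <- NULL
  names(tab) <- c("df", "sum_sq", "mean_sq", "F", "p", "term")[seq_len(ncol(tab))]
  tab <- tab[, c("term", "df", "sum_sq", "mean_sq", "F", "p")]

  # sphericity and Greenhouse-Geisser correction from the wide value matrix
  wide <- tapply(data$value, list(data$unit, data$time), mean)
  mau <- tryCatch(mauchly_sphericity(wide), error = function(e) NULL)
  if (!is.null(mau)) {
    tab$p_gg <- NA_real_
    within <- tab$term %in% c("time", paste0(bterm, ":time"))
    err_df <- tab$df[tab$term == "Residuals" & seq_len(nrow(tab)) > 2][1]
    eps <- mau$gg_epsilon
    if (isTRUE(mau$p_value < 0.05)) {
      err_row <- max(which(tab$term == "Residuals"))
      for (i in which(within)) {
        tab$p_gg[i] <- stats::pf(tab$F[i], eps * tab$df[i],
                                 eps * tab$df[err_row], lower.tail = FALSE)
      }
    }
    attr(tab, "mauchly") <- mau
  }
  tab
}

#' Mauchly's test of sphericity
#'
#' Tests whether the covariance of the within-subject differences is
#' spherical: Mauchly's W from the sample covariance of orthonormal
#' contrasts of the repeated measures, with the standard chi-square
#' approximation (delegated to \code{stats::mauchly.test} on an intercept
#' multivariate fit).  The Greenhouse-Geisser epsilon from the same
#' contrast covariance is returned for use in corrected F tests.
#'
#' @param wide n x k numeric matrix: units in rows, timepoints in columns
#'   (k >= 3, n > k).
#' @return list with \code{W}, \code{p_value}, \code{gg_epsilon}.
#' @export
mauchly_sphericity <- function(wide) {
  wide <- as.matrix(wide)
  k <- ncol(wide); n <- nrow(wide)
  if (k < 3) stop("mauchly_sphericity: need >= 3 timepoints")
  if (n <= k) stop("mauchly_sphericity: need more units than timepoints")
  ctr <- stats::contr.helmert(k)
  ctr <- sweep(ctr, 2, sqrt(colSums(ctr^2)), `/`)  # orthonormal contrasts
  S <- stats::cov(wide %*% ctr)
  scale <- (sum(diag(S)) / (k - 1))^(k - 1)
  if (!all(is.finite(S)) || scale <= 0 || abs(det(S)) < 1e-12 * scale)
    stop("mauchly_sphericity: contrast covariance is singular")
  mt <- stats::mauchly.test(stats::lm(wide ~ 1), X = ~1)
  eps <- (sum(diag(S)))^2 / ((k - 1) * sum(S^2))
  list(W = unname(mt$statistic), p_value = mt$p.value, gg_epsilon = eps)
}

#' Lesion-size-weighted per-patient mean
#'
#' Patients with several lesions contribute a single value per diffusion
#' parameter: the weighted mean of the per-lesion values with weights equal
#' to lesion size (baseline CT diameter by default; pass squared diameters
#' for area-proportional weighting).
#'
#' @param lesion_values numeric per-lesion values.
#' @param lesion_sizes positive weights of equal length.
#' @export
patient_weighted_mean <- function(lesion_values, lesion_sizes) {
  stopifnot(length(lesion_values) == length(lesion_sizes))
  if (any(lesion_sizes <= 0))
    stop("patient_weighted_mean: weights must be positive")
  sum(lesion_values * lesion_sizes) / sum(lesion_sizes)
}

#' Correlate week-1 diffusion parameters with progression-free interval
#'
#' Pearson product-moment correlation (with the usual two-sided t-test)
#' between each per-patient parameter and the progression-free interval,
#' after dropping excluded patients (e.g. death unrelated to progression)
#' and patients with missing PFS.
#'
#' @param params data.frame of per-patient parameters; one row per patient.
#' @param pfs_months numeric progression-free interval per patient.
#' @param exclude logical vector (or patient indices) to drop.
#' @return data.frame with \code{parameter}, \code{r}, \code{p}, \code{n}.
#' @export
pfs_correlation <- function(params, pfs_months, exclude = NULL) {
  stopifnot(nrow(params) == length(pfs_months))
  drop <- rep(FALSE, length(pfs_months))
  if (!is.null(exclude)) {
    if (is.logical(exclude)) drop <- drop | exclude else drop[exclude] <- TRUE
  }
  keep <- !drop & is.finite(pfs_months)
  if (sum(keep) < 3)
    stop("pfs_correlation: fewer than 3 patients after exclusions")
  out <- lapply(names(params), function(nm) {
    ct <- stats::cor.test(params[[nm]][keep], pfs_months[keep],
                          method = "pearson")
    data.frame(parameter = nm, r = unname(ct$estimate), p = ct$p.value,
               n = sum(keep))
  })
  do.call(rbind, out)
}

#' Load the bundled lesion CT / ADC tables
#'
#' The per-lesion CT-diameter table (13 lesions of 9 patients: therapy,
#' progression-free interval, diameters before treatment and after two
#' chemotherapy cycles) and the matching per-lesion ADC table (baseline
#' mean ADC and mean ADC change at weeks 1, 2, 6, in 1e-3 mm^2/s) ship with
#' the package as CSV fixtures.
#'
#' @param which \code{"ct"} or \code{"adc"}.
#' @return data.frame.
#' @export
load_lesion_table <- function(which = c("ct", "adc")) {
  which <- match.arg(which)
  f <- system.file("extdata",
                   if (which == "ct") "table1_lesion_ct.csv"
                   else "table3_lesion_adc.csv",
                   package = "fdmap", mustWork = TRUE)
  utils::read.csv(f, stringsAsFactors = FALSE)
}
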