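# Pipeline orchestration: configuration validation and the end-to-end run
# (simulate -> eddy-correct -> ADC fit -> coregistration -> thresholds ->
# fDMs -> statistics), with a machine-readable run report.

fdmap_default_config <- function() {
  list(
    mode = "phantom",            # "phantom" (imaging pipeline) or "stats"
    bvalues = c(100, 600, 800),  # s/mm^2
    min_signal = 1,              # signal floor for the log-linear ADC fit
    eddy_correct = FALSE,        # per-session b-value alignment
    registration_levels = 3,
    registration_tol = 1e-4,
    register_sessions = TRUE,    # coregister all maps to baseline1
    threshold_scope = "per_lesion",  # or "per_patient" (pooled baselines)
    cluster_connectivity = 26,
    min_cluster = 6,
    recist_boundary = 30,        # % decrease; equality -> stable disease
    weighting = "diameter",      # patient weights: "diameter" or "area"
    seed = 1,
    phantom = list(),            # phantom_spec() overrides
    ct_table = NULL,             # paths; NULL -> bundled fixtures
    adc_table = NULL,
    output_dir = NULL            # when set, volumes/tables/report written
  )
}

#' Validate a pipeline configuration
#'
#' Fills defaults, records them, and collects \emph{all} problems rather
#' than failing at the first.  Unknown keys produce warnings, not errors;
#' the configuration is never partially applied.
#'
#' @param config named list of settings (may be empty).
#' @return validated config (class \code{fdmap_config}) with an
#'   \code{injected_defaults} attribute, or an error listing every
#'   violation.
#' @export
validate_config <- function(config = list()) {
  defaults <- fdmap_default_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    warning("validate_config: ignoring unknown key(s): ",
            paste(unknown, collapse = ", "))
  config <- config[intersect(names(config), names(defaults))]
  injected <- setdiff(names(defaults), names(config))
  full <- utils::modifyList(defaults, config)

  errors <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) errors <<- c(errors, msg)
  chk(full$mode %in% c("phantom", "stats"),
      "mode: must be 'phantom' or 'stats'")
  chk(length(full$bvalues) >= 2 && all(full$bvalues > 0) &&
        !anyDuplicated(full$bvalues),
      "bvalues: need >= 2 distinct positive values")
  chk(is.numeric(full$min_signal) && full$min_signal > 0,
      "min_signal: must be > 0")
  chk(full$registration_levels >= 1, "registration_levels: must be >= 1")
  chk(full$threshold_scope %in% c("per_lesion", "per_patient"),
      "threshold_scope: must be 'per_lesion' or 'per_patient'")
  chk(full$cluster_connectivity %in% c(6, 18, 26),
      "cluster_connectivity: must be 6, 18 or 26")
  chk(is.numeric(full$min_cluster) && full$min_cluster >= 1,
      "min_cluster: must be >= 1")
  chk(is.numeric(full$recist_boundary) && full$recist_boundary > 0 &&
        full$recist_boundary < 100,
      "recist_boundary: must be a percentage in (0, 100)")
  chk(full$weighting %in% c("diameter", "area"),
      "weighting: must be 'diameter' or 'area'")
  for (f in c("ct_table", "adc_table"))
    if (!is.null(full[[f]]))
      chk(file.exists(full[[f]]), sprintf("%s: file not found: %s", f, full[[f]]))
  if (length(errors))
    stop("invalid configuration:\n  - ", paste(errors, collapse = "\n  - "))
  attr(full, "injected_defaults") <- injected
  class(full) <- "fdmap_config"
  full
}

#' Run the full fDM pipeline
#'
#' In \code{"phantom"} mode: generates a synthetic longitudinal patient
#' dataset, optionally corrects eddy-current warping within each session,
#' fits ADC maps, coregisters the second baseline and all posttreatment
#' maps to the first pretreatment map (with Pearson-correlation QC),
#' estimates the per-lesion repeatability threshold from the duplicate
#' baselines, computes cluster-filtered fDMs for each posttreatment
#' timepoint on the ROI intersection, and summarizes lesion statistics.
#' In \code{"stats"} mode it runs the cohort statistics alone on the
#' CT-diameter and lesion-ADC tables (bundled fixtures by default).
#'
#' The run is deterministic given config + seed.  If \code{output_dir} is
#' set, volumes (NIfTI), fraction tables (CSV) and the report (JSON) are
#' written there.
#'
#' @param config a list of settings (validated via [validate_config()]).
#' @return a \code{fdmap_report}: nested list with per-stage settings and
#'   results (QC correlations, thresholds, fraction tables, statistics).
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "fdmap_config")) config else validate_config(config)
  report <- list(config = unclass(cfg),
                 injected_defaults = attr(cfg, "injected_defaults"),
                 warnings = character(0))

  report$statistics <- run_stats_stage(cfg)
  if (cfg$mode == "phantom") {
    img <- run_imaging_stages(cfg)
    report <- utils::modifyList(report, img)
  }
  class(report) <- "fdmap_report"
  if (!is.null(cfg$output_dir)) write_report(report, cfg$output_dir)
  report
}

run_stats_stage <- function(cfg) {
  ct <- if (is.null(cfg$ct_table)) load_lesion_table("ct")
        else utils::read.csv(cfg$ct_table)
  adc <- if (is.null(cfg$adc_table)) load_lesion_table("adc")
         else utils::read.csv(cfg$adc_table)

  wil <- wilcoxon_signed_rank_exact(ct$diameter_pre_cm, ct$diameter_post_cm)
  gs <- group_summary(adc, ct)
  counts <- table(gs$lesions$recist_class)

  long <- data.frame(
    unit = rep(paste(adc$patient_id, adc$lesion_id, sep = "."), 3),
    time = rep(c("week1", "week2", "week6"), each = nrow(adc)),
    value = c(gs$lesions$rel_w1, gs$lesions$rel_w2, gs$lesions$rel_w6),
    group = rep(gs$lesions$recist_class, 3),
    covariate = rep(gs$lesions$ct_percent_change, 3))
  anova_group <- rm_anova(long, between = "group")
  anova_cov <- rm_anova(long, between = "covariate")

  w <- if (cfg$weighting == "area") ct$diameter_pre_cm^2 else ct$diameter_pre_cm
  per_patient <- do.call(rbind, lapply(split(seq_len(nrow(ct)), ct$patient_id),
    function(i) data.frame(
      patient_id = ct$patient_id[i[1]],
      pfs_months = ct$pfs_months[i[1]],
      rel_adc_w1 = patient_weighted_mean(gs$lesions$rel_w1[i], w[i]))))
  pfs <- pfs_correlation(per_patient["rel_adc_w1"], per_patient$pfs_months)

  list(diameter_mean_pre = mean(ct$diameter_pre_cm),
       diameter_mean_post = mean(ct$diameter_post_cm),
       wilcoxon = wil,
       recist_counts = as.list(counts),
       group_means = gs$group_means,
       lesions = gs$lesions,
       rm_anova_group = anova_group,
       rm_anova_covariate = anova_cov,
       per_patient = per_patient,
       pfs_correlation = pfs)
}

run_imaging_stages <- function(cfg) {
  spec <- do.call(phantom_spec, utils::modifyList(
    list(bvalues = cfg$bvalues, seed = cfg$seed), cfg$phantom))
  ds <- generate_patient_dataset(spec)
  out <- list(phantom_truth_fractions = as.list(ds$truth$fractions))
  warns <- character(0)

  series <- ds$series
  if (isTRUE(cfg$eddy_correct)) {
    series <- lapply(series, correct_eddy_warp, levels = cfg$registration_levels)
    warns <- c(warns, unlist(lapply(series, `[[`, "warnings")))
  }
  maps <- lapply(series, fit_adc_map, min_signal = cfg$min_signal)

  ref <- maps$baseline1
  qc <- list()
  if (isTRUE(cfg$register_sessions)) {
    for (ses in setdiff(names(maps), "baseline1")) {
      reg <- register_affine(maps[[ses]], ref,
                             levels = cfg$registration_levels,
                             tol = cfg$registration_tol)
      qc[[ses]] <- unclass(reg$qc)[c("before", "after", "n_voxels", "fallback")]
      maps[[ses]] <- resample_map(maps[[ses]], reg$transform, ref)
      ds$masks[[ses]] <- resample_mask(ds$masks[[ses]], reg$transform,
                                       spec$spacing)
      if (isTRUE(reg$qc$fallback))
        warns <- c(warns, sprintf("registration of %s fell back to identity", ses))
    }
  }
  out$registration_qc <- qc

  roi_base <- ds$masks$baseline1 & ds$masks$baseline2
  thr <- estimate_repeatability_threshold(maps$baseline1, maps$baseline2,
                                          roi_base, lesion_id = "lesion1")
  out$threshold <- unclass(thr)

  fractions <- list()
  for (tp in c("week1", "week2", "week6")) {
    roi <- ds$masks$baseline1 & ds$masks[[tp]]
    labels <- classify_voxels(maps$baseline1, maps[[tp]], roi, thr)
    labels <- filter_clusters(labels, min_cluster = cfg$min_cluster,
                              connectivity = cfg$cluster_connectivity)
    res <- fdm_fractions(labels, roi, lesion_id = "lesion1", timepoint = tp,
                         threshold = thr, min_cluster = cfg$min_cluster)
    fractions[[tp]] <- res
  }
  out$fdm <- lapply(fractions, function(r)
    r[c("f_red", "f_blue", "f_green", "n", "timepoint")])
  out$fdm_results <- fractions
  out$lesion_mean_adc <- lapply(maps, function(m)
    tryCatch(lesion_mean_adc(m, ds$masks$baseline1), error = function(e) NA_real_))
  out$warnings <- warns
  out
}

write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  frac_tab <- NULL
  if (!is.null(report$fdm_results)) {
    frac_tab <- do.call(rbind, lapply(report$fdm_results, function(r)
      data.frame(lesion_id = r$lesion_id, timepoint = r$timepoint,
                 f_red = r$f_red, f_blue = r$f_blue, f_green = r$f_green,
                 threshold = r$threshold, n_voxels = r$n)))
    utils::write.csv(frac_tab, file.path(dir, "fdm_fractions.csv"),
                     row.names = FALSE)
  }
  slim <- report
  slim$fdm_results <- NULL
  slim$statistics$lesions <- NULL
  jsonlite::write_json(slim, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       na = "null")
  invisible(dir)
}

#' @export
print.fdmap_report <- function(x, ...) {
  s <- x$statistics
  cat("fDM pipeline report\n")
  cat(sprintf("  CT diameters: mean %.1f -> %.1f cm; Wilcoxon p = %.3g\n",
              s$diameter_mean_pre, s$diameter_mean_post, s$wilcoxon$p_value))
  cat(sprintf("  RECIST: %s\n",
              paste(names(s$recist_counts), unlist(s$recist_counts),
                    collapse = ", ", sep = " = ")))
  if (!is.null(x$threshold))
    cat(sprintf("  repeatability threshold: %.3f x1e-3 mm^2/s (n = %d)\n",
                x$threshold$threshold, x$threshold$n))
  if (length(x$fdm))
    for (tp in names(x$fdm))
      cat(sprintf("  fDM %s: red %.1f%% blue %.1f%% green %.1f%%\n", tp,
                  100 * x$fdm[[tp]]$f_red, 100 * x$fdm[[tp]]$f_blue,
                  100 * x$fdm[[tp]]$f_green))
  invisible(x)
}
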