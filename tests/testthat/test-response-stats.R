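# lesion/cohort statistics: ROI means, RECIST, Wilcoxon, group summaries,
# repeated-measures ANOVA, sphericity, weighted means, PFS correlations

test_that("lesion mean ADC averages valid ROI voxels only", {
  expect_equal(lesion_mean_adc(make_map(rep(0.7, 4)), array(TRUE, c(4, 1, 1))),
               0.7)
  expect_equal(lesion_mean_adc(make_map(c(1.0, 1.2, 1.4), c(3, 1, 1)),
                               array(TRUE, c(3, 1, 1))), 1.2)
  m <- make_map(c(1.0, 1.2, NA, 9))
  roi <- array(c(TRUE, TRUE, TRUE, FALSE), c(4, 1, 1))
  expect_equal(lesion_mean_adc(m, roi), 1.1)  # NA voxel excluded
  expect_error(lesion_mean_adc(m, array(FALSE, c(4, 1, 1))), "valid")
})

test_that("lesion mean over the phantom matches the true field", {
  ds <- generate_patient_dataset(phantom_spec(noise_sigma = 15, seed = 3))
  fit <- fit_adc_map(ds$series$baseline1)
  truth <- mean(ds$truth$adc$baseline1[ds$truth$lesion_mask])
  expect_equal(lesion_mean_adc(fit, ds$truth$lesion_mask), truth,
               tolerance = 0.03)
})

test_that("RECIST classification reproduces the worked diameters", {
  r1 <- recist_classify(4.4, 1.8)
  expect_equal(r1$percent_change, -59.09, tolerance = 1e-3)
  expect_identical(r1$recist_class, "partial_response")
  r2 <- recist_classify(5.8, 5.0)
  expect_equal(r2$percent_change, -13.79, tolerance = 1e-3)
  expect_identical(r2$recist_class, "stable_disease")
  expect_identical(recist_classify(3, 3)$recist_class, "stable_disease")
  # exactly -30% is not "exceeding 30%": stable disease
  expect_identical(recist_classify(10, 7)$recist_class, "stable_disease")
  expect_error(recist_classify(0, 1), "positive")
})

test_that("the bundled CT table splits 4 partial response / 9 stable disease", {
  ct <- load_lesion_table("ct")
  expect_equal(nrow(ct), 13)
  cls <- recist_classify(ct$diameter_pre_cm, ct$diameter_post_cm)
  expect_equal(sum(cls$recist_class == "partial_response"), 4)
  expect_equal(sum(cls$recist_class == "stable_disease"), 9)
})

test_that("exact Wilcoxon p matches enumeration and published small-sample values", {
  # all 13 diameter pairs decreased: the most extreme assignment out of 2^13
  ct <- load_lesion_table("ct")
  w <- wilcoxon_signed_rank_exact(ct$diameter_pre_cm, ct$diameter_post_cm)
  expect_identical(w$method, "exact (sign-assignment enumeration)")
  expect_equal(w$p_value, 2 / 2^13, tolerance = 1e-12)
  expect_lte(w$p_value, 0.001)
  # n = 5, single discordant smallest-rank pair: classical table value 0.125
  before <- c(10, 10, 10, 10, 10)
  after <- before + c(-1, 2, 3, 4, 5)
  w5 <- wilcoxon_signed_rank_exact(before, after)
  expect_equal(w5$p_value, 0.125, tolerance = 1e-12)
  # degenerate inputs
  expect_error(wilcoxon_signed_rank_exact(1:4, 1:4), "zero")
  one <- wilcoxon_signed_rank_exact(c(1, 2, 3), c(1, 2, 4))
  expect_equal(one$n, 1L)
  expect_equal(one$p_value, 1)  # single pair cannot reach significance
})

test_that("exact enumeration agrees with wilcox.test and its normal approximation", {
  set.seed(21)
  x <- rnorm(13); y <- x + rnorm(13, 0.4)
  ours <- wilcoxon_signed_rank_exact(x, y)
  ref <- stats::wilcox.test(y, x, paired = TRUE, exact = TRUE)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  approx <- wilcoxon_signed_rank_exact(x, y, exact_max = 0)
  expect_equal(approx$p_value, ours$p_value, tolerance = 0.1)  # relative
})

test_that("group summary reproduces the per-class mean relative ADC changes", {
  gs <- group_summary(load_lesion_table("adc"), load_lesion_table("ct"))
  gm <- gs$group_means
  pr <- gm[gm$recist_class == "partial_response", ]
  sd_ <- gm[gm$recist_class == "stable_disease", ]
  expect_equal(round(c(pr$week1, pr$week2, pr$week6), 1), c(16.2, 9.4, 19.0))
  expect_equal(round(c(sd_$week1, sd_$week2, sd_$week6), 1), c(-7.4, -8.9, -3.5))
  expect_equal(pr$n, 4); expect_equal(sd_$n, 9)
})

test_that("group summary is permutation- and scale-invariant", {
  adc <- load_lesion_table("adc"); ct <- load_lesion_table("ct")
  gm1 <- group_summary(adc, ct)$group_means
  perm <- sample(nrow(adc))
  gm2 <- group_summary(adc[perm, ], ct)$group_means
  expect_equal(gm1, gm2)
  adc_scaled <- adc
  adc_scaled[, 3:6] <- adc_scaled[, 3:6] * 3.14
  expect_equal(group_summary(adc_scaled, ct)$group_means, gm1)
  # unmatched lesion is a descriptive failure
  bad <- adc; bad$lesion_id[1] <- 99
  expect_error(group_summary(bad, ct), "matching CT record")
  # single lesion per class reduces to that lesion's changes
  solo <- group_summary(adc[c(1, 2), ], ct)
  expect_equal(solo$group_means$week1,
               100 * adc$adc_change_w1[1:2] / adc$adc_baseline[1:2],
               tolerance = 1e-12)
})

test_that("rm_anova: identical group means give F ~ 0 for the group term", {
  long <- data.frame(
    unit = rep(c("a1", "a2", "b1", "b2"), each = 3),
    time = rep(c("t1", "t2", "t3"), 4),
    value = c(0, 1, 2, 4, 5, 6, 1, 2, 3, 3, 4, 5),
    group = rep(c("A", "A", "B", "B"), each = 3))
  tab <- rm_anova(long, "group")
  g <- tab[tab$term == "group", ]
  expect_lt(g$F, 1e-10)
  expect_gt(g$p, 0.999)
})

test_that("rm_anova matches a hand-computed sums-of-squares oracle", {
  set.seed(30)
  n_per <- 4; k <- 3
  grp <- rep(c("A", "B"), each = n_per)
  eff <- ifelse(grp == "A", 1.5, 0)
  subj <- rnorm(2 * n_per, 0, 1)
  y <- matrix(NA_real_, 2 * n_per, k)
  for (t in 1:k) y[, t] <- 10 + eff + subj + 0.3 * t + rnorm(2 * n_per, 0, 0.5)
  long <- data.frame(unit = rep(sprintf("u%02d", 1:(2 * n_per)), k),
                     time = rep(paste0("t", 1:k), each = 2 * n_per),
                     value = as.vector(y), group = rep(grp, k))
  tab <- rm_anova(long, "group")
  # closed-form balanced-design sums of squares
  grand <- mean(y)
  m_subj <- rowMeans(y); m_time <- colMeans(y)
  m_grp <- tapply(m_subj, grp, mean)
  m_gt <- rbind(colMeans(y[grp == "A", ]), colMeans(y[grp == "B", ]))
  ss_group <- k * n_per * sum((m_grp - grand)^2)
  ss_subj <- k * sum((m_subj - m_grp[grp])^2)
  ss_time <- 2 * n_per * sum((m_time - grand)^2)
  ss_gt <- n_per * sum(sweep(sweep(m_gt, 2, m_time), 1, m_grp - grand)^2)
  ss_tot <- sum((y - grand)^2)
  ss_err <- ss_tot - ss_group - ss_subj - ss_time - ss_gt
  f_group <- (ss_group / 1) / (ss_subj / (2 * n_per - 2))
  f_time <- (ss_time / (k - 1)) / (ss_err / ((2 * n_per - 2) * (k - 1)))
  expect_equal(tab$sum_sq[tab$term == "group"], ss_group, tolerance = 1e-8)
  expect_equal(tab$sum_sq[tab$term == "time"], ss_time, tolerance = 1e-8)
  expect_equal(tab$sum_sq[tab$term == "group:time"], ss_gt, tolerance = 1e-8)
  expect_equal(tab$F[tab$term == "group"], f_group, tolerance = 1e-8)
  expect_equal(tab$F[tab$term == "time"], f_time, tolerance = 1e-8)
})

test_that("rm_anova type-I error is near nominal and detects injected effects", {
  # scaled-down Monte-Carlo; the full-size run lives in the acceptance suite
  reject <- function(effect, reps) {
    mean(vapply(seq_len(reps), function(r) {
      set.seed(4000 + r + round(1000 * effect))
      grp <- rep(c("A", "B"), c(4, 5))
      y <- matrix(rnorm(27), 9, 3) + ifelse(grp == "A", effect, 0)
      long <- data.frame(unit = rep(1:9, 3), time = rep(1:3, each = 9),
                         value = as.vector(y), group = rep(grp, 3))
      rm_anova(long, "group")$p[1] < 0.05
    }, logical(1)))
  }
  expect_lt(abs(reject(0, 200) - 0.05), 0.05)
  expect_gt(reject(2.5, 100), 0.5)
})

test_that("Mauchly W matches determinant/trace arithmetic on a worked matrix", {
  set.seed(33)
  Y <- matrix(rnorm(48), 16, 3)
  Y[, 2] <- Y[, 2] * 1.6; Y[, 3] <- Y[, 3] + 0.5 * Y[, 1]
  m <- mauchly_sphericity(Y)
  k <- 3; n <- 16
  ctr <- stats::contr.helmert(k)
  ctr <- sweep(ctr, 2, sqrt(colSums(ctr^2)), `/`)
  S <- stats::cov(Y %*% ctr)
  W <- det(S) / (sum(diag(S)) / (k - 1))^(k - 1)
  df <- k * (k - 1) / 2 - 1
  f <- (2 * (k - 1)^2 + (k - 1) + 2) / (6 * (k - 1) * (n - 1))
  chi2 <- -(1 - f) * (n - 1) * log(W)
  expect_equal(m$W, W, tolerance = 1e-9)
  expect_equal(m$p_value, stats::pchisq(chi2, df, lower.tail = FALSE),
               tolerance = 1e-9)
  expect_equal(m$gg_epsilon, sum(diag(S))^2 / ((k - 1) * sum(S^2)),
               tolerance = 1e-9)
})

test_that("Mauchly accepts compound symmetry and rejects degenerate input", {
  set.seed(34)
  n <- 400
  z <- rnorm(n)
  Y <- cbind(z + rnorm(n), z + rnorm(n), z + rnorm(n))  # compound symmetric
  m <- mauchly_sphericity(Y)
  expect_gt(m$W, 0.95)
  expect_gt(m$p_value, 0.05)
  Ydup <- cbind(Y[, 1], Y[, 1], Y[, 2])
  expect_error(mauchly_sphericity(Ydup), "singular")
})

test_that("patient-weighted means use lesion size as weights", {
  expect_equal(patient_weighted_mean(5, 2.9), 5)
  expect_equal(patient_weighted_mean(c(7, 7, 7), c(1, 5, 9)), 7)
  # patient 7 of the bundled tables: two lesions, diameters 2.9 / 2.5 cm
  adc <- load_lesion_table("adc"); ct <- load_lesion_table("ct")
  i <- which(adc$patient_id == 7)
  rel <- 100 * adc$adc_change_w1[i] / adc$adc_baseline[i]
  wm <- patient_weighted_mean(rel, ct$diameter_pre_cm[ct$patient_id == 7])
  expect_equal(wm, sum(rel * c(2.9, 2.5)) / 5.4, tolerance = 1e-12)
  expect_equal(wm, -23.9, tolerance = 0.05)
  expect_error(patient_weighted_mean(c(1, 2), c(1, 0)), "positive")
})

test_that("PFS correlations drop exclusions and match the Pearson wrapper", {
  params <- data.frame(x = c(1, 2, 3, 4, 5, 6))
  pfs <- c(2, 4, 6, 8, 10, 12)
  out <- pfs_correlation(params, pfs)
  expect_equal(out$r, 1)
  out_neg <- pfs_correlation(data.frame(x = -params$x), pfs)
  expect_equal(out_neg$r, -1)
  set.seed(35)
  params$x <- rnorm(6)
  out2 <- pfs_correlation(params, pfs, exclude = c(2L))
  expect_equal(out2$n, 5)
  expect_equal(out2$r, pearson_correlation(params$x[-2], pfs[-2]),
               tolerance = 1e-12)
  expect_error(pfs_correlation(params[1:3, , drop = FALSE], c(1, NA, 3)),
               "fewer than 3")
})
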