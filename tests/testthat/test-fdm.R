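# repeatability thresholds, voxel classification, cluster filtering,
# fractions

test_that("identical baselines give a zero threshold", {
  m <- make_map(c(1.0, 1.1, 1.3, 0.8))
  thr <- estimate_repeatability_threshold(m, m, array(TRUE, c(4, 1, 1)))
  expect_equal(thr$s_w, 0)
  expect_equal(thr$threshold, 0)
})

test_that("threshold matches the hand-computed one-way ANOVA on 4 voxels", {
  roi <- array(TRUE, c(4, 1, 1))
  b1 <- make_map(c(1.0, 1.1, 1.3, 0.8))
  b2 <- make_map(c(1.2, 0.9, 1.3, 1.0))
  thr <- estimate_repeatability_threshold(b1, b2, roi)
  # d = (0.2, -0.2, 0, 0.2); s_w^2 = mean(d^2/2) = 0.015
  expect_equal(thr$s_w^2, 0.015)
  expect_equal(thr$s_w, sqrt(0.015), tolerance = 1e-12)
  expect_equal(thr$threshold, 2.77 * sqrt(0.015), tolerance = 1e-12)
  expect_equal(thr$threshold, 0.339, tolerance = 1e-3)
  expect_equal(thr$n, 4L)
})

test_that("threshold tracks 2.77 sigma for Gaussian replicate noise", {
  rel_err <- vapply(1:10, function(s) {
    set.seed(s)
    sigma <- 0.1
    d3 <- c(18, 18, 18)
    base <- array(1.4, d3)
    b1 <- adc_map(base + array(rnorm(prod(d3), 0, sigma), d3), spacing = c(2, 2, 2))
    b2 <- adc_map(base + array(rnorm(prod(d3), 0, sigma), d3), spacing = c(2, 2, 2))
    thr <- estimate_repeatability_threshold(b1, b2, array(TRUE, d3))
    abs(thr$threshold - 2.77 * sigma) / (2.77 * sigma)
  }, numeric(1))
  expect_lt(max(rel_err), 0.05)
})

test_that("threshold scales linearly with replicate noise", {
  set.seed(77)
  d3 <- c(15, 15, 15)
  n1 <- array(rnorm(prod(d3)), d3); n2 <- array(rnorm(prod(d3)), d3)
  thr_at <- function(c) {
    b1 <- adc_map(1.4 + c * 0.05 * n1, spacing = c(2, 2, 2))
    b2 <- adc_map(1.4 + c * 0.05 * n2, spacing = c(2, 2, 2))
    estimate_repeatability_threshold(b1, b2, array(TRUE, d3))$threshold
  }
  expect_equal(thr_at(3) / thr_at(1), 3, tolerance = 1e-9)
})

test_that("fewer than two valid ROI voxels is a descriptive failure", {
  b1 <- make_map(c(1, NA, NA, NA))
  expect_error(
    estimate_repeatability_threshold(b1, b1, array(TRUE, c(4, 1, 1))),
    "fewer than 2")
})

test_that("voxel classification obeys the strict-threshold convention", {
  d3 <- c(4, 1, 1)
  roi <- array(TRUE, d3)
  # values chosen to be exactly representable in binary so the boundary
  # comparison is a true equality test, not a rounding artefact
  pre <- make_map(rep(1, 4))
  post <- make_map(1 + c(0.5, -0.5, 0.25, -0.25))
  lab <- classify_voxels(pre, post, roi, 0.25)
  expect_identical(as.integer(lab),
                   unname(FDM_LABELS[c("red", "blue", "green", "green")]))
  # no change at all -> all green
  lab0 <- classify_voxels(pre, pre, roi, 0.25)
  expect_true(all(lab0 == FDM_LABELS[["green"]]))
  expect_error(classify_voxels(pre, post, array(FALSE, d3), 0.25), "ROI")
})

test_that("classification matches a brute-force per-voxel oracle", {
  set.seed(8)
  d3 <- c(9, 8, 5)
  roi <- array(runif(prod(d3)) < 0.7, d3)
  pre <- adc_map(array(runif(prod(d3), 0.8, 2), d3), spacing = c(2, 2, 6))
  post <- adc_map(pre$data + array(rnorm(prod(d3), 0, 0.4), d3),
                  spacing = c(2, 2, 6))
  thr <- 0.35
  lab <- classify_voxels(pre, post, roi, thr)
  oracle <- array(0L, d3)
  for (i in 1:d3[1]) for (j in 1:d3[2]) for (k in 1:d3[3]) {
    if (!roi[i, j, k]) next
    dd <- post$data[i, j, k] - pre$data[i, j, k]
    oracle[i, j, k] <- if (dd > thr) 2L else if (dd < -thr) 3L else 1L
  }
  expect_identical(as.integer(lab), as.integer(oracle))
})

test_that("connected components honour the requested connectivity", {
  m <- array(FALSE, c(4, 4, 1))
  m[1, 1, 1] <- TRUE; m[2, 2, 1] <- TRUE  # diagonal contact
  expect_equal(max(label_components(m, 26)), 1)
  expect_equal(max(label_components(m, 6)), 2)
  # two slices touching only across z
  m2 <- array(FALSE, c(3, 3, 2))
  m2[1, 1, 1] <- TRUE; m2[2, 2, 2] <- TRUE
  expect_equal(max(label_components(m2, 26)), 1)
  expect_equal(max(label_components(m2, 6)), 2)
  # sizes come out right on a mixed field
  set.seed(12)
  m3 <- array(runif(6 * 6 * 3) < 0.3, c(6, 6, 3))
  comp <- label_components(m3, 26)
  expect_equal(sum(comp > 0), sum(m3))
})

test_that("cluster filtering matches the hand-counted 10x10 example", {
  lab <- array(FDM_LABELS[["green"]], c(10, 10, 1))
  lab[3:5, 3:5, 1] <- FDM_LABELS[["red"]]    # 9-voxel red block
  lab[8:9, 8:9, 1] <- FDM_LABELS[["blue"]]   # 4-voxel blue block
  out <- filter_clusters(lab, min_cluster = 6)
  expect_equal(sum(out == FDM_LABELS[["red"]]), 9)
  expect_equal(sum(out == FDM_LABELS[["blue"]]), 0)
  expect_equal(sum(out == FDM_LABELS[["green"]]), 91)
  # fractions over the full 10x10 slice
  fr <- fdm_fractions(out, array(TRUE, c(10, 10, 1)))
  expect_equal(fr$f_red, 9 / 100)
  expect_equal(fr$f_blue, 0)
  expect_equal(fr$f_green, 91 / 100)
  # restricted to the centred 6x6 ROI containing the whole red block
  roi <- array(FALSE, c(10, 10, 1)); roi[3:8, 3:8, 1] <- TRUE
  fr6 <- fdm_fractions(out, roi)
  expect_equal(fr6$f_red, 9 / 36)
})

test_that("cluster filter edge cases: identity, just-below threshold, monotonicity", {
  lab <- array(FDM_LABELS[["green"]], c(8, 8, 1))
  lab[2:6, 2, 1] <- FDM_LABELS[["red"]]  # 5-voxel line
  expect_identical(filter_clusters(lab, 1), lab)
  out <- filter_clusters(lab, 6)
  expect_true(all(out == FDM_LABELS[["green"]]))
  # filtering never increases the significant fraction, never changes green
  set.seed(13)
  lab2 <- array(sample(FDM_LABELS[c("green", "red", "blue")], 500, TRUE,
                       prob = c(0.8, 0.1, 0.1)), c(10, 10, 5))
  for (mc in c(2, 6, 10)) {
    out2 <- filter_clusters(lab2, mc)
    expect_lte(sum(out2 %in% FDM_LABELS[c("red", "blue")]),
               sum(lab2 %in% FDM_LABELS[c("red", "blue")]))
    expect_true(all(out2[lab2 == FDM_LABELS[["green"]]] == FDM_LABELS[["green"]]))
  }
})

test_that("fractions sum to one and respect the red/blue symmetry", {
  set.seed(14)
  d3 <- c(8, 8, 4)
  roi <- array(runif(prod(d3)) < 0.8, d3)
  pre <- adc_map(array(1.4, d3), spacing = c(2, 2, 6))
  post <- adc_map(1.4 + array(rnorm(prod(d3), 0, 0.5), d3), spacing = c(2, 2, 6))
  lab <- classify_voxels(pre, post, roi, 0.4)
  fr <- fdm_fractions(lab, roi)
  expect_equal(fr$f_red + fr$f_blue + fr$f_green, 1)
  # negating the change swaps red and blue exactly
  post_neg <- adc_map(2 * 1.4 - post$data, spacing = c(2, 2, 6))
  fr_neg <- fdm_fractions(classify_voxels(pre, post_neg, roi, 0.4), roi)
  expect_equal(fr_neg$f_red, fr$f_blue)
  expect_equal(fr_neg$f_blue, fr$f_red)
  expect_error(fdm_fractions(lab, array(FALSE, d3)), "empty")
  # all-green field
  fr0 <- fdm_fractions(classify_voxels(pre, pre, roi, 0.4), roi)
  expect_equal(c(fr0$f_red, fr0$f_blue, fr0$f_green), c(0, 0, 1))
})

test_that("invalid-fit voxels are excluded from the fDM denominator", {
  d3 <- c(4, 1, 1)
  roi <- array(TRUE, d3)
  pre <- make_map(c(1, 1, 1, NA))
  post <- make_map(c(2, 1, 1, 2))
  lab <- classify_voxels(pre, post, roi, 0.3)
  fr <- fdm_fractions(lab, roi)
  expect_equal(fr$n, 3L)
  expect_equal(fr$f_red, 1 / 3)
})
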