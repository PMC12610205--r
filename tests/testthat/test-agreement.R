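test_that("ICC matches a two-way ANOVA oracle on small integer tables", {
  tabs <- list(
    matrix(c(9, 6, 8, 2, 1, 3, 5, 4, 7), 3, 3),
    matrix(c(1, 2, 3, 2, 3, 4, 1, 3, 5), 3, 3),
    matrix(c(10, 40, 70, 12, 38, 75, 8, 45, 66), 3, 3)
  )
  for (m in tabs)
    expect_equal(icc_absolute_agreement(m), oracle_icc_a1(m),
                 tolerance = 1e-12)
  set.seed(61)
  for (i in 1:20) {
    m <- matrix(sample(0:100, 15, replace = TRUE), 5, 3)
    if (stats::sd(m) == 0) next
    expect_equal(icc_absolute_agreement(m), oracle_icc_a1(m),
                 tolerance = 1e-10)
  }
})

test_that("ICC behaves at agreement extremes", {
  x <- c(5, 30, 60, 90)
  # identical columns, nonzero row variance: perfect agreement
  expect_equal(icc_absolute_agreement(cbind(x, x)), 1, tolerance = 1e-12)
  # large constant offset with small row variance: absolute agreement ~ 0
  y <- c(10, 11, 12, 13)
  expect_lt(icc_absolute_agreement(cbind(y, y + 80)), 0.01)
  # independent random columns: near zero
  set.seed(71)
  m <- cbind(runif(50, 0, 100), runif(50, 0, 100))
  expect_lt(abs(icc_absolute_agreement(m)), 0.3)
  # all-equal table: 1 by convention, with warning
  expect_warning(v <- icc_absolute_agreement(matrix(5, 4, 3)), "zero total")
  expect_equal(v, 1)
  expect_error(icc_absolute_agreement(matrix(1:2, 1, 2)), "at least 2")
})

test_that("ICC is invariant under a common additive shift", {
  set.seed(83)
  m <- matrix(runif(20, 0, 100), 5, 4)
  expect_equal(icc_absolute_agreement(m), icc_absolute_agreement(m + 17.3),
               tolerance = 1e-9)
  # average-measures variant is at least the single-measures value
  expect_gte(icc_absolute_agreement(m, "average"),
             icc_absolute_agreement(m, "single"))
})

test_that("pair statistics match long-hand arithmetic", {
  x <- c(10, 20, 30, 40); y <- c(12, 18, 33, 41)
  ps <- pair_stats(x, y)
  d <- x - y                          # -2, 2, -3, -1
  expect_equal(ps$mean_diff, mean(d))
  expect_equal(ps$sd_diff, sqrt(sum((d - mean(d))^2) / 3))
  half <- qt(0.975, 3) * ps$sd_diff / 2
  expect_equal(ps$ci95, c(ps$mean_diff - half, ps$mean_diff + half))
  expect_equal(ps$pearson_r, cor(x, y))
  # CI contains the mean difference
  expect_true(ps$ci95[1] <= ps$mean_diff && ps$mean_diff <= ps$ci95[2])
  # shifted copy: r = 1, mean_diff = -5 under the x - y convention
  ps2 <- pair_stats(x, x + 5)
  expect_equal(ps2$mean_diff, -5)
  expect_equal(ps2$sd_diff, 0)
  expect_equal(ps2$pearson_r, 1)
  # identical zero-variance inputs: r is an undefined marker, not 1
  ps3 <- pair_stats(rep(4, 5), rep(4, 5))
  expect_true(is.na(ps3$pearson_r))
  expect_equal(ps3$mean_diff, 0)
  expect_error(pair_stats(1:2, 1:2), "at least 3")
})

test_that("reliability labels use strict boundaries", {
  expect_equal(reliability_label(0.95), "excellent")
  expect_equal(reliability_label(0.90), "good")
  expect_equal(reliability_label(0.80), "good")
  expect_equal(reliability_label(0.75), "below_good")
  expect_equal(reliability_label(0.2), "below_good")
  expect_error(reliability_label(1.2), "exceed")
})

test_that("calibration sweep recovers the designed coverage threshold", {
  # panel whose consensus equals the truth at threshold 0.8: coverage values
  # kept >= 0.05 away from every sweep point so recovery is exact
  # each sweep point below 0.8 loses agreement somewhere (values like 0.74,
  # 0.65 flip between adjacent thresholds) and 0.86 breaks 0.9, so the ICC
  # peak at 0.8 is unique
  covs <- list(c(0.95, 0.95, 0.92, 0.15, 0.22, 0.35, 0.55, 0.74),
               c(0.98, 0.92, 0.86, 0.86, 0.25, 0.45, 0.12, 0.32),
               c(0.95, 0.05, 0.15, 0.25, 0.35, 0.45, 0.74, 0.65),
               c(0.92, 0.86, 0.95, 0.98, 0.86, 0.05, 0.15, 0.25),
               c(0.86, 0.92, 0.95, 0.15, 0.05, 0.25, 0.45, 0.55))
  specs <- lapply(seq_along(covs), function(i)
    make_field_spec(seed = 300 + i, n_nuclei = 8, coverage = covs[[i]]))
  fields <- lapply(specs, function(s) list(image = render_h_dab(s)$image))
  consensus <- vapply(specs, true_percent_positive, numeric(1),
                      threshold = 0.8)
  cal <- calibrate_coverage_threshold(fields, consensus)
  expect_s3_class(cal, "nq_calibration")
  expect_equal(nrow(cal$curve), 10L)
  expect_equal(cal$best_threshold, 0.8)
  expect_equal(cal$best_icc, 1, tolerance = 1e-9)
  # reproducible bit-for-bit
  cal2 <- calibrate_coverage_threshold(fields, consensus)
  expect_identical(cal$curve, cal2$curve)
  # single-point sweep
  cal1 <- calibrate_coverage_threshold(fields, consensus, thresholds = 0.8)
  expect_equal(nrow(cal1$curve), 1L)
  expect_equal(cal1$best_threshold, 0.8)
  # ties resolve toward the lower threshold: consensus equal to program
  # output at every threshold (single shared value pattern)
  expect_error(calibrate_coverage_threshold(fields[1], consensus[1]),
               "at least 2")
})

test_that("rater tables round-trip through CSV", {
  m <- matrix(c(10.5, 40, 70, 20, 42.25, 68), 3, 2,
              dimnames = list(paste0("image", 1:3), c("r1", "r2")))
  p <- tempfile(fileext = ".csv")
  write.csv(data.frame(image = rownames(m), m, check.names = FALSE), p,
            row.names = FALSE)
  back <- read_rater_table(p)
  expect_equal(unname(back), unname(m))
  bad <- tempfile(fileext = ".csv")
  write.csv(data.frame(image = "a", r1 = 150), bad, row.names = FALSE)
  expect_error(read_rater_table(bad), "\\[0, 100\\]")
})
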