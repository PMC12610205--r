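mk_region <- function(pixels, area = length(pixels), mean_gray = 100,
                      positive = NA, coverage = NA_real_) {
  list(label = 1L, pixels = pixels, area = area, mean_gray = mean_gray,
       coverage = coverage, positive = positive,
       intensity_class = NA_character_)
}

test_that("coverage fraction counts signal pixels over the nucleus area", {
  sig <- matrix(0L, 10, 10)
  px <- 1:100
  sig[px[1:80]] <- 1L
  r <- mk_region(px)
  expect_equal(coverage_fraction(r, sig), 0.80)
  expect_equal(coverage_fraction(r, matrix(0L, 10, 10)), 0)
  expect_equal(coverage_fraction(r, matrix(1L, 10, 10)), 1)
  # agrees exactly with a per-pixel double loop on random fields
  set.seed(19)
  for (i in 1:50) {
    m <- matrix(rbinom(300, 1, 0.4), 15, 20)
    sigr <- matrix(rbinom(300, 1, runif(1)), 15, 20)
    for (r in measure_regions(label_components(m), sigr * 0L))
      expect_identical(coverage_fraction(r, sigr), oracle_coverage(r, sigr))
  }
})

test_that("positivity boundary is inclusive", {
  expect_true(classify_positive(0.80, 0.80))
  expect_false(classify_positive(0.79, 0.80))
  expect_true(classify_positive(0, 0))
  expect_true(classify_positive(0.3, 0))
})

test_that("percent positive handles the empty field as undefined", {
  regs <- lapply(1:5, function(i) mk_region(i, positive = i <= 4))
  expect_equal(percent_positive(regs), 80)
  regs0 <- lapply(1:10, function(i) mk_region(i, positive = FALSE))
  expect_equal(percent_positive(regs0), 0)
  expect_warning(p <- percent_positive(list()), "empty field")
  expect_true(is.na(p))
})

test_that("intensity classes follow the 60/120 mean-gray boundaries", {
  cls <- function(mg, pos = TRUE)
    classify_intensity(mk_region(1L, mean_gray = mg, positive = pos))
  expect_equal(cls(59), "strong")
  expect_equal(cls(59.999), "strong")
  expect_equal(cls(60), "moderate")
  expect_equal(cls(119.999), "moderate")
  expect_equal(cls(120), "weak")
  expect_equal(cls(255), "weak")
  expect_equal(cls(10, pos = FALSE), "negative")
  expect_error(cls(300), "\\[0, 255\\]")
})

test_that("histoscore and overall score follow the weighted-sum formulas", {
  expect_equal(histoscore(100, 0, 0), 300)
  expect_equal(histoscore(0, 0, 0), 0)
  expect_equal(histoscore(50, 30, 20), 230)
  ov <- overall_score(100, 0, 0, 0)
  expect_equal(ov$score, 400); expect_equal(ov$category, "strong")
  ov2 <- overall_score(0, 0, 0, 100)
  expect_equal(ov2$score, 100); expect_equal(ov2$category, "negative")
  # the >=99%-negative cut-off overrides the score category
  ov3 <- overall_score(0, 0, 1, 99)
  expect_equal(ov3$score, 101); expect_equal(ov3$category, "negative")
  # category boundaries: strict > 301 for strong, so score 301 is moderate
  expect_equal(overall_score(67, 0, 0, 33)$category, "moderate")  # score 301
  expect_equal(overall_score(68, 0, 0, 32)$category, "strong")    # score 304
  expect_error(overall_score(50, 0, 0, 0), "sum to 100")
})

test_that("overall category partitions the score range", {
  # sweep compositions of strong vs negative: score = 100 + 3 * pct_strong
  cats <- vapply(seq(0, 100, by = 0.5), function(s)
    overall_score(s, 0, 0, 100 - s)$category, character(1))
  scores <- 100 + 3 * seq(0, 100, by = 0.5)
  expect_true(all(cats[scores > 301] == "strong"))
  expect_true(all(cats[scores <= 301 & scores > 201] == "moderate"))
  expect_true(all(cats[scores <= 201 & scores > 101 &
                         (100 - seq(0, 100, by = 0.5)) < 99] == "weak"))
  expect_true(all(cats[scores <= 101 | (100 - seq(0, 100, by = 0.5)) >= 99]
                  == "negative"))
})

test_that("overall score is histoscore plus 100 on random compositions", {
  set.seed(47)
  for (i in 1:100) {
    p <- as.vector(stats::rmultinom(1, 200, runif(4))) / 2
    hs <- histoscore(p[1], p[2], p[3])
    ov <- overall_score(p[1], p[2], p[3], p[4])
    expect_equal(ov$score, hs + 100, tolerance = 1e-9)
    expect_gte(hs, 0); expect_lte(hs, 300)
    expect_gte(ov$score, 100); expect_lte(ov$score, 400)
  }
})

test_that("quantitative intensity respects scope and matches mean_gray", {
  regs <- lapply(1:5, function(i)
    modifyList(mk_region(i, mean_gray = 10 * i), list(label = i,
                                                      positive = i <= 2)))
  all_tab <- quantitative_intensity(regs, "all")
  expect_equal(nrow(all_tab), 5L)
  expect_equal(all_tab$mean_gray, 10 * (1:5))
  pos_tab <- quantitative_intensity(regs, "positive_only")
  expect_equal(nrow(pos_tab), 2L)
  none <- lapply(regs, function(r) modifyList(r, list(positive = FALSE)))
  expect_warning(tab0 <- quantitative_intensity(none, "positive_only"),
                 "no positive")
  expect_equal(nrow(tab0), 0L)
})

test_that("analyze_field recovers designed positivity on synthetic H-DAB", {
  spec <- make_field_spec(seed = 101, n_nuclei = 20,
                          coverage = rep(c(1, 0), c(12, 8)))
  img <- render_h_dab(spec)$image
  f <- analyze_field(image = img, config = quant_config("h_dab"))
  expect_equal(f$result$n_nuclei, 20L)
  expect_equal(f$result$pct_positive, 60)
  # degenerate threshold 0: everything positive
  f0 <- analyze_field(image = img,
                      config = quant_config("h_dab", coverage_threshold = 0))
  expect_equal(f0$result$pct_positive, 100)
  # fluorescence with an empty signal channel: nothing positive
  fl <- render_fluorescence(spec)
  expect_warning(
    fe <- analyze_field(nuclei = fl$nuclei,
                        signal = matrix(0L, spec$height, spec$width),
                        config = quant_config("fluorescence")),
    "constant signal")
  expect_equal(fe$result$pct_positive, 0)
  # mode/arity mismatch
  expect_error(analyze_field(config = quant_config("h_dab")), "needs 'image'")
  expect_error(analyze_field(image = img,
                             config = quant_config("fluorescence")),
               "nuclei")
})

test_that("pct_positive is non-increasing in the coverage threshold", {
  spec <- make_field_spec(seed = 55, n_nuclei = 15,
                          coverage = seq(0.05, 0.95, length.out = 15))
  img <- render_h_dab(spec)$image
  pcts <- vapply(seq(0, 1, by = 0.1), function(th) {
    analyze_field(image = img,
                  config = quant_config("h_dab",
                                        coverage_threshold = th))$result$pct_positive
  }, numeric(1))
  expect_true(all(diff(pcts) <= 0))
})

test_that("preprocessed mode consumes external masks or label images", {
  spec <- make_field_spec(seed = 77, n_nuclei = 10,
                          coverage = rep(c(1, 0), 5))
  rh <- render_h_dab(spec)
  sep <- separate_h_dab(rh$image)
  # build an external binary mask from the known geometry
  mask <- matrix(0L, spec$height, spec$width)
  for (i in seq_len(10)) {
    ds <- nucquant:::disk_and_sector(spec$nuclei$row[i], spec$nuclei$col[i],
                                     spec$nuclei$radius[i], 0, spec$height,
                                     spec$width)
    mask[ds$disk] <- 255L
  }
  f <- analyze_field(nuclei = mask, signal = sep$dab,
                     config = quant_config("preprocessed_h_dab"))
  expect_equal(f$result$n_nuclei, 10L)
  expect_equal(f$result$pct_positive, 50)
  # same field via a label image (as a deep-learning segmenter would emit)
  lab <- label_components(mask > 0)
  f2 <- analyze_field(nuclei = lab * 3L, signal = sep$dab,
                      config = quant_config("preprocessed_h_dab"))
  expect_equal(f2$result$n_nuclei, 10L)
  expect_equal(f2$result$pct_positive, 50)
})

test_that("semiquantitative summary sums to 100 and scores stay in range", {
  spec <- make_field_spec(seed = 202, n_nuclei = 18,
                          coverage = rep(c(1, 0.9, 0), 6))
  img <- render_h_dab(spec)$image
  f <- analyze_field(image = img,
                     config = quant_config("h_dab",
                                           intensity_mode = "semiquantitative"))
  r <- f$result
  expect_equal(r$pct_strong + r$pct_moderate + r$pct_weak + r$pct_negative,
               100, tolerance = 1e-9)
  expect_gte(r$histoscore, 0); expect_lte(r$histoscore, 300)
  expect_gte(r$overall_score, 100); expect_lte(r$overall_score, 400)
  expect_equal(r$overall_score, r$histoscore + 100, tolerance = 1e-9)
  expect_true(r$overall_category %in% c("negative", "weak", "moderate",
                                        "strong"))
})
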