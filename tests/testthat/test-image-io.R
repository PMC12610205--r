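test_that("read_image round-trips canonical 8-bit TIFF and PNG pixel-exactly", {
  set.seed(7)
  rgb <- array(sample(0:255, 4 * 5 * 3, replace = TRUE), c(4, 5, 3))
  gray <- matrix(sample(0:255, 24, replace = TRUE), 4, 6)
  for (ext in c("tif", "png")) {
    p <- tempfile(fileext = paste0(".", ext))
    write_image(rgb, p)
    expect_identical(read_image(p), nucquant:::canonical8(rgb))
    p2 <- tempfile(fileext = paste0(".", ext))
    write_image(gray, p2)
    expect_identical(read_image(p2), nucquant:::canonical8(gray))
  }
})

test_that("read_image reports shape in (height, width) and handles depth/alpha", {
  # all-white RGB
  p <- tempfile(fileext = ".tif")
  write_image(array(255, c(4, 4, 3)), p)
  x <- read_image(p)
  expect_true(all(x == 255L))
  # rectangular: 12 rows x 19 cols survives as height 12, width 19
  p2 <- tempfile(fileext = ".png")
  write_image(matrix(0L, 12, 19), p2)
  expect_equal(dim(read_image(p2)), c(12L, 19L))
  # 16-bit constant 65535 -> 255 after full-range rescale
  p3 <- tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(1, 3, 3), p3, bits.per.sample = 16L)
  expect_true(all(read_image(p3) == 255L))
  # 16-bit midpoint maps linearly
  p4 <- tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(32768 / 65535, 3, 3), p4, bits.per.sample = 16L)
  expect_true(all(read_image(p4) == 128L))
  # alpha channel dropped
  p5 <- tempfile(fileext = ".png")
  png::writePNG(array(runif(4 * 4 * 4), c(4, 4, 4)), p5)
  expect_equal(nucquant:::n_channels(read_image(p5)), 3L)
  # unreadable path errors
  expect_error(read_image(tempfile(fileext = ".tif")), "not found")
})

test_that("to_gray8 averages channels unweighted and is idempotent", {
  px <- function(r, g, b) array(c(r, g, b), c(1, 1, 3))
  expect_equal(as.vector(to_gray8(px(255, 255, 255))), 255L)
  expect_equal(as.vector(to_gray8(px(0, 0, 0))), 0L)
  expect_equal(as.vector(to_gray8(px(10, 20, 40))), 23L)  # round(70/3)
  g <- matrix(sample(0:255, 30, replace = TRUE), 5, 6)
  expect_identical(to_gray8(to_gray8(g)), to_gray8(g))
})

test_that("nucleus table round-trips coverage to 4 decimals", {
  reg <- function(label, area, cov, pos, mg, cls)
    list(label = label, pixels = seq_len(area), area = area, mean_gray = mg,
         coverage = cov, positive = pos, intensity_class = cls)
  p <- tempfile(fileext = ".csv")
  # empty list: header only
  write_nucleus_table(list(), p)
  expect_length(readLines(p), 1L)
  # two nuclei: header + 2 rows; coverage printed with 4 decimals
  write_nucleus_table(list(reg(1L, 400L, 0.85, TRUE, 55.2, "strong"),
                           reg(2L, 350L, 1 / 3, FALSE, 200.4, "negative")), p)
  lines <- readLines(p)
  expect_length(lines, 3L)
  expect_match(lines[2], "0.8500", fixed = TRUE)
  back <- utils::read.csv(p)
  expect_equal(back$coverage, c(0.8500, 0.3333), tolerance = 1e-12)
})

test_that("overlay draws outlines only, colour-coded by class", {
  img <- array(100L, c(20, 20, 3))
  # no regions: pixel-identical
  expect_identical(write_overlay(img, list()), nucquant:::canonical8(img))
  # one square region: outline changed, interior untouched
  px <- as.vector(outer(5:9, (6:10 - 1) * 20, "+"))
  reg <- list(label = 1L, pixels = px, area = length(px), mean_gray = 0,
              coverage = 1, positive = TRUE, intensity_class = NA_character_)
  ov <- write_overlay(img, list(reg))
  interior <- px[!px %in% nucquant:::region_outline(px, 20L, 20L)]
  expect_true(all(ov[interior] == 100L))
  edge <- nucquant:::region_outline(px, 20L, 20L)
  expect_true(all(ov[edge] != 100L | ov[edge + 400L] != 100L))
  # four classes give four distinct outline colours
  mk <- function(r0, c0, cls) {
    p <- as.vector(outer(r0:(r0 + 2), (c0:(c0 + 2) - 1) * 20, "+"))
    list(label = 1L, pixels = p, area = length(p), mean_gray = 0,
         coverage = 1, positive = cls != "negative", intensity_class = cls)
  }
  regs <- list(mk(2, 2, "negative"), mk(2, 12, "weak"),
               mk(12, 2, "moderate"), mk(12, 12, "strong"))
  ov4 <- write_overlay(img, regs)
  cols <- unique(vapply(regs, function(r) {
    e <- nucquant:::region_outline(r$pixels, 20L, 20L)[1]
    paste(ov4[e], ov4[e + 400L], ov4[e + 800L])
  }, character(1)))
  expect_length(cols, 4L)
  # out-of-bounds region errors
  bad <- list(label = 9L, pixels = 500L, area = 1L, mean_gray = 0,
              coverage = 0, positive = FALSE, intensity_class = NA_character_)
  expect_error(write_overlay(img, list(bad)), "bounds")
})
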