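#' @title Canonical 8-bit raster images
#'
#' @description
#' All pipeline stages operate on plain base-R arrays of integer intensities
#' in \code{[0, 255]}: a \code{height x width} matrix for single-channel
#' images and a \code{height x width x 3} array for RGB. \code{[i, j]} indexes
#' row \code{i} (from the top of the image) and column \code{j} (from the
#' left). No special class is attached; any numeric matrix/array in range is
#' accepted and canonicalized on entry.
#'
#' @name raster-images
NULL

n_channels <- function(img) {
  d <- dim(img)
  if (is.null(d) || length(d) < 2L) stop("image must be a matrix or 3-d array")
  if (length(d) == 2L) return(1L)
  if (length(d) == 3L && d[3] %in% c(1L, 3L)) return(as.integer(d[3]))
  stop("unsupported image shape: ", paste(d, collapse = "x"))
}

assert_gray <- function(img, what = "image") {
  if (n_channels(img) != 1L)
    stop(what, " must be single-channel (got ", n_channels(img), " channels)")
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img
}

# Clamp + round any numeric raster to the canonical 8-bit integer range
# (integer storage, whatever the input type).
canonical8 <- function(img) {
  v <- as.integer(pmin(255, pmax(0, round(img))))
  dim(v) <- dim(img)
  v
}

#' Read a raster image as canonical 8-bit
#'
#' Reads a TIFF or PNG file into the canonical 8-bit representation
#' (see \link{raster-images}). Bit depths above 8 are rescaled by the linear
#' map \code{[0, 2^depth - 1] -> [0, 255]} (full-range, not per-image
#' min--max, so a batch of images shares one scale). An alpha channel, if
#' present, is dropped.
#'
#' @param path Path to a \code{.tif}/\code{.tiff} or \code{.png} file.
#' @return An integer matrix (grayscale) or \code{h x w x 3} array (RGB)
#'   with values in \code{[0, 255]}.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format: .", ext, " (expected TIFF or PNG)")
  )
  # readTIFF may return a list of directories; take the first
  if (is.list(x) && !is.array(x)) x <- x[[1L]]
  d <- dim(x)
  if (length(d) == 3L) {
    if (d[3] == 4L) x <- x[, , 1:3, drop = FALSE]   # drop alpha
    if (d[3] == 2L) x <- x[, , 1L]                  # gray + alpha
    d <- dim(x)
    if (length(d) == 3L && !d[3] %in% c(1L, 3L))
      stop("unsupported channel count after alpha drop: ", d[3])
    if (length(d) == 3L && d[3] == 1L) x <- x[, , 1L]
  }
  # tiff/png normalize all bit depths to [0,1]; x*255 is the full-range
  # linear rescale for 8- and 16-bit sources alike.
  canonical8(x * 255)
}

#' Write a canonical 8-bit image to TIFF or PNG
#'
#' @param img Canonical 8-bit image (see \link{raster-images}).
#' @param path Output path; format chosen by extension.
#' @return Invisibly, \code{path}.
#' @export
write_image <- function(img, path) {
  img <- canonical8(img)
  ext <- tolower(tools::file_ext(path))
  x <- img / 255
  switch(ext,
    tif = , tiff = tiff::writeTIFF(x, path, bits.per.sample = 8L),
    png = png::writePNG(x, path),
    stop("unsupported image format: .", ext, " (expected TIFF or PNG)")
  )
  invisible(path)
}

#' Convert an image to single-channel 8-bit
#'
#' Single-channel input is returned unchanged. RGB input is converted
#' per pixel to \code{round((R + G + B) / 3)}, the unweighted channel mean
#' (the convention of the ImageJ platform the method was developed on).
#'
#' @param img Canonical 8-bit image.
#' @return Integer matrix with values in \code{[0, 255]}.
#' @export
to_gray8 <- function(img) {
  if (n_channels(img) == 1L) return(canonical8(assert_gray(img)))
  canonical8((img[, , 1L] + img[, , 2L] + img[, , 3L]) / 3)
}

#' Write the per-nucleus results table
#'
#' One CSV row per nucleus: field id, label, area (px), signal coverage
#' fraction, positive flag, mean gray value, intensity class. Fractional
#' columns are written with 4 decimal places.
#'
#' @param regions List of nucleus regions (see [measure_regions()]) or the
#'   data frame from [regions_table()].
#' @param path Output CSV path.
#' @param field_id Field identifier written in the first column.
#' @return Invisibly, \code{path}.
#' @export
write_nucleus_table <- function(regions, path, field_id = "field") {
  df <- if (is.data.frame(regions)) regions else regions_table(regions)
  out <- data.frame(
    field = rep(field_id, nrow(df)),
    label = df$label,
    area = df$area,
    coverage = sprintf("%.4f", df$coverage),
    positive = df$positive,
    mean_gray = sprintf("%.4f", df$mean_gray),
    intensity_class = df$intensity_class,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# boundary pixels of a pixel-index set: pixels with a 4-neighbour outside the set
region_outline <- function(pixels, h, w) {
  inset <- logical(h * w)
  inset[pixels] <- TRUE
  r <- ((pixels - 1L) %% h) + 1L
  cc <- ((pixels - 1L) %/% h) + 1L
  on_border <- r == 1L | r == h | cc == 1L | cc == w
  nb_out <- on_border
  for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
    rn <- r + d[1]; cn <- cc + d[2]
    ok <- rn >= 1L & rn <= h & cn >= 1L & cn <= w
    idx <- pmin(pmax((cn - 1L) * h + rn, 1L), h * w)
    nb_out <- nb_out | (ok & !inset[idx])
  }
  pixels[nb_out]
}

#' Write a classification overlay image
#'
#' Draws each nucleus outline on top of the source image, colour-coded by
#' classification: blue = negative, yellow = weak, orange = moderate,
#' red = strong, green = positive (when no intensity class was computed).
#' Interior pixels are left untouched.
#'
#' @param img Canonical 8-bit image (grayscale is expanded to RGB).
#' @param regions List of nucleus regions.
#' @param path Output PNG path (or NULL to return the overlay array).
#' @return Invisibly the overlay RGB array; written to \code{path} if given.
#' @export
write_overlay <- function(img, regions, path = NULL) {
  if (n_channels(img) == 1L) {
    g <- assert_gray(img)
    img <- array(g, dim = c(dim(g), 3L))
  }
  img <- canonical8(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  plane <- h * w
  cols <- list(negative = c(60L, 60L, 255L), weak = c(255L, 255L, 0L),
               moderate = c(255L, 140L, 0L), strong = c(255L, 0L, 0L),
               positive = c(0L, 255L, 0L))
  for (rg in regions) {
    if (any(rg$pixels < 1L | rg$pixels > plane))
      stop("region ", rg$label, " lies outside the image bounds")
    cls <- rg$intensity_class
    if (is.null(cls) || is.na(cls)) cls <- if (isTRUE(rg$positive)) "positive" else "negative"
    col <- cols[[cls]]
    edge <- region_outline(rg$pixels, h, w)
    for (ch in 1:3) img[edge + (ch - 1L) * plane] <- col[ch]
  }
  if (!is.null(path)) write_image(img, path)
  invisible(img)
}
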