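#' Label 8-connected components of a binary mask
#'
#' Particle detection in the ImageJ "Analyze Particles" sense: foreground
#' pixels touching horizontally, vertically or diagonally belong to one
#' object. Labels are assigned 1..n in raster-scan order (top row first,
#' left to right) of each component's first pixel, so labelling is fully
#' deterministic.
#'
#' Implemented by iterated label propagation (each foreground pixel takes the
#' minimum provisional label over its 8-neighbourhood until a fixed point);
#' the installed image packages only offer 4-connected labelling.
#'
#' @param mask Integer/logical matrix; non-zero is foreground.
#' @return Integer matrix of labels, 0 = background, with attribute
#'   \code{n_labels}.
#' @export
label_components <- function(mask) {
  if (length(dim(mask)) != 2L) stop("mask must be a matrix")
  h <- nrow(mask); w <- ncol(mask)
  fg <- mask != 0
  lab <- matrix(0L, h, w)
  if (!any(fg)) { attr(lab, "n_labels") <- 0L; return(lab) }
  # provisional labels: raster-scan (row-major) order so the final relabel
  # by minimum is already in first-pixel order
  rm_order <- matrix(seq_len(h * w), h, w, byrow = TRUE)
  cur <- ifelse(fg, rm_order, Inf)
  shift <- function(m, dr, dc) {
    out <- matrix(Inf, h, w)
    rs <- max(1, 1 + dr):min(h, h + dr)
    cs <- max(1, 1 + dc):min(w, w + dc)
    out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
    out
  }
  repeat {
    nb <- cur
    for (d in list(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, -1L),
                   c(0L, 1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))) {
      nb <- pmin(nb, shift(cur, d[1], d[2]))
    }
    nb[!fg] <- Inf
    if (identical(nb, cur)) break
    cur <- nb
  }
  ids <- sort(unique(cur[fg]))
  lab[fg] <- match(cur[fg], ids)
  attr(lab, "n_labels") <- length(ids)
  lab
}

n_labels <- function(lm) {
  n <- attr(lm, "n_labels")
  if (is.null(n)) n <- if (any(lm > 0)) max(lm) else 0L
  as.integer(n)
}

# re-number positive labels to consecutive 1..k, keeping raster-scan order
# of each component's first pixel
compact_labels <- function(lm) {
  pos <- which(lm > 0)
  out <- matrix(0L, nrow(lm), ncol(lm))
  if (!length(pos)) { attr(out, "n_labels") <- 0L; return(out) }
  h <- nrow(lm); w <- ncol(lm)
  r <- ((pos - 1L) %% h) + 1L
  cc <- ((pos - 1L) %/% h) + 1L
  rmaj <- (r - 1L) * w + cc
  first_px <- tapply(rmaj, lm[pos], min)
  ord <- names(sort(first_px))
  out[pos] <- match(as.character(lm[pos]), ord)
  attr(out, "n_labels") <- length(ord)
  out
}

#' Ingest an externally produced nucleus mask or label image
#'
#' Entry point for the preprocessed H-DAB mode, where nuclei have been
#' segmented outside the pipeline (e.g. by StarDist or Trainable WEKA) and
#' only their masks are supplied. An image with exactly two distinct values
#' is treated as a binary mask (thresholded at the midpoint of the two
#' values, brighter side = foreground) and labelled 8-connected; an image
#' with more distinct values is treated as a label image and its labels are
#' compacted to 1..n.
#'
#' @param img Single-channel image (8-bit mask or integer label image).
#' @return Integer label matrix with attribute \code{n_labels}.
#' @export
ingest_mask <- function(img) {
  img <- assert_gray(img)
  vals <- sort(unique(as.vector(img)))
  if (length(vals) == 1L) {
    lab <- matrix(0L, nrow(img), ncol(img))
    attr(lab, "n_labels") <- 0L
    return(lab)
  }
  if (length(vals) == 2L) {
    mid <- mean(vals)
    return(label_components(img > mid))
  }
  compact_labels(round(img))
}

#' Size-gate labelled particles into nucleus regions
#'
#' Mirrors the particle-analysis stage: optionally fills holes in each
#' object (so nucleoli voids count as nuclear area), optionally drops
#' objects touching the image border, keeps objects with
#' \code{min_area <= area <= max_area}, and re-labels the survivors 1..k.
#'
#' @param lm Label matrix from [label_components()] or [ingest_mask()].
#' @param min_area,max_area Area gate in pixels (inclusive).
#' @param exclude_edges Drop components touching the image border.
#' @param fill_holes Fill enclosed background holes before measuring area.
#' @return List of nucleus regions; each a list with \code{label},
#'   \code{pixels} (linear indices into the image matrix), \code{area},
#'   and placeholders \code{mean_gray}, \code{coverage}, \code{positive},
#'   \code{intensity_class}. The filtered label matrix is attached as
#'   attribute \code{label_map}.
#' @export
filter_particles <- function(lm, min_area = 0, max_area = Inf,
                             exclude_edges = FALSE, fill_holes = TRUE) {
  if (min_area > max_area) stop("min_area must not exceed max_area")
  if (fill_holes && any(lm > 0)) {
    lm2 <- EBImage::fillHull(lm)
    attr(lm2, "n_labels") <- n_labels(lm)
    lm <- lm2
  }
  h <- nrow(lm); w <- ncol(lm)
  pos <- which(lm > 0)
  keep_lm <- matrix(0L, h, w)
  regions <- list()
  if (length(pos)) {
    labs <- lm[pos]
    areas <- tabulate(labs)
    edge_labs <- integer(0)
    if (exclude_edges) {
      edge_px <- unique(c(lm[1, ], lm[h, ], lm[, 1], lm[, w]))
      edge_labs <- edge_px[edge_px > 0]
    }
    keep <- which(areas >= min_area & areas <= max_area &
                    !(seq_along(areas) %in% edge_labs) & areas > 0)
    newlab <- 0L
    for (l in keep) {
      newlab <- newlab + 1L
      px <- pos[labs == l]
      keep_lm[px] <- newlab
      regions[[newlab]] <- list(label = newlab, pixels = px,
                                area = length(px), mean_gray = NA_real_,
                                coverage = NA_real_, positive = NA,
                                intensity_class = NA_character_)
    }
  }
  attr(regions, "label_map") <- keep_lm
  regions
}

#' Measure area and mean intensity of labelled regions
#'
#' @param lm Label matrix, or a region list from [filter_particles()].
#' @param channel Single-channel image on which to measure mean gray value.
#' @return List of nucleus regions with \code{area} and \code{mean_gray}
#'   filled in.
#' @export
measure_regions <- function(lm, channel) {
  channel <- assert_gray(channel)
  if (is.list(lm)) {
    regions <- lm
    lmat <- attr(lm, "label_map")
    if (!is.null(lmat) && !identical(dim(lmat), dim(channel)))
      stop("channel shape does not match the label map")
    for (i in seq_along(regions))
      regions[[i]]$mean_gray <- mean(channel[regions[[i]]$pixels])
    return(regions)
  }
  if (!identical(dim(lm), dim(channel)))
    stop("channel shape does not match the label map")
  pos <- which(lm > 0)
  if (!length(pos)) return(list())
  labs <- lm[pos]
  means <- tapply(as.numeric(channel[pos]), labs, mean)
  lapply(sort(unique(labs)), function(l) {
    px <- pos[labs == l]
    list(label = as.integer(l), pixels = px, area = length(px),
         mean_gray = unname(means[as.character(l)]),
         coverage = NA_real_, positive = NA, intensity_class = NA_character_)
  })
}

#' Per-nucleus results as a data frame
#'
#' @param regions List of nucleus regions.
#' @return Data frame with one row per nucleus (label, area, mean_gray,
#'   coverage, positive, intensity_class).
#' @export
regions_table <- function(regions) {
  if (!length(regions))
    return(data.frame(label = integer(0), area = integer(0),
                      mean_gray = numeric(0), coverage = numeric(0),
                      positive = logical(0), intensity_class = character(0),
                      stringsAsFactors = FALSE))
  data.frame(
    label = vapply(regions, function(r) as.integer(r$label), integer(1)),
    area = vapply(regions, function(r) as.integer(r$area), integer(1)),
    mean_gray = vapply(regions, function(r) as.numeric(r$mean_gray), numeric(1)),
    coverage = vapply(regions, function(r) as.numeric(r$coverage), numeric(1)),
    positive = vapply(regions, function(r) as.logical(r$positive), logical(1)),
    intensity_class = vapply(regions, function(r) as.character(r$intensity_class), character(1)),
    stringsAsFactors = FALSE
  )
}
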