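#' @title Synthetic fields with exact ground truth
#'
#' @description
#' Seeded generators of H-DAB-like and fluorescence-like fields of view in
#' which every nucleus is a disk with a known area and a known fraction of
#' that area carrying antibody signal. The signal occupies a contiguous
#' angular sector whose pixel count is exactly
#' \code{round(true_coverage * area)}, so recovery of the positivity call
#' can be checked against an exact oracle. All generators are deterministic
#' given their seed.
#'
#' @name synthetic-fields
NULL

# run expr with a temporarily-seeded RNG, restoring global state after
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Specify a synthetic field of disk nuclei
#'
#' Places \code{n_nuclei} non-overlapping disks by rejection sampling
#' (pairwise centre distance above the radius sum plus 2 px, at most 10000
#' attempts). Radii are drawn uniformly from \code{radius_range}, chosen so
#' default disk areas fall inside the 300--1200 px particle gate.
#'
#' @param seed RNG seed.
#' @param n_nuclei Number of nuclei.
#' @param coverage Per-nucleus true signal coverage fractions; either a
#'   vector of length \code{n_nuclei}, a single value, or \code{NULL} to
#'   draw uniformly on \code{[0, 1]}.
#' @param height,width Field size in pixels.
#' @param radius_range Disk radius bounds in pixels (min 3).
#' @param dab_concentration,hema_concentration Stain amounts (OD units) used
#'   when rendering.
#' @param noise_sd Gaussian background noise SD in 8-bit intensity units.
#' @return Object of class \code{field_spec}: field geometry plus a
#'   \code{nuclei} data frame (centre row/col, radius, true coverage,
#'   concentrations).
#' @export
make_field_spec <- function(seed, n_nuclei = 20, coverage = NULL,
                            height = 300, width = 400,
                            radius_range = c(10, 18),
                            dab_concentration = 0.8,
                            hema_concentration = 0.7,
                            noise_sd = 0) {
  stopifnot(radius_range[1] >= 3, radius_range[2] >= radius_range[1])
  if (!is.null(coverage)) {
    if (length(coverage) == 1L) coverage <- rep(coverage, n_nuclei)
    if (length(coverage) != n_nuclei)
      stop("coverage must have one value per nucleus")
    if (any(coverage < 0 | coverage > 1)) stop("coverage must lie in [0, 1]")
  }
  nuc <- with_seed(seed, {
    cov <- if (is.null(coverage)) stats::runif(n_nuclei) else coverage
    rows <- numeric(0); cols <- numeric(0); radii <- numeric(0)
    attempts <- 0L
    while (length(rows) < n_nuclei) {
      attempts <- attempts + 1L
      if (attempts > 10000L)
        stop("could not place ", n_nuclei, " non-overlapping nuclei in a ",
             height, "x", width, " field; use fewer or smaller nuclei")
      rad <- stats::runif(1, radius_range[1], radius_range[2])
      cy <- stats::runif(1, rad + 2, height - rad - 1)
      cx <- stats::runif(1, rad + 2, width - rad - 1)
      if (length(rows) == 0 ||
          all(sqrt((rows - cy)^2 + (cols - cx)^2) > radii + rad + 2)) {
        rows <- c(rows, cy); cols <- c(cols, cx); radii <- c(radii, rad)
      }
    }
    data.frame(row = rows, col = cols, radius = radii,
               true_coverage = cov,
               dab_concentration = rep(dab_concentration, n_nuclei),
               hema_concentration = rep(hema_concentration, n_nuclei))
  })
  if (n_nuclei == 0L)
    nuc <- data.frame(row = numeric(0), col = numeric(0), radius = numeric(0),
                      true_coverage = numeric(0),
                      dab_concentration = numeric(0),
                      hema_concentration = numeric(0))
  structure(list(seed = seed, height = height, width = width,
                 noise_sd = noise_sd, nuclei = nuc),
            class = "field_spec")
}

#' @export
print.field_spec <- function(x, ...) {
  cat(sprintf("Synthetic field spec: %dx%d px, %d nuclei, seed %s, noise sd %g\n",
              x$height, x$width, nrow(x$nuclei), format(x$seed), x$noise_sd))
  invisible(x)
}

# disk pixels and the sector carrying signal; selection is deterministic:
# pixels ordered by polar angle from the centre (ties broken by radius,
# then raster order), first round(coverage * area) pixels form the sector
disk_and_sector <- function(cy, cx, radius, coverage, h, w) {
  r0 <- max(1L, floor(cy - radius)); r1 <- min(h, ceiling(cy + radius))
  c0 <- max(1L, floor(cx - radius)); c1 <- min(w, ceiling(cx + radius))
  rr <- r0:r1; cc <- c0:c1
  grid_r <- rep(rr, times = length(cc))
  grid_c <- rep(cc, each = length(rr))
  d2 <- (grid_r - cy)^2 + (grid_c - cx)^2
  inside <- d2 <= radius^2
  pr <- grid_r[inside]; pc <- grid_c[inside]
  px <- (pc - 1L) * h + pr
  ang <- atan2(pr - cy, pc - cx)
  ord <- order(ang, d2[inside], pr, pc)
  k <- round(coverage * length(px))
  list(disk = px, sector = px[ord][seq_len(k)])
}

#' Render an H-DAB-like RGB field from a spec
#'
#' Each nucleus disk receives haematoxylin at its spec concentration;
#' its signal sector additionally receives DAB. The concentration maps are
#' composed to RGB through the forward Beer--Lambert model
#' ([render_from_concentrations()]); optional Gaussian noise is then added
#' and the image re-quantized to 8-bit.
#'
#' @param spec A [make_field_spec()] object.
#' @param vectors 3x3 stain matrix.
#' @return List: \code{image} (8-bit RGB), \code{truth} (the spec's nucleus
#'   table with exact sector pixel counts), \code{c_hema}, \code{c_dab}.
#' @export
render_h_dab <- function(spec, vectors = stain_vectors_hdab()) {
  h <- spec$height; w <- spec$width
  c_hema <- matrix(0, h, w); c_dab <- matrix(0, h, w)
  truth <- spec$nuclei
  truth$area <- integer(nrow(truth)); truth$sector_px <- integer(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    ds <- disk_and_sector(truth$row[i], truth$col[i], truth$radius[i],
                          truth$true_coverage[i], h, w)
    c_hema[ds$disk] <- truth$hema_concentration[i]
    c_dab[ds$sector] <- truth$dab_concentration[i]
    truth$area[i] <- length(ds$disk)
    truth$sector_px[i] <- length(ds$sector)
  }
  img <- render_from_concentrations(c_hema, c_dab, vectors)
  if (spec$noise_sd > 0) {
    img <- with_seed(spec$seed + 1L, {
      canonical8(img + stats::rnorm(length(img), 0, spec$noise_sd))
    })
  }
  list(image = img, truth = truth, c_hema = c_hema, c_dab = c_dab)
}

#' Render a fluorescence-like channel pair from a spec
#'
#' Nuclei channel: disks bright on a dark background, intensity
#' \code{round(255 * hema_concentration)} scaled into 8-bit; signal
#' channel: the same per-nucleus sectors at
#' \code{round(255 * dab_concentration)}. Optional Gaussian noise.
#'
#' @param spec A [make_field_spec()] object.
#' @return List: \code{nuclei}, \code{signal} (8-bit matrices),
#'   \code{truth}.
#' @export
render_fluorescence <- function(spec) {
  h <- spec$height; w <- spec$width
  nuc8 <- matrix(0L, h, w); sig8 <- matrix(0L, h, w)
  truth <- spec$nuclei
  truth$area <- integer(nrow(truth)); truth$sector_px <- integer(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    ds <- disk_and_sector(truth$row[i], truth$col[i], truth$radius[i],
                          truth$true_coverage[i], h, w)
    nuc8[ds$disk] <- as.integer(min(255, round(255 * truth$hema_concentration[i])))
    sig8[ds$sector] <- as.integer(min(255, round(255 * truth$dab_concentration[i])))
    truth$area[i] <- length(ds$disk)
    truth$sector_px[i] <- length(ds$sector)
  }
  if (spec$noise_sd > 0) {
    res <- with_seed(spec$seed + 1L, {
      list(nuclei = canonical8(nuc8 + stats::rnorm(length(nuc8), 0, spec$noise_sd)),
           signal = canonical8(sig8 + stats::rnorm(length(sig8), 0, spec$noise_sd)))
    })
    nuc8 <- res$nuclei; sig8 <- res$signal
  }
  list(nuclei = nuc8, signal = sig8, truth = truth)
}

#' True percent-positive of a spec at a coverage threshold
#'
#' @param spec A [make_field_spec()] object.
#' @param threshold Coverage threshold (inclusive).
#' @return Percentage of nuclei with \code{true_coverage >= threshold}.
#' @export
true_percent_positive <- function(spec, threshold = 0.80) {
  n <- nrow(spec$nuclei)
  if (n == 0L) return(NA_real_)
  100 * sum(spec$nuclei$true_coverage >= threshold) / n
}

#' Simulate a rater panel for calibration tests
#'
#' Emulates a panel of human raters scoring a set of fields: each rater's
#' score for a field is its true percent-positive at the 0.80 coverage
#' threshold plus independent Gaussian noise, clipped to \code{[0, 100]}.
#'
#' @param specs List of [make_field_spec()] objects.
#' @param noise_sd Rater noise SD in percentage points.
#' @param k_raters Number of raters (at least 2).
#' @param seed RNG seed.
#' @return Numeric matrix (fields x raters) with dimnames, attribute
#'   \code{truth} holding the noise-free scores.
#' @export
make_rater_panel <- function(specs, noise_sd = 5, k_raters = 5, seed = 1) {
  if (k_raters < 2L) stop("need at least 2 raters")
  truth <- vapply(specs, true_percent_positive, numeric(1))
  scores <- with_seed(seed, {
    m <- truth + matrix(stats::rnorm(length(truth) * k_raters, 0, noise_sd),
                        length(truth), k_raters)
    pmin(pmax(m, 0), 100)                 # scalars second: keep the dim
  })
  dimnames(scores) <- list(paste0("image", seq_along(specs)),
                           paste0("rater", seq_len(k_raters)))
  attr(scores, "truth") <- truth
  scores
}
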