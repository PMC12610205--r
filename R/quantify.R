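#' Fraction of a nucleus covered by the signal mask
#'
#' @param region A nucleus region (see [measure_regions()]).
#' @param signal Integer 0/1 signal mask, same shape as the source image.
#' @return Fraction in \code{[0, 1]}.
#' @export
coverage_fraction <- function(region, signal) {
  if (any(region$pixels > length(signal)))
    stop("region lies outside the signal mask")
  sum(signal[region$pixels] != 0) / region$area
}

#' Positivity call from a coverage fraction
#'
#' A nucleus is positive when the signal covers at least the configured
#' fraction of its area (the boundary is inclusive: coverage exactly equal
#' to the threshold counts as positive).
#'
#' @param fraction,threshold Values in \code{[0, 1]}.
#' @return Logical.
#' @export
classify_positive <- function(fraction, threshold = 0.80) {
  stopifnot(fraction >= 0, fraction <= 1, threshold >= 0, threshold <= 1)
  fraction >= threshold
}

#' Percentage of positive nuclei in a field
#'
#' @param regions List of nucleus regions with \code{positive} set.
#' @return Percentage in \code{[0, 100]}; \code{NA} with a warning on an
#'   empty field (no nuclei is not the same as no positivity).
#' @export
percent_positive <- function(regions) {
  n <- length(regions)
  if (n == 0L) {
    warning("empty field: percentage of positive nuclei is undefined")
    return(NA_real_)
  }
  100 * sum(vapply(regions, function(r) isTRUE(r$positive), logical(1))) / n
}

#' Semiquantitative intensity class of a nucleus
#'
#' Positivity gates intensity: a non-positive nucleus is "negative"
#' regardless of its staining. Positive nuclei are classed on their mean
#' gray value measured on the DAB pseudo-transmittance (or signal) channel:
#' strong below 60, moderate in \code{[60, 120)}, weak at 120 and above.
#'
#' @param region Nucleus region with \code{mean_gray} and \code{positive} set.
#' @return One of \code{"negative"}, \code{"weak"}, \code{"moderate"},
#'   \code{"strong"}.
#' @export
classify_intensity <- function(region) {
  mg <- region$mean_gray
  if (is.na(mg) || mg < 0 || mg > 255) stop("mean_gray outside [0, 255]")
  if (!isTRUE(region$positive)) return("negative")
  if (mg < 60) "strong" else if (mg < 120) "moderate" else "weak"
}

#' Histoscore (H-score)
#'
#' \code{3 * \%strong + 2 * \%moderate + 1 * \%weak}, range 0--300.
#'
#' @param pct_strong,pct_moderate,pct_weak Class percentages.
#' @return Numeric score.
#' @export
histoscore <- function(pct_strong, pct_moderate, pct_weak) {
  3 * pct_strong + 2 * pct_moderate + 1 * pct_weak
}

#' Overall intensity score and field category
#'
#' \code{4 * \%strong + 3 * \%moderate + 2 * \%weak + 1 * \%negative},
#' range 100--400, mapped to a field-level category: above 301 strong,
#' (201, 301] moderate, (101, 201] weak, at or below 101 negative. A 1%
#' cut-off overrides the score: a field with at least 99% negative nuclei
#' is categorized negative outright.
#'
#' @param pct_strong,pct_moderate,pct_weak,pct_negative Class percentages
#'   summing to 100.
#' @return List with \code{score} and \code{category}.
#' @export
overall_score <- function(pct_strong, pct_moderate, pct_weak, pct_negative) {
  s <- pct_strong + pct_moderate + pct_weak + pct_negative
  if (abs(s - 100) > 1e-6) stop("class percentages must sum to 100")
  score <- 4 * pct_strong + 3 * pct_moderate + 2 * pct_weak + 1 * pct_negative
  category <- if (pct_negative >= 99) "negative"
  else if (score > 301) "strong"
  else if (score > 201) "moderate"
  else if (score > 101) "weak"
  else "negative"
  list(score = score, category = category)
}

#' Per-nucleus quantitative mean intensities
#'
#' @param regions List of nucleus regions with \code{mean_gray} (and, for
#'   \code{scope = "positive_only"}, \code{positive}) set.
#' @param scope \code{"all"} or \code{"positive_only"}.
#' @return Data frame of \code{label}, \code{mean_gray}.
#' @export
quantitative_intensity <- function(regions, scope = c("all", "positive_only")) {
  scope <- match.arg(scope)
  if (scope == "positive_only")
    regions <- Filter(function(r) isTRUE(r$positive), regions)
  if (!length(regions)) {
    if (scope == "positive_only")
      warning("no positive nuclei: quantitative intensity table is empty")
    return(data.frame(label = integer(0), mean_gray = numeric(0)))
  }
  data.frame(label = vapply(regions, function(r) as.integer(r$label), integer(1)),
             mean_gray = vapply(regions, function(r) r$mean_gray, numeric(1)))
}

# Signal-channel mask: automatic threshold + manual offset. A constant
# channel carries no detectable signal and yields an empty mask (rather
# than the degenerate-threshold convention selecting every pixel).
signal_mask <- function(channel, method, offset, polarity) {
  if (length(unique(as.vector(channel))) == 1L) {
    warning("constant signal channel: no signal detected")
    return(matrix(0L, nrow(channel), ncol(channel)))
  }
  t <- auto_threshold(histogram256(channel), method)
  t <- manual_offset(t, offset)
  apply_threshold(channel, t, polarity)
}

#' Analyze one field of view
#'
#' Runs the full pipeline on a single field: nucleus detection (colour
#' deconvolution and auto-thresholding for H-DAB, direct thresholding for
#' fluorescence, or ingestion of a supplied mask), size-gated particle
#' analysis, independent signal thresholding, per-nucleus coverage and
#' positivity, and optional intensity measurement.
#'
#' @param image RGB H-DAB image (\code{mode = "h_dab"} only).
#' @param nuclei Nuclei-channel image (fluorescence) or mask/label image
#'   (preprocessed mode).
#' @param signal Signal-channel image (fluorescence or preprocessed mode).
#' @param config A [quant_config()] object.
#' @return An object of class \code{nq_field}: list with \code{regions}
#'   (per-nucleus list), \code{result} (field summary), \code{config},
#'   \code{label_map}, \code{signal_mask}, and per-mode channels; plus
#'   \code{intensity} table when a quantitative mode is selected.
#' @export
analyze_field <- function(image = NULL, nuclei = NULL, signal = NULL,
                          config = quant_config()) {
  if (!inherits(config, "quant_config")) stop("config must be a quant_config")
  mode <- config$mode
  if (mode == "h_dab") {
    if (is.null(image)) stop("configuration error: h_dab mode needs 'image'")
    if (n_channels(image) != 3L) stop("h_dab mode needs an RGB image")
    sep <- separate_h_dab(canonical8(image), config$stain_vectors)
    nuclei_chan <- sep$nuclei
    signal_chan <- sep$dab
    nuc_polarity <- sig_polarity <- "dark_object"
    display <- canonical8(image)
  } else if (mode == "fluorescence") {
    if (is.null(nuclei) || is.null(signal))
      stop("configuration error: fluorescence mode needs 'nuclei' and 'signal'")
    nuclei_chan <- to_gray8(canonical8(nuclei))
    signal_chan <- to_gray8(canonical8(signal))
    nuc_polarity <- sig_polarity <- "bright_object"
    display <- nuclei_chan
  } else {                                # preprocessed_h_dab
    if (is.null(nuclei) || is.null(signal))
      stop("configuration error: preprocessed mode needs 'nuclei' and 'signal'")
    nuclei_chan <- NULL
    signal_chan <- to_gray8(canonical8(signal))
    sig_polarity <- "dark_object"
    display <- signal_chan
  }
  if (!is.null(nuclei_chan) &&
      !identical(dim(nuclei_chan), dim(signal_chan)[1:2]))
    stop("nuclei and signal images must share one shape")

  # --- nucleus detection ---
  if (mode == "preprocessed_h_dab") {
    nm <- if (n_channels(nuclei) == 3L) nuclei[, , 1L] else nuclei
    lm <- ingest_mask(round(nm))           # labels may exceed 255; no 8-bit clamp
  } else {
    if (length(unique(as.vector(nuclei_chan))) == 1L) {
      warning("constant nuclei channel: no nuclei detected")
      lm <- matrix(0L, nrow(signal_chan), ncol(signal_chan))
    } else {
      tn <- auto_threshold(histogram256(nuclei_chan), config$nuclei_method)
      lm <- label_components(apply_threshold(nuclei_chan, tn, nuc_polarity))
    }
  }
  regions <- filter_particles(lm, config$min_area, config$max_area,
                              config$exclude_edges, config$fill_holes)
  label_map <- attr(regions, "label_map")

  # --- signal detection ---
  smask <- signal_mask(signal_chan, config$signal_method,
                       config$signal_offset, sig_polarity)

  # --- per-nucleus quantification ---
  regions <- measure_regions(regions, signal_chan)
  for (i in seq_along(regions)) {
    regions[[i]]$coverage <- coverage_fraction(regions[[i]], smask)
    regions[[i]]$positive <- classify_positive(regions[[i]]$coverage,
                                               config$coverage_threshold)
  }
  semi <- config$intensity_mode == "semiquantitative"
  if (semi) {
    for (i in seq_along(regions))
      regions[[i]]$intensity_class <- classify_intensity(regions[[i]])
  }

  # --- field summary ---
  n <- length(regions)
  pct_pos <- percent_positive(regions)
  res <- list(n_nuclei = n,
              n_positive = if (n) sum(vapply(regions, function(r) isTRUE(r$positive), logical(1))) else 0L,
              pct_positive = pct_pos,
              pct_strong = NA_real_, pct_moderate = NA_real_,
              pct_weak = NA_real_, pct_negative = NA_real_,
              histoscore = NA_real_, overall_score = NA_real_,
              overall_category = NA_character_)
  if (semi && n > 0) {
    cls <- vapply(regions, function(r) r$intensity_class, character(1))
    pct <- function(k) 100 * sum(cls == k) / n
    res$pct_strong <- pct("strong"); res$pct_moderate <- pct("moderate")
    res$pct_weak <- pct("weak"); res$pct_negative <- pct("negative")
    res$histoscore <- histoscore(res$pct_strong, res$pct_moderate, res$pct_weak)
    ov <- overall_score(res$pct_strong, res$pct_moderate, res$pct_weak,
                        res$pct_negative)
    res$overall_score <- ov$score
    res$overall_category <- ov$category
  }
  out <- list(regions = regions, result = res, config = config,
              label_map = label_map, signal_mask = smask,
              signal_channel = signal_chan, display = display)
  if (config$intensity_mode %in% c("quantitative_all", "quantitative_positive")) {
    out$intensity <- quantitative_intensity(
      regions,
      if (config$intensity_mode == "quantitative_all") "all" else "positive_only")
  }
  class(out) <- "nq_field"
  out
}

#' @export
print.nq_field <- function(x, ...) {
  r <- x$result
  cat(sprintf("Field analysis (%s mode)\n", x$config$mode))
  cat(sprintf("  nuclei detected: %d\n", r$n_nuclei))
  if (is.na(r$pct_positive)) {
    cat("  %% positive: undefined (empty field)\n")
  } else {
    cat(sprintf("  positive nuclei: %d (%.1f%%) at coverage >= %.2f\n",
                r$n_positive, r$pct_positive, x$config$coverage_threshold))
  }
  if (!is.na(r$histoscore)) {
    cat(sprintf("  classes: %.1f%% strong / %.1f%% moderate / %.1f%% weak / %.1f%% negative\n",
                r$pct_strong, r$pct_moderate, r$pct_weak, r$pct_negative))
    cat(sprintf("  histoscore: %.1f; overall score %.1f (%s)\n",
                r$histoscore, r$overall_score, r$overall_category))
  }
  invisible(x)
}

#' @export
summary.nq_field <- function(object, ...) {
  df <- regions_table(object$regions)
  print(object)
  if (nrow(df)) {
    cat("\nPer-nucleus summary:\n")
    print(summary(df[, c("area", "mean_gray", "coverage")]))
  }
  invisible(df)
}

#' @export
plot.nq_field <- function(x, ...) {
  ov <- write_overlay(x$display, x$regions, path = NULL)
  op <- graphics::par(mar = c(0.5, 0.5, 2, 0.5)); on.exit(graphics::par(op))
  graphics::plot(c(0, ncol(ov)), c(0, nrow(ov)), type = "n", asp = 1,
                 axes = FALSE, xlab = "", ylab = "",
                 main = sprintf("%d nuclei, %.1f%% positive",
                                x$result$n_nuclei,
                                ifelse(is.na(x$result$pct_positive), 0,
                                       x$result$pct_positive)))
  graphics::rasterImage(ov / 255, 0, 0, ncol(ov), nrow(ov))
  invisible(x)
}
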