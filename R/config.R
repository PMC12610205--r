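#' Analysis configuration
#'
#' Bundles every user-settable parameter of the pipeline. Defaults mirror
#' the method's published defaults: coverage threshold 0.80, "Default"
#' thresholding for both nuclei and signal, no manual signal offset, and no
#' intensity measurement.
#'
#' @param mode Staining mode: \code{"h_dab"} (one RGB image),
#'   \code{"fluorescence"} (nuclei + signal images) or
#'   \code{"preprocessed_h_dab"} (nucleus mask/label image + signal image).
#' @param nuclei_method,signal_method Threshold algorithm names
#'   (see [threshold_methods()]).
#' @param signal_offset Signed integer added to the automatic signal
#'   threshold (clipped to \code{[0, 255]}); the nuclei threshold is always
#'   fully automatic.
#' @param min_area,max_area Nucleus size gate in pixels. The defaults
#'   300--1200 px suit the cell lines the method was tuned on at 200x /
#'   1920x1200 px; re-measure for other material.
#' @param coverage_threshold Fraction of the nuclear area that the signal
#'   mask must cover (inclusive) for a nucleus to be called positive.
#' @param intensity_mode \code{"none"}, \code{"semiquantitative"}
#'   (negative/weak/moderate/strong classes, histoscore, overall score),
#'   \code{"quantitative_all"} or \code{"quantitative_positive"}
#'   (per-nucleus mean gray values).
#' @param exclude_edges,fill_holes Particle-filter switches
#'   (see [filter_particles()]).
#' @param stain_vectors 3x3 H-DAB stain matrix (see [stain_vectors_hdab()]).
#' @return An object of class \code{quant_config}.
#' @export
quant_config <- function(mode = c("h_dab", "fluorescence", "preprocessed_h_dab"),
                         nuclei_method = "Default",
                         signal_method = "Default",
                         signal_offset = 0L,
                         min_area = 300,
                         max_area = 1200,
                         coverage_threshold = 0.80,
                         intensity_mode = c("none", "semiquantitative",
                                            "quantitative_all",
                                            "quantitative_positive"),
                         exclude_edges = FALSE,
                         fill_holes = TRUE,
                         stain_vectors = stain_vectors_hdab()) {
  mode <- match.arg(mode)
  intensity_mode <- match.arg(intensity_mode)
  nuclei_method <- match.arg(nuclei_method, threshold_methods())
  signal_method <- match.arg(signal_method, threshold_methods())
  if (!is.numeric(coverage_threshold) || coverage_threshold < 0 ||
      coverage_threshold > 1)
    stop("configuration error: coverage_threshold must lie in [0, 1]")
  if (min_area < 0 || min_area > max_area)
    stop("configuration error: need 0 <= min_area <= max_area")
  if (abs(signal_offset) > 255)
    stop("configuration error: signal_offset must lie in [-255, 255]")
  structure(list(
    mode = mode, nuclei_method = nuclei_method, signal_method = signal_method,
    signal_offset = as.integer(signal_offset), min_area = min_area,
    max_area = max_area, coverage_threshold = coverage_threshold,
    intensity_mode = intensity_mode, exclude_edges = isTRUE(exclude_edges),
    fill_holes = isTRUE(fill_holes), stain_vectors = stain_vectors
  ), class = "quant_config")
}

#' @export
print.quant_config <- function(x, ...) {
  cat("Nuclear quantification configuration\n")
  cat(sprintf("  mode: %s\n", x$mode))
  cat(sprintf("  thresholds: nuclei '%s', signal '%s' (offset %+d)\n",
              x$nuclei_method, x$signal_method, x$signal_offset))
  cat(sprintf("  nucleus area gate: %g-%g px%s%s\n", x$min_area, x$max_area,
              if (x$exclude_edges) ", edge-excluded" else "",
              if (x$fill_holes) ", holes filled" else ""))
  cat(sprintf("  coverage threshold: %.2f; intensity: %s\n",
              x$coverage_threshold, x$intensity_mode))
  invisible(x)
}

#' Load a configuration from a YAML file with flag overrides
#'
#' Keys in the file correspond to [quant_config()] arguments; any entry of
#' \code{overrides} (e.g. parsed CLI flags) wins over the file value, and
#' package defaults fill the rest.
#'
#' @param path Path to a YAML config file, or \code{NULL} for defaults only.
#' @param overrides Named list of values taking precedence over the file.
#' @return A \code{quant_config} object.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    vals <- yaml::read_yaml(path)
    if (!is.list(vals)) stop("config file must contain a mapping")
  }
  vals[names(overrides)] <- overrides
  allowed <- names(formals(quant_config))
  bad <- setdiff(names(vals), allowed)
  if (length(bad)) stop("configuration error: unknown key(s): ",
                        paste(bad, collapse = ", "))
  do.call(quant_config, vals)
}
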